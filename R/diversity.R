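#' Alpha diversity of a single sample
#'
#' `observed_otus()` counts OTUs with positive counts. `chao1()` is the
#' classic richness estimator `S_obs + F1^2 / (2 F2)` where `F1`/`F2` are
#' the singleton/doubleton counts, switching to the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` when there are no doubletons (the
#' QIIME convention); with no singletons it equals `S_obs`. `shannon()` is
#' `-sum p_i log p_i` (natural log by default) and `simpson()` the
#' Gini-Simpson index `1 - sum p_i^2` (set `gini = FALSE` for raw
#' Simpson concentration).
#'
#' @param counts Non-negative integer vector of OTU counts for one sample.
#' @param base Logarithm base for `shannon()`.
#' @param gini Report `1 - D` (default) or raw `D`.
#' @return A single number.
#' @examples
#' chao1(c(rep(1, 4), rep(2, 2), rep(10, 4))) # 10 + 16/4 = 14
#' shannon(rep(5, 4))                         # log(4)
#' @name alpha_metrics
NULL

#' @rdname alpha_metrics
#' @export
observed_otus <- function(counts) {
  check_counts(counts)
  sum(counts > 0)
}

#' @rdname alpha_metrics
#' @export
chao1 <- function(counts) {
  check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f1 == 0) return(as.numeric(s_obs))
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' @rdname alpha_metrics
#' @export
shannon <- function(counts, base = exp(1)) {
  check_counts(counts, positive_sum = TRUE)
  vegan::diversity(counts, index = "shannon", base = base)
}

#' @rdname alpha_metrics
#' @export
simpson <- function(counts, gini = TRUE) {
  check_counts(counts, positive_sum = TRUE)
  d <- vegan::diversity(counts, index = "simpson") # Gini-Simpson 1 - sum p^2
  if (gini) d else 1 - d
}

check_counts <- function(counts, positive_sum = FALSE) {
  abort_if(!is.numeric(counts) || any(counts < 0) ||
             any(counts != round(counts)),
           "counts must be non-negative integers")
  abort_if(positive_sum && sum(counts) == 0, "zero-sum count vector")
  invisible(TRUE)
}

#' Alpha diversity table
#'
#' @param table A (typically rarefied) [count_table()].
#' @param shannon_base Logarithm base for Shannon entropy.
#' @return Tibble with `sample_id`, `observed`, `chao1`, `shannon`,
#'   `simpson` (Gini-Simpson).
#' @export
alpha_diversity <- function(table, shannon_base = exp(1)) {
  m <- as_count_matrix(table)
  out <- tibble::tibble(
    sample_id = rownames(m),
    observed = unname(apply(m, 1, observed_otus)),
    chao1 = unname(apply(m, 1, chao1)),
    shannon = unname(apply(m, 1, shannon, base = shannon_base)),
    simpson = unname(apply(m, 1, simpson)))
  structure(out, class = c("emf_alpha", class(out)))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` on count vectors, computed
#' with [vegan::vegdist()].
#'
#' @param table A [count_table()] with at least two samples and positive
#'   row sums.
#' @return A [stats::dist] object labelled by sample ids.
#' @export
bray_curtis <- function(table) {
  m <- as_count_matrix(table)
  abort_if(nrow(m) < 2, "need at least two samples")
  zero <- rowSums(m) == 0
  abort_if(any(zero), paste0("zero-sum sample(s): ",
                             paste(rownames(m)[zero], collapse = ", ")))
  vegan::vegdist(m, method = "bray")
}

#' Community similarity from a dissimilarity matrix
#'
#' Similarity is the complement of dissimilarity: `s = 1 - d`, so identical
#' communities score 1.
#'
#' @param d A [stats::dist] or square matrix with entries in `[0, 1]`.
#' @return A square similarity matrix with unit diagonal.
#' @export
community_similarity <- function(d) {
  m <- as.matrix(d)
  abort_if(any(m < 0 | m > 1), "dissimilarities must lie in [0, 1]")
  s <- 1 - m
  diag(s) <- 1
  s
}

#' Within-group mean community similarity
#'
#' Averages pairwise similarities over sample pairs inside each group, the
#' usual per-group summary of how alike communities are.
#'
#' @param d Bray-Curtis [stats::dist] over samples.
#' @param frame Sample frame.
#' @param grouping Columns of `frame` that define groups.
#' @return Tibble with group labels, `mean_similarity`, `sd_similarity`,
#'   `n_pairs`.
#' @export
group_similarity <- function(d, frame, grouping = c("disturbance", "surface")) {
  frame <- validate_sample_frame(frame)
  s <- community_similarity(d)
  ids <- rownames(s)
  frame <- frame[match(ids, frame$sample_id), ]
  key <- do.call(paste, c(frame[grouping], sep = ":"))
  purrr::map_dfr(unique(key), function(k) {
    idx <- which(key == k)
    if (length(idx) < 2) {
      return(tibble::tibble(group = k, mean_similarity = NA_real_,
                            sd_similarity = NA_real_, n_pairs = 0L))
    }
    vals <- upper_tri_vec(s[idx, idx, drop = FALSE])
    tibble::tibble(group = k, mean_similarity = mean(vals),
                   sd_similarity = stats::sd(vals),
                   n_pairs = length(vals))
  })
}
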