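#' One-way analysis of variance
#'
#' Classic equal-variance one-way ANOVA: `F = MS_between / MS_within`, with
#' the p-value from the F distribution (delegated to
#' [stats::oneway.test()] with `var.equal = TRUE`). With zero variance both
#' between and within groups the statistic is undefined and reported as
#' `NA` with a warning.
#'
#' @param values Numeric response vector.
#' @param labels Group labels, same length; at least 2 groups with at least
#'   2 observations each.
#' @return Tibble with `statistic` (F), `p_value`, `df_between`,
#'   `df_within`.
#' @export
oneway_anova <- function(values, labels) {
  labels <- as.factor(labels)
  abort_if(length(values) != length(labels), "values and labels differ in length")
  abort_if(nlevels(droplevels(labels)) < 2, "need at least 2 groups")
  abort_if(any(table(droplevels(labels)) < 2),
           "every group needs at least 2 observations")
  ft <- tryCatch(stats::oneway.test(values ~ labels, var.equal = TRUE),
                 error = function(e) NULL)
  if (is.null(ft) || !is.finite(ft$statistic)) {
    warning("F statistic undefined (degenerate variances)", call. = FALSE)
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          df_between = nlevels(droplevels(labels)) - 1L,
                          df_within = length(values) -
                            nlevels(droplevels(labels))))
  }
  tibble::tibble(statistic = unname(ft$statistic),
                 p_value = unname(ft$p.value),
                 df_between = unname(ft$parameter[1]),
                 df_within = unname(ft$parameter[2]))
}

#' Mann-Whitney U test
#'
#' Rank-sum test via [stats::wilcox.test()]: exact enumeration when the
#' pooled sample is small (`n_x + n_y <= 12`) and tie-free, otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples.
#' @return Tibble with `U` (statistic for `x`), `p_value`, `exact`.
#' @export
mann_whitney_u <- function(x, y) {
  abort_if(length(x) == 0 || length(y) == 0, "both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value,
                 exact = exact)
}

as_dist_matrix <- function(d, what = "distance matrix") {
  m <- as.matrix(d)
  abort_if(nrow(m) != ncol(m), paste0(what, " must be square"))
  abort_if(max(abs(m - t(m))) > 1e-12, paste0(what, " must be symmetric"))
  abort_if(any(abs(diag(m)) > 1e-12), paste0(what, " must have zero diagonal"))
  m
}

# All permutations of 1..n (n <= 8 guard), as a matrix with one row each.
all_permutations <- function(n) {
  abort_if(n > 8, "exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the total
#' sum of squared distances `SS_total = sum_{i<j} d_ij^2 / n` into
#' within-group (`SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`) and
#' between-group parts, and tests the pseudo-F
#' `(SS_between / (a - 1)) / (SS_within / (n - a))` by permuting group
#' labels. The permutation p-value uses the add-one convention
#' `(1 + #{F* >= F}) / (1 + n_perm)`; with `exhaustive = TRUE` every
#' distinct label ordering is enumerated instead and
#' `p = #{F* >= F} / n!` (the observed ordering included).
#'
#' @param d Distance matrix ([stats::dist] or square matrix).
#' @param labels Group labels covering all samples; every group needs at
#'   least 2 members.
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive Enumerate all orderings (sample size at most 8).
#' @return An `emf_permanova` object with `statistic` (pseudo-F), `R2`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  labels <- droplevels(as.factor(labels))
  abort_if(length(labels) != n, "labels must cover all samples")
  abort_if(nlevels(labels) < 2, "need at least 2 groups")
  abort_if(any(table(labels) < 2), "refusing groups with a single sample")
  d2 <- m^2
  a <- nlevels(labels)
  pseudo_f <- function(lab_idx) {
    ssw <- 0
    for (lev in levels(labels)) {
      idx <- lab_idx[[lev]]
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sst <- sum(d2) / (2 * n)
    ssb <- sst - ssw
    c(F = (ssb / (a - 1)) / (ssw / (n - a)), R2 = ssb / sst)
  }
  obs <- pseudo_f(split(seq_len(n), labels))
  if (exhaustive) {
    perms <- all_permutations(n)
    fs <- apply(perms, 1, function(o) pseudo_f(split(o, labels))[["F"]])
    p <- mean(fs >= obs[["F"]] - 1e-12)
    n_used <- nrow(perms)
  } else {
    fs <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        o <- sample.int(n)
        pseudo_f(split(o, labels))[["F"]]
      }, numeric(1))
    })
    p <- (1 + sum(fs >= obs[["F"]] - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(statistic = unname(obs[["F"]]), R2 = unname(obs[["R2"]]),
                 p_value = p, n_permutations = n_used, seed = seed,
                 exhaustive = exhaustive, n = n),
            class = "emf_permanova")
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper triangles of two distance matrices and assesses
#' significance by jointly permuting the rows/columns of the second matrix
#' (one-sided, greater). Add-one convention for random permutations;
#' `exhaustive = TRUE` enumerates all orderings (`p = #{r* >= r} / n!`).
#'
#' @param d1,d2 Distance matrices over the same samples.
#' @param n_perm Number of random permutations.
#' @param seed Integer seed.
#' @param method `"pearson"` (classic) or `"spearman"`.
#' @param exhaustive Enumerate all orderings (sample size at most 8).
#' @return An `emf_mantel` object with `statistic` (r), `p_value`,
#'   `n_permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL,
                        method = c("pearson", "spearman"),
                        exhaustive = FALSE) {
  method <- match.arg(method)
  m1 <- as_dist_matrix(d1); m2 <- as_dist_matrix(d2)
  abort_if(nrow(m1) != nrow(m2), "distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    abort_if(!identical(rownames(m1), rownames(m2)),
             "distance matrices cover different samples")
  }
  n <- nrow(m1)
  v1 <- upper_tri_vec(m1)
  r_for <- function(ord) {
    stats::cor(v1, upper_tri_vec(m2[ord, ord]), method = method)
  }
  obs <- r_for(seq_len(n))
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, r_for)
    p <- mean(rs >= obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    rs <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) r_for(sample.int(n)), numeric(1))
    })
    p <- (1 + sum(rs >= obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(statistic = unname(obs), p_value = p,
                 n_permutations = n_used, seed = seed, method = method,
                 n = n),
            class = "emf_mantel")
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the response distance matrix's upper triangle
#' on the predictor matrices' upper triangles (intercept always included).
#' Per-coefficient permutation p-values come from jointly permuting the
#' rows/columns of the response matrix and refitting
#' (`p = (1 + #{|b*| >= |b|}) / (1 + n_perm)`). Collinear predictors are
#' flagged with a warning; rank-deficient coefficients come back `NA`.
#'
#' @param response Response distance matrix.
#' @param predictors Named list of predictor distance matrices.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return An `emf_mrm` object with `coefficients` (tibble `term`,
#'   `estimate`, `p_value`), `R2`, `n_permutations`, `seed`.
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = NULL) {
  abort_if(!is.list(predictors) || length(predictors) == 0,
           "need at least one predictor matrix")
  ym <- as_dist_matrix(response, "response")
  n <- nrow(ym)
  X <- vapply(predictors, function(p) {
    pm <- as_dist_matrix(p, "predictor")
    abort_if(nrow(pm) != n, "predictor size mismatch")
    upper_tri_vec(pm)
  }, numeric(n * (n - 1) / 2))
  terms <- names(predictors) %||% paste0("X", seq_along(predictors))
  if (is.null(colnames(X))) colnames(X) <- terms
  Xd <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xd)
  if (qrx$rank < ncol(Xd)) {
    warning("collinear predictors: coefficients not all identifiable",
            call. = FALSE)
  }
  fit_coefs <- function(yvec) {
    qr.coef(qrx, yvec)
  }
  y <- upper_tri_vec(ym)
  beta <- fit_coefs(y)
  fitted <- Xd[, !is.na(beta), drop = FALSE] %*% beta[!is.na(beta)]
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  exceed <- rep(0, length(beta))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      o <- sample.int(n)
      bstar <- fit_coefs(upper_tri_vec(ym[o, o]))
      exceed <- exceed + as.numeric(abs(bstar) >= abs(beta) - 1e-12)
    }
  })
  pvals <- (1 + exceed) / (1 + n_perm)
  pvals[is.na(beta)] <- NA_real_
  structure(list(coefficients = tibble::tibble(term = names(beta),
                                               estimate = unname(beta),
                                               p_value = unname(pvals)),
                 R2 = r2, n_permutations = n_perm, seed = seed, n = n),
            class = "emf_mrm")
}

#' Least-squares linear regression
#'
#' Simple linear regression with the slope's F-test p-value and R-squared,
#' via [stats::lm()].
#'
#' @param x,y Numeric vectors, `n >= 3`; `x` must vary.
#' @return An `emf_regression` object with `slope`, `intercept`, `R2`,
#'   `p_value`, and the underlying data for plotting.
#' @export
linear_regression <- function(x, y) {
  abort_if(length(x) != length(y), "x and y differ in length")
  abort_if(length(x) < 3, "need n >= 3")
  abort_if(stats::sd(x) == 0, "zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 R2 = sm$r.squared, p_value = p,
                 data = tibble::tibble(x = x, y = y)),
            class = "emf_regression")
}

#' Per-OTU enrichment ratio relative to a control group
#'
#' For every OTU present in the focal or control samples, a one-way ANOVA
#' compares its relative abundance between the two groups; the OTU counts
#' as enriched when `p < alpha` AND its focal mean exceeds its control
#' mean. The ratio is the enriched fraction of all tested OTUs; OTUs with
#' all-zero counts in both groups are excluded from the denominator.
#'
#' @param table A rarefied [count_table()].
#' @param frame Sample frame.
#' @param focal_group,control_group Group selectors like `"PL:G"`
#'   (disturbance:surface) or `"C"` (disturbance only).
#' @param alpha Significance level in `(0, 1)`.
#' @return Tibble with `group`, `n_otus_tested`, `n_enriched`, `ratio`,
#'   `alpha`.
#' @export
enrichment_ratio <- function(table, frame, focal_group, control_group = "C",
                             alpha = 0.05) {
  abort_if(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  frame <- validate_sample_frame(frame)
  pick <- function(selector) {
    sel <- parse_group(selector)
    ids <- frame$sample_id[frame$disturbance == sel$disturbance &
                             (if (is.null(sel$surface)) TRUE
                              else frame$surface == sel$surface)]
    intersect(ids, table$sample_id)
  }
  focal_ids <- pick(focal_group)
  control_ids <- pick(control_group)
  abort_if(length(focal_ids) < 2 || length(control_ids) < 2,
           "each group needs at least 2 samples")
  sub <- as_count_matrix(table)[c(focal_ids, control_ids), , drop = FALSE]
  ra <- sub / rowSums(sub)
  is_focal <- rownames(ra) %in% focal_ids
  present <- colSums(sub) > 0
  if (any(!present)) {
    message(sprintf("excluding %d OTU(s) absent from both groups",
                    sum(!present)))
  }
  ra <- ra[, present, drop = FALSE]
  g <- factor(ifelse(is_focal, "focal", "control"))
  enriched <- vapply(seq_len(ncol(ra)), function(j) {
    v <- ra[, j]
    ft <- tryCatch(stats::oneway.test(v ~ g, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ft) || !is.finite(ft$p.value)) return(FALSE)
    ft$p.value < alpha && mean(v[is_focal]) > mean(v[!is_focal])
  }, logical(1))
  tibble::tibble(group = focal_group,
                 n_otus_tested = ncol(ra),
                 n_enriched = sum(enriched),
                 ratio = sum(enriched) / ncol(ra),
                 alpha = alpha)
}
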