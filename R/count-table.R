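#' OTU count tables
#'
#' A count table is the universal input of the pipeline: a tibble with a
#' `sample_id` character column followed by one non-negative integer column
#' per OTU, carrying a `domain` attribute (`"bacteria"`, `"fungi"`,
#' `"archaea"` or `"merged"`). Samples are rows, as produced by standard
#' amplicon pipelines after OTU picking.
#'
#' @param x A data frame with a `sample_id` column and numeric OTU columns,
#'   or a numeric matrix (samples x OTUs) with row and column names.
#' @param domain Domain label, one of `"bacteria"`, `"fungi"`, `"archaea"`,
#'   `"merged"`.
#' @return A `count_table` tibble.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' count_table(m, domain = "bacteria")
#' @export
count_table <- function(x, domain) {
  abort_if(missing(domain) || !domain %in% c(DOMAINS, "merged"),
           "domain must be one of 'bacteria', 'fungi', 'archaea', 'merged'")
  if (is.matrix(x)) {
    abort_if(is.null(rownames(x)) || is.null(colnames(x)),
             "matrix input needs sample row names and OTU column names")
    x <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)),
                          tibble::as_tibble(x))
  }
  x <- tibble::as_tibble(x)
  abort_if(!"sample_id" %in% names(x), "count table needs a 'sample_id' column")
  x$sample_id <- as.character(x$sample_id)
  counts <- as.matrix(x[setdiff(names(x), "sample_id")])
  abort_if(anyDuplicated(x$sample_id) > 0, "sample ids must be unique")
  abort_if(anyDuplicated(colnames(counts)) > 0, "OTU ids must be unique")
  abort_if(!is.numeric(counts) || anyNA(counts),
           "counts must be numeric with no missing values")
  abort_if(any(counts < 0), "counts must be non-negative")
  abort_if(any(counts != round(counts)), "counts must be integers")
  out <- dplyr::bind_cols(x["sample_id"], tibble::as_tibble(counts))
  structure(out, domain = domain,
            class = c("emf_count_table", class(tibble::tibble())))
}

#' @export
print.emf_count_table <- function(x, ...) {
  cat(sprintf("# count table: %d samples x %d OTUs (domain: %s)\n",
              nrow(x), ncol(x) - 1L, ct_domain(x)))
  NextMethod()
}

#' Extract the counts of a count table as a matrix
#'
#' @param table A [count_table()].
#' @return Integer matrix, samples as rows (named), OTUs as columns.
#' @export
as_count_matrix <- function(table) {
  m <- as.matrix(table[setdiff(names(table), "sample_id")])
  rownames(m) <- table$sample_id
  storage.mode(m) <- "double"
  m
}

#' @rdname as_count_matrix
#' @export
ct_domain <- function(table) attr(table, "domain", exact = TRUE)

#' Read and write count tables
#'
#' TSV files are tab-separated with a header, samples as rows and
#' `sample_id` as the first column. BIOM v1 (JSON) files interoperate with
#' QIIME-era tooling via the biomformat package (OTUs as BIOM rows, the
#' transpose of the in-memory layout).
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param domain Domain label to attach on read.
#' @return `read_count_table()` a [count_table()]; `write_count_table()`
#'   the path, invisibly.
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json"),
                             domain = "merged") {
  format <- match.arg(format)
  abort_if(!file.exists(path), paste0("file not found: ", path))
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    abort_if(!"sample_id" %in% names(df),
             paste0("malformed count table ", path,
                    ": missing 'sample_id' header column"))
    return(count_table(df, domain = domain))
  }
  b <- biomformat::read_biom(path)
  m <- t(as(biomformat::biom_data(b), "matrix"))
  count_table(m, domain = domain)
}

#' @rdname read_count_table
#' @param table A [count_table()].
#' @export
write_count_table <- function(table, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(tibble::as_tibble(table), path)
  } else {
    b <- biomformat::make_biom(t(as_count_matrix(table)))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read sample metadata and environment tables
#'
#' The sample frame holds the experimental design (disturbance C/P/PL,
#' surface G/N/O/B/I, block, site); the environment table holds the measured
#' soil and vegetation variables.
#'
#' @param path TSV file path.
#' @return A tibble, one row per sample.
#' @export
read_sample_frame <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(sample_id = "c"))
  validate_sample_frame(df)
}

#' @rdname read_sample_frame
#' @export
read_env_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(sample_id = "c"))
  abort_if(anyDuplicated(df$sample_id) > 0, "duplicate sample ids in env table")
  df
}

validate_sample_frame <- function(frame) {
  needed <- c("sample_id", "disturbance", "surface", "block", "site")
  missing <- setdiff(needed, names(frame))
  abort_if(length(missing) > 0,
           paste0("sample frame missing columns: ",
                  paste(missing, collapse = ", ")))
  abort_if(anyDuplicated(frame$sample_id) > 0, "duplicate sample ids in frame")
  abort_if(!all(frame$disturbance %in% c("C", "P", "PL")),
           "disturbance labels must be in {C, P, PL}")
  abort_if(!all(frame$surface %in% c("G", "N", "O", "B", "I")),
           "surface labels must be in {G, N, O, B, I}")
  tibble::as_tibble(frame)
}

#' Rarefy a count table to even depth
#'
#' Random subsampling without replacement (multivariate hypergeometric) of
#' each sample's counts to a common depth, the standard correction for
#' unequal library sizes before diversity and network analysis. Samples with
#' total count below `depth` are dropped with a warning naming them.
#'
#' @param table A [count_table()].
#' @param depth Target depth (sequences per sample), `>= 1`.
#' @param seed Integer seed; rarefaction is deterministic given the seed.
#' @return A [count_table()] in which every retained row sums to `depth`.
#' @examples
#' ct <- count_table(matrix(c(600L, 300L, 100L), 1, 3,
#'   dimnames = list("s1", c("a", "b", "c"))), domain = "bacteria")
#' rowSums(as_count_matrix(rarefy(ct, depth = 100, seed = 1)))
#' @export
rarefy <- function(table, depth, seed = NULL) {
  abort_if(!is.numeric(depth) || length(depth) != 1 || depth < 1,
           "depth must be a single integer >= 1")
  depth <- as.integer(depth)
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  drop <- totals < depth
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(rownames(m)[drop], collapse = ", ")),
            call. = FALSE)
    m <- m[!drop, , drop = FALSE]
  }
  abort_if(nrow(m) == 0, "no sample reaches the requested depth")
  out <- with_seed(seed, {
    t(apply(m, 1, function(row) {
      if (sum(row) == depth) return(row)
      # draw reads without replacement from the expanded pool
      pool <- rep.int(seq_along(row), row)
      tab <- tabulate(pool[sample.int(length(pool), depth)],
                      nbins = length(row))
      tab
    }))
  })
  colnames(out) <- colnames(m)
  storage.mode(out) <- "integer"
  count_table(out, domain = ct_domain(table))
}

#' Convert counts to relative abundances
#'
#' @param table A [count_table()] with positive row sums.
#' @return A tibble with the same axes; each row of OTU columns sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- as_count_matrix(table)
  zero <- rowSums(m) == 0
  abort_if(any(zero),
           paste0("zero-sum sample(s): ",
                  paste(rownames(m)[zero], collapse = ", ")))
  ra <- m / rowSums(m)
  dplyr::bind_cols(table["sample_id"], tibble::as_tibble(ra))
}

#' Keep dominant OTUs
#'
#' Retains OTUs whose mean relative abundance across the table's samples is
#' strictly greater than `threshold` (default 0.01%), the eligibility rule
#' for co-occurrence network construction. Column order is preserved.
#'
#' @param table A [count_table()].
#' @param threshold Mean relative-abundance cutoff in `[0, 1)`.
#' @return A [count_table()] with the dominant OTUs only.
#' @export
filter_dominant <- function(table, threshold = 1e-4) {
  abort_if(!is.numeric(threshold) || threshold < 0 || threshold >= 1,
           "threshold must be in [0, 1)")
  ra <- as.matrix(relative_abundance(table)[-1])
  keep <- colMeans(ra) > threshold
  m <- as_count_matrix(table)[, keep, drop = FALSE]
  count_table(m, domain = ct_domain(table))
}

#' Merge per-domain count tables into one cross-domain table
#'
#' OTU ids get a domain prefix (`bac|`, `fun|`, `arc|`) so that merged edge
#' lists and networks remain self-describing; [otu_domain()] inverts the
#' tagging. All tables must cover the same sample set.
#'
#' @param tables List of [count_table()]s with domains in
#'   bacteria/fungi/archaea.
#' @return A [count_table()] with `domain = "merged"`.
#' @export
merge_domains <- function(tables) {
  abort_if(!is.list(tables) || length(tables) == 0, "need at least one table")
  doms <- vapply(tables, ct_domain, character(1))
  abort_if(!all(doms %in% DOMAINS),
           "merge_domains takes per-domain tables (bacteria/fungi/archaea)")
  ids <- lapply(tables, function(t) sort(t$sample_id))
  for (i in seq_along(tables)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      only1 <- setdiff(ids[[1]], ids[[i]])
      only2 <- setdiff(ids[[i]], ids[[1]])
      stop(sprintf("sample sets differ: {%s} only in table 1, {%s} only in table %d",
                   paste(only1, collapse = ","),
                   paste(only2, collapse = ","), i), call. = FALSE)
    }
  }
  ref <- tables[[1]]$sample_id
  mats <- lapply(tables, function(t) {
    m <- as_count_matrix(t)[ref, , drop = FALSE]
    colnames(m) <- paste0(DOMAIN_PREFIX[[ct_domain(t)]], colnames(m))
    m
  })
  merged <- do.call(cbind, mats)
  count_table(merged, domain = "merged")
}

#' Recover the domain of prefixed OTU ids
#'
#' @param otu_ids Character vector of OTU ids carrying a `bac|`/`fun|`/`arc|`
#'   prefix.
#' @return Character vector of domain labels.
#' @export
otu_domain <- function(otu_ids) {
  pre <- substr(otu_ids, 1, 4)
  out <- names(DOMAIN_PREFIX)[match(pre, DOMAIN_PREFIX)]
  abort_if(anyNA(out),
           paste0("OTU id(s) without a recognizable domain prefix: ",
                  paste(utils::head(otu_ids[is.na(out)], 5), collapse = ", ")))
  out
}

#' Subset a count table to one experimental group
#'
#' @param table A [count_table()].
#' @param frame Sample frame (see [read_sample_frame()]).
#' @param disturbance,surface Labels to match; `NULL` matches everything.
#' @return A [count_table()] with exactly the matching samples; OTU columns
#'   are untouched (no re-filtering).
#' @export
subset_by_group <- function(table, frame, disturbance = NULL, surface = NULL) {
  frame <- validate_sample_frame(frame)
  keep <- rep(TRUE, nrow(frame))
  if (!is.null(disturbance)) {
    abort_if(!disturbance %in% frame$disturbance,
             paste0("disturbance label not present in frame: ", disturbance))
    keep <- keep & frame$disturbance == disturbance
  }
  if (!is.null(surface)) {
    abort_if(!surface %in% frame$surface,
             paste0("surface label not present in frame: ", surface))
    keep <- keep & frame$surface == surface
  }
  want <- intersect(frame$sample_id[keep], table$sample_id)
  abort_if(length(want) == 0, "empty group: no samples match the selection")
  m <- as_count_matrix(table)[want, , drop = FALSE]
  count_table(m, domain = ct_domain(table))
}
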