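#' The seven ecosystem-function variables
#'
#' Support/regulation services entering the multifunctionality index:
#' total vegetation coverage, dry and wet vegetation weight, ammonium
#' nitrogen, nitrate nitrogen, soil organic carbon and total nitrogen.
#'
#' @export
EMF_FUNCTIONS <- c("total_coverage", "dry_weight", "wet_weight",
                   "NH4_N", "NO3_N", "SOC", "TN")

#' Select the function matrix from an environment table
#'
#' @param env Environment tibble with a `sample_id` column.
#' @param columns Names of the seven function columns in `env`, in the
#'   order of [EMF_FUNCTIONS].
#' @return Tibble `sample_id` + 7 function columns; refuses missing values.
#' @export
function_matrix <- function(env, columns = EMF_FUNCTIONS) {
  abort_if(length(columns) != 7, "exactly 7 function columns are required")
  missing <- setdiff(c("sample_id", columns), names(env))
  abort_if(length(missing) > 0,
           paste0("environment table missing column(s): ",
                  paste(missing, collapse = ", ")))
  out <- env[c("sample_id", columns)]
  abort_if(anyNA(out), "missing values in the function matrix")
  abort_if(anyDuplicated(out$sample_id) > 0, "duplicate sample ids")
  tibble::as_tibble(out)
}

#' Z-standardize function columns
#'
#' Per column, `(x - mean) / sd` with the sample standard deviation (n - 1
#' denominator), computed jointly over all samples so that groups are
#' compared on a common scale.
#'
#' @param m Function matrix from [function_matrix()].
#' @return Tibble of the same shape; every function column has mean 0 and
#'   sd 1.
#' @export
zscore_columns <- function(m) {
  vars <- setdiff(names(m), "sample_id")
  for (v in vars) {
    s <- stats::sd(m[[v]])
    abort_if(!is.finite(s) || s == 0,
             paste0("zero or undefined standard deviation in column: ", v))
    m[[v]] <- (m[[v]] - mean(m[[v]])) / s
  }
  m
}

#' Ecosystem multifunctionality scores
#'
#' Per-sample EMF index: the mean of the sample's seven function Z-scores.
#' By construction the index is unit-free, symmetric in the functions, and
#' averages to zero over the standardization population.
#'
#' @param m Function matrix from [function_matrix()].
#' @return Tibble `sample_id`, `emf`, with grand mean 0.
#' @examples
#' fm <- tibble::tibble(sample_id = c("a", "b", "c"))
#' for (v in EMF_FUNCTIONS) fm[[v]] <- c(1, 2, 3)
#' emf_scores(fm)$emf # -1, 0, 1
#' @export
emf_scores <- function(m) {
  z <- zscore_columns(m)
  vals <- rowMeans(as.matrix(z[setdiff(names(z), "sample_id")]))
  out <- tibble::tibble(sample_id = z$sample_id, emf = vals)
  structure(out, class = c("emf_scores", class(out)))
}

#' Per-group EMF summary
#'
#' @param scores Output of [emf_scores()].
#' @param frame Sample frame.
#' @param grouping Columns of `frame` defining the groups.
#' @return Tibble with the grouping columns, `mean_emf`, `sd_emf`, `n`,
#'   ordered by group label; the sample-size-weighted mean of `mean_emf`
#'   is 0.
#' @export
group_emf <- function(scores, frame, grouping = c("disturbance", "surface")) {
  frame <- validate_sample_frame(frame)
  joined <- dplyr::inner_join(scores, frame, by = "sample_id")
  abort_if(nrow(joined) == 0, "no overlap between scores and frame")
  out <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(mean_emf = mean(.data$emf),
                     sd_emf = stats::sd(.data$emf),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grouping)))
  structure(out, class = c("emf_group", class(out)))
}
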