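#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for test results
#'
#' broom-style one-row (or one-row-per-term) summaries of the permutation
#' and regression result objects.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name emfnet-tidiers
NULL

#' @rdname emfnet-tidiers
#' @method tidy emf_permanova
#' @export
tidy.emf_permanova <- function(x, ...) {
  tibble::tibble(term = "groups", statistic = x$statistic, R2 = x$R2,
                 p.value = x$p_value, n.permutations = x$n_permutations)
}

#' @rdname emfnet-tidiers
#' @method glance emf_permanova
#' @export
glance.emf_permanova <- function(x, ...) {
  tibble::tibble(pseudo.F = x$statistic, R2 = x$R2, p.value = x$p_value,
                 n = x$n, n.permutations = x$n_permutations,
                 exhaustive = x$exhaustive)
}

#' @rdname emfnet-tidiers
#' @method tidy emf_mantel
#' @export
tidy.emf_mantel <- function(x, ...) {
  tibble::tibble(term = "mantel.r", estimate = x$statistic,
                 p.value = x$p_value, method = x$method,
                 n.permutations = x$n_permutations)
}

#' @rdname emfnet-tidiers
#' @method tidy emf_mrm
#' @export
tidy.emf_mrm <- function(x, ...) {
  dplyr::rename(x$coefficients, p.value = "p_value")
}

#' @rdname emfnet-tidiers
#' @method glance emf_mrm
#' @export
glance.emf_mrm <- function(x, ...) {
  tibble::tibble(R2 = x$R2, n = x$n, n.permutations = x$n_permutations)
}

#' @rdname emfnet-tidiers
#' @method tidy emf_regression
#' @export
tidy.emf_regression <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope),
                 p.value = c(NA_real_, x$p_value))
}

#' @rdname emfnet-tidiers
#' @method glance emf_regression
#' @export
glance.emf_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$R2, p.value = x$p_value,
                 nobs = nrow(x$data))
}

#' @export
print.emf_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%s, %d perms)\n",
              x$statistic, x$R2, x$p_value,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  invisible(x)
}

#' @export
print.emf_mantel <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4g, p = %.4g (%s, %d perms)\n",
              x$statistic, x$p_value, x$method, x$n_permutations))
  invisible(x)
}

#' @export
print.emf_mrm <- function(x, ...) {
  cat(sprintf("MRM: R2 = %.4g (%d perms)\n", x$R2, x$n_permutations))
  print(x$coefficients)
  invisible(x)
}

#' @export
print.emf_regression <- function(x, ...) {
  cat(sprintf("Linear regression: slope = %.4g, intercept = %.4g, R2 = %.4g, p = %.4g\n",
              x$slope, x$intercept, x$R2, x$p_value))
  invisible(x)
}
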