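#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' ggplot2 visualizations of the main result types: the correlation
#' frequency distribution, per-group EMF means, alpha diversity by group
#' and the EMF-diversity regression.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name emfnet-plots
NULL

#' @rdname emfnet-plots
#' @method autoplot emf_corr_hist
#' @export
autoplot.emf_corr_hist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1],
                      fill = "steelblue") +
    ggplot2::labs(x = "Spearman rho", y = "Number of OTU pairs",
                  title = "Frequency distribution of pairwise correlations") +
    ggplot2::theme_minimal()
}

#' @rdname emfnet-plots
#' @method autoplot emf_group
#' @export
autoplot.emf_group <- function(object, ...) {
  grouping <- setdiff(names(object), c("mean_emf", "sd_emf", "n"))
  object$label <- do.call(paste, c(object[grouping], sep = ":"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$label, y = .data$mean_emf)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_emf - .data$sd_emf / sqrt(.data$n),
      ymax = .data$mean_emf + .data$sd_emf / sqrt(.data$n)), width = 0.3) +
    ggplot2::labs(x = NULL, y = "Ecosystem multifunctionality (mean Z)",
                  title = "EMF by group (error bars: SE)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname emfnet-plots
#' @param frame Sample frame used to color samples by disturbance.
#' @param metric Which alpha metric to show.
#' @export
plot_alpha <- function(object, frame, metric = "chao1") {
  abort_if(!metric %in% c("observed", "chao1", "shannon", "simpson"),
           "unknown alpha metric")
  frame <- validate_sample_frame(frame)
  df <- dplyr::inner_join(tibble::as_tibble(object), frame, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$surface,
                                   y = .data[[metric]],
                                   fill = .data$disturbance)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Surface type", y = metric,
                  title = paste("Alpha diversity:", metric)) +
    ggplot2::theme_minimal()
}

#' @rdname emfnet-plots
#' @method autoplot emf_regression
#' @export
autoplot.emf_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "firebrick") +
    ggplot2::labs(title = sprintf("Least-squares fit (R2 = %.3f, p = %.3g)",
                                  object$R2, object$p_value)) +
    ggplot2::theme_minimal()
}
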