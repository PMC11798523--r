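#' Plot a fitted phenophase summary
#'
#' Posterior median of the true date per year with its 95% credible ribbon,
#' and the observed dates as points. The ribbon visibly widens over decades
#' without observations.
#'
#' @param object A `pheno_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pheno_summary <- function(object, ...) {
  alpha <- dplyr::filter(object$states, .data$quantity == "alpha")
  p <- ggplot2::ggplot(alpha, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "#f8b5c9", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "#b03060") +
    ggplot2::labs(
      x = "Year", y = "Day of year",
      title = paste0(object$phenophase,
                     ": estimated true date (median, 95% CI)")
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$observations) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$observations,
      ggplot2::aes(x = .data$year, y = .data$doy), size = 1, colour = "grey20"
    )
  }
  p
}

#' @rdname autoplot.pheno_summary
#' @export
autoplot.pheno_fit <- function(object, ...) {
  autoplot(summarize_posterior(object), ...)
}

#' Plot latent coefficient paths
#'
#' Per-year posterior median and 95% credible ribbon of the intercept and
#' each temperature coefficient, one facet per quantity. Ribbons widen
#' into the record-free past and tighten where observations constrain the
#' walks.
#'
#' @param summary A `pheno_summary`.
#' @return A ggplot object.
#' @export
plot_coefficient_paths <- function(summary) {
  stopifnot(inherits(summary, "pheno_summary"))
  coefs <- dplyr::filter(summary$states, .data$quantity != "alpha")
  ggplot2::ggplot(coefs, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "#9ecae1", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "#08519c") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Year", y = "Posterior median (95% CI)",
                  title = paste0(summary$phenophase, ": coefficient paths")) +
    ggplot2::theme_minimal()
}
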