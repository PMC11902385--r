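#' Plot an IPSG band: mean curve with classical and sup-t ribbons
#'
#' @param object An `ipsg_band` from [ps_bootstrap_band()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ipsg_band <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$boot_lower,
                                      ymax = .data$boot_upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         fill = "grey50", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$boot_mean), colour = "steelblue",
                       linetype = "dashed", linewidth = 0.4) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (a.u.)",
                  title = sprintf("Mean PS curve, classical-t and sup-t bands (B = %d)",
                                  object$B)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of predictions against reference RR
#'
#' @param pred Prediction tibble with reference and prediction columns.
#' @param truth,estimate Column names.
#' @param k Agreement-limit multiplier.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(pred, truth = "rr", estimate = ".pred", k = 2) {
  ba <- bland_altman(pred, truth, estimate, k = k)
  d <- tibble::tibble(avg = (pred[[truth]] + pred[[estimate]]) / 2,
                      diff = pred[[estimate]] - pred[[truth]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$me, colour = "black") +
    ggplot2::geom_hline(yintercept = c(ba$lower, ba$upper), colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of prediction and reference (brpm)",
                  y = "Prediction - reference (brpm)",
                  title = sprintf("Bland-Altman: ME %.2f, limits %.2f / %.2f brpm",
                                  ba$me, ba$lower, ba$upper)) +
    ggplot2::theme_minimal()
}

#' Box plot of per-repetition MAEs by model and augmentation variant
#'
#' @param study Output of [rr_study()].
#' @param metric Metric column to plot.
#' @return A ggplot.
#' @export
plot_study <- function(study, metric = "mae") {
  study$variant <- ifelse(study$ipsg, "IPSG", "plain")
  ggplot2::ggplot(study, ggplot2::aes(x = .data$model,
                                      y = .data[[metric]],
                                      fill = .data$variant)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = sprintf("%s (brpm)", toupper(metric)),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
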