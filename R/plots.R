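#' Plot replicate estimate densities from a simulation study
#'
#' Kernel density curves of the replicate estimates for one parameter,
#' one panel per sample size, with dotted lines at the empirical
#' 2.5%/97.5% quantiles of each model and a dashed line at the
#' generating value.
#'
#' @param object An `"allom_study"` from [run_study()].
#' @param parameter `"slope"` or `"intercept"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allom_study
#' @export
autoplot.allom_study <- function(object, parameter = c("slope", "intercept"),
                                 ...) {
  parameter <- match.arg(parameter)
  dens <- dplyr::filter(object$densities, .data$parameter == !!parameter)
  qs <- dplyr::filter(object$summary, .data$parameter == !!parameter) |>
    tidyr::pivot_longer(c("q2.5", "q97.5"), names_to = "which",
                        values_to = "q")
  truth <- switch(parameter, slope = object$config$sim$alpha,
                  intercept = object$config$sim$beta)
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$grid, y = .data$density,
                                     colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = qs,
                        ggplot2::aes(xintercept = .data$q,
                                     colour = .data$model),
                        linetype = "dotted", linewidth = 0.3,
                        show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = truth, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::facet_wrap(~sample_size, scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = parameter, y = "density", colour = "model") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap slope/intercept distributions
#'
#' Kernel density curves of the bootstrap replicate estimates per model,
#' with dotted lines at the percentile 95% interval bounds.
#'
#' @param object An `"allom_boot"` from [run_bootstrap()].
#' @param parameter `"slope"` or `"intercept"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allom_boot
#' @export
autoplot.allom_boot <- function(object, parameter = c("slope", "intercept"),
                                ...) {
  parameter <- match.arg(parameter)
  est <- object$estimates
  est$value <- est[[parameter]]
  qs <- est |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(q2.5 = .q95(.data$value)[1],
                     q97.5 = .q95(.data$value)[2], .groups = "drop") |>
    tidyr::pivot_longer(c("q2.5", "q97.5"), names_to = "which",
                        values_to = "q")
  ggplot2::ggplot(est, ggplot2::aes(x = .data$value,
                                    colour = .data$model)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(data = qs,
                        ggplot2::aes(xintercept = .data$q,
                                     colour = .data$model),
                        linetype = "dotted", linewidth = 0.3,
                        show.legend = FALSE) +
    ggplot2::labs(x = parameter, y = "density", colour = "model") +
    ggplot2::theme_minimal()
}
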