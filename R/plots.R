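#' Plot experiment accuracies
#'
#' Replicate-mean accuracy (EBV against TBV) by genotyping scenario, faceted
#' by genetic effect, with one line per statistical model.
#'
#' @param object a `pig_experiment`.
#' @param metric which metric to plot (`"accuracy"`, `"slope"`,
#'   `"top1_tbv"`, `"top30_tbv"`).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pig_experiment <- function(object, metric = "accuracy", ...) {
  d <- object$results[object$results$metric == metric, ]
  assert_that(nrow(d) > 0, paste("no rows for metric", metric))
  d <- d |>
    dplyr::group_by(.data$scenario, .data$model, .data$effect) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  scen_order <- c("G_all", "G80_ran", "G_alive", "G_none")
  d$scenario <- factor(d$scenario,
                       levels = intersect(scen_order, unique(d$scenario)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scenario, y = .data$mean,
                                  colour = .data$model,
                                  group = .data$model)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.15, position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3),
                       alpha = 0.5) +
    ggplot2::facet_wrap(~effect) +
    ggplot2::labs(x = "genotyping scenario", y = metric,
                  title = paste0(unique(object$results$trait), ": ", metric,
                                 " by scenario")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed versus predicted survival EBV shrinkage plot
#'
#' Scatter of EBV against TBV for the validation animals of one fitted
#' model, with the identity and regression lines.
#'
#' @param fit a `surv_fit`.
#' @param tbv tibble with `id`, `tbv_a`, `tbv_m`.
#' @param ids validation ids (default: all in the fit).
#' @param effect `"a"`, `"m"`, or `"total"`.
#' @return A ggplot object.
#' @export
plot_ebv_tbv <- function(fit, tbv, ids = NULL, effect = "total") {
  ids <- ids %||% intersect(fit$ebv$id, tbv$id)
  e <- fit$ebv[match(ids, fit$ebv$id), ]
  t <- tbv[match(ids, tbv$id), ]
  d <- tibble::tibble(
    ebv = switch(effect, a = e$ebv_a, m = e$ebv_m, total = e$ebv_total),
    tbv = switch(effect, a = t$tbv_a, m = t$tbv_m,
                 total = t$tbv_a + t$tbv_m)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ebv, y = .data$tbv)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = paste("EBV", effect), y = paste("TBV", effect)) +
    ggplot2::theme_minimal()
}
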