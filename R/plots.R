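# ggplot2 convenience output for the main result types.

#' Fine-grade distribution of Matching Scores
#'
#' @param x An `ms_scored` object or flat data frame with a `score` column.
#' @return A ggplot bar chart of patients per fine score grade.
#' @export
plot_score_distribution <- function(x) {
  tbl <- as_scored_tbl(x)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$fine_grade)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "Matching Score grade", y = "patients") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step curves by score stratum
#'
#' @param km A result of [km_by_stratum()].
#' @param endpoint Axis label, e.g. `"PFS"`.
#' @return A ggplot of the per-stratum survival curves.
#' @export
plot_km <- function(km, endpoint = "survival") {
  df <- purrr::imap_dfr(km$curves, function(cv, g) {
    dplyr::bind_rows(tibble::tibble(time = 0, surv = 1), cv[, c("time", "surv")]) |>
      dplyr::mutate(stratum = g)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = paste(endpoint, "probability"),
                  colour = "score stratum") +
    ggplot2::theme_minimal()
}

#' @describeIn roc_cutoff ROC curve with the selected Youden cutoff marked.
#' @param object An `ms_roc` object.
#' @export
autoplot.ms_roc <- function(object, ...) {
  cv <- dplyr::arrange(object$curve, .data$sensitivity)
  sel <- dplyr::filter(object$curve, .data$cutoff == object$cutoff)
  ggplot2::ggplot(cv, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::geom_point(data = sel, colour = "red") +
    ggplot2::labs(
      title = sprintf("AUC = %.3f; cutoff: score >= %g", object$auc, object$cutoff),
      x = "1 - specificity", y = "sensitivity"
    ) +
    ggplot2::theme_minimal()
}

#' Grade-trend scatter with least-squares line
#'
#' @param trend A result of [grade_trend()].
#' @param metric `"dcr"` or `"pfs_median"`.
#' @return A ggplot of the per-grade outcome against the grade encoding.
#' @export
plot_grade_trend <- function(trend, metric = c("dcr", "pfs_median")) {
  metric <- match.arg(metric)
  by_grade <- attr(trend, "by_grade")
  ycol <- if (metric == "dcr") "dc_rate" else "pfs_median"
  r2 <- trend$r_squared[trend$metric == metric]
  ggplot2::ggplot(by_grade, ggplot2::aes(.data$grade_x, .data[[ycol]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(
      title = sprintf("%s vs score grade (R^2 = %.2f)", metric, r2),
      x = sprintf("grade (%s encoding)", attr(trend, "x_encoding")),
      y = metric
    ) +
    ggplot2::theme_minimal()
}
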