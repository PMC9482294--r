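#' Forest plot of prevalence estimates
#'
#' Draws per-stratum prevalence estimates with their confidence intervals
#' as a standard forest plot, optionally with the pooled summary appended.
#'
#' @param estimates Tibble from [svy_prevalence()] (needs a label column,
#'   `p`, `ci_low`, `ci_high`).
#' @param label Column used for the row labels (default `"country"`).
#' @param pooled Optional [pool_prevalence()] result appended as a summary
#'   row.
#' @param percent Show the x axis in percent (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_forest <- function(estimates, label = "country", pooled = NULL,
                        percent = TRUE) {
  df <- tibble::as_tibble(estimates)
  if (label %not_in% names(df)) abort(sprintf("label column `%s` not found", label))
  df$..lab <- as.character(df[[label]])
  df$..kind <- "stratum"
  if (!is.null(pooled)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      ..lab = sprintf("Pooled (%s)", pooled$method), ..kind = "pooled",
      p = pooled$p_pooled, ci_low = pooled$ci_low, ci_high = pooled$ci_high))
  }
  s <- if (percent) 100 else 1
  df$..lab <- factor(df$..lab, levels = rev(unique(df$..lab)))
  ggplot2::ggplot(df, ggplot2::aes(x = s * .data$p, y = .data$..lab)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = s * .data$ci_low,
                                         xmax = s * .data$ci_high),
                            height = 0.2, linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$..kind), size = 2) +
    ggplot2::scale_shape_manual(values = c(stratum = 15, pooled = 18),
                                guide = "none") +
    ggplot2::labs(x = if (percent) "Prevalence (%)" else "Prevalence",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.svy_decomp <- function(object, ...) {
  df <- tidyr::pivot_longer(object$variables, c("e_pct", "c_pct"),
                            names_to = "component", values_to = "pct")
  df$component <- dplyr::recode(df$component,
                                e_pct = "Characteristics (E)",
                                c_pct = "Coefficients (C)")
  df$variable <- factor(df$variable, levels = rev(unique(object$variables$variable)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$variable,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Share of total gap (%)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.svy_logit <- function(object, conf_level = 0.95, ...) {
  tab <- odds_ratio_table(object, conf_level = conf_level)
  tab$..lab <- factor(paste(tab$variable, tab$level, sep = ": "),
                      levels = rev(paste(tab$variable, tab$level, sep = ": ")))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$aOR, y = .data$..lab)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, linewidth = 0.4) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Adjusted odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
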