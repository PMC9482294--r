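#' Design-weighted prevalence with Taylor-linearized confidence intervals
#'
#' Estimates the weighted proportion of a binary outcome within each cell of
#' the stratifiers in `by` (e.g. country, residence group, or both). The
#' point estimate is the Hajek ratio `sum(w*y)/sum(w)`; its standard error
#' comes from Taylor linearization of the estimating-equation residuals
#' aggregated to PSU totals within design strata; the confidence interval is
#' a Wald interval on the logit scale mapped back to `[0, 1]` (so it can
#' never escape the unit interval). Estimation cells that intersect a design
#' stratum containing a single PSU are flagged (`single_psu > 0`): for those
#' the between-PSU variance of the lone cluster is taken about the grand
#' mean of all PSU totals.
#'
#' @param data Microdata with the outcome, weight, stratum and PSU columns.
#' @param by Character vector of stratifier columns (may be empty for an
#'   overall estimate).
#' @param outcome,weight,stratum,psu Column names.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per non-empty cell: the `by` columns plus
#'   `p`, `se`, `ci_low`, `ci_high`, `n_raw`, `n_weighted`, `n_psu`,
#'   `single_psu`.
#' @examples
#' sim <- simulate_survey(default_scenario(seed = 3, clusters_per_country = 20))
#' svy_prevalence(sim, by = c("country", "group"))
#' @export
svy_prevalence <- function(data, by = character(),
                           outcome = "outcome", weight = "weight",
                           stratum = "stratum", psu = "psu",
                           conf_level = 0.95) {
  used <- c(by, outcome, weight, stratum, psu)
  missing_cols <- used[used %not_in% names(data)]
  if (length(missing_cols) > 0L) {
    abort(paste("column(s) not found:", paste(missing_cols, collapse = ", ")),
          class = "svygap_column_error")
  }
  if (!all(data[[outcome]] %in% c(0, 1))) abort("outcome must be coded 0/1")
  if (any(data[[weight]] <= 0)) abort("weights must be strictly positive")
  z <- qnorm(1 - (1 - conf_level) / 2)
  cells <- if (length(by) == 0L) {
    list(overall = seq_len(nrow(data)))
  } else {
    key <- do.call(paste, c(data[by], sep = "\r"))
    split(seq_len(nrow(data)), key)
  }
  rows <- lapply(cells, function(idx) {
    y <- data[[outcome]][idx]
    w <- data[[weight]][idx]
    st <- as.character(data[[stratum]][idx])
    cl <- paste(st, data[[psu]][idx], sep = "\r")
    p <- sum(w * y) / sum(w)
    # linearized residuals of the ratio estimator
    u <- w * (y - p) / sum(w)
    V <- psu_total_cov(matrix(u, ncol = 1), st, cl)
    se <- sqrt(max(V[1, 1], 0))
    if (p <= 0 || p >= 1 || se == 0) {
      lo <- hi <- p
      if (se > 0) { # non-degenerate p with zero-variance guard unreachable
        lo <- max(0, p - z * se); hi <- min(1, p + z * se)
      }
    } else {
      lse <- se / (p * (1 - p))
      lo <- plogis(qlogis(p) - z * lse)
      hi <- plogis(qlogis(p) + z * lse)
    }
    out <- tibble::tibble(p = p, se = se, ci_low = lo, ci_high = hi,
                          n_raw = length(idx), n_weighted = sum(w),
                          n_psu = attr(V, "n_psu"),
                          single_psu = attr(V, "single_psu"))
    if (length(by) > 0L) {
      lab <- data[idx[1L], by, drop = FALSE]
      out <- dplyr::bind_cols(tibble::as_tibble(lab), out)
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  if (length(by) > 0L) res <- dplyr::arrange(res, dplyr::across(dplyr::all_of(by)))
  if (any(res$single_psu > 0)) {
    warn("some estimation cells contain single-PSU strata; their SEs use grand-mean centering")
  }
  res
}
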