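#' Published example: detailed decomposition of a caesarean-delivery gap
#'
#' Loads the detailed decomposition table packaged with `svygap`: per-term
#' characteristics (`e_coef`, `e_pct`) and coefficients (`c_coef`, `c_pct`)
#' contributions from a published multi-country decomposition of the
#' rural-urban caesarean-delivery disparity among facility births in
#' sub-Saharan Africa, covering 20 categorical maternal/child covariates.
#' Percents are shares of the total gap, so the characteristics and
#' coefficients percents jointly sum to 100. Useful for exercising
#' [aggregate_contributions()] on a realistic published output surface.
#'
#' @return A list with `terms` (tibble of per-term rows) and `totals`
#'   (one-row tibble: total `E`, `C` coefficients and percent shares).
#' @examples
#' ex <- example_decomposition_table()
#' aggregate_contributions(ex$terms, D = ex$totals$e_coef + ex$totals$c_coef)
#' @export
example_decomposition_table <- function() {
  path <- system.file("extdata", "ssa_cesarean_decomposition.csv",
                      package = "svygap", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  totals <- df[df$variable == "total", c("e_coef", "e_pct", "c_coef", "c_pct")]
  terms <- df[df$variable != "total", , drop = FALSE]
  list(terms = terms, totals = totals)
}
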