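#' Variance inflation factors of a categorical design
#'
#' Multicollinearity screen for the regression design: each non-intercept
#' design-matrix column is regressed on all the others (with intercept) and
#' `VIF = 1/(1 - R^2)` is reported, together with the mean/min/max summary
#' conventionally quoted alongside. Computed on the unweighted design, as in
#' standard post-estimation collinearity checks. A rank-deficient design is
#' an error naming the aliased columns.
#'
#' @param data Microdata table.
#' @param terms Character vector of categorical covariate names (treatment
#'   coded against each term's reference level; see [design_spec()]).
#' @param refs Optional named vector of reference levels.
#' @return A tibble with columns `term`, `variable`, `level`, `vif`, and
#'   attribute `summary` (tibble of `mean`, `min`, `max`).
#' @export
svy_vif <- function(data, terms, refs = NULL) {
  spec <- design_spec(terms, refs = refs)
  used <- terms[terms %not_in% names(data)]
  if (length(used) > 0L) {
    abort(paste("column(s) not found:", paste(used, collapse = ", ")),
          class = "svygap_column_error")
  }
  # build only the covariate part of the design
  df <- data[, terms, drop = FALSE]
  df$outcome <- 0; df$weight <- 1; df$stratum <- "s"; df$psu <- as.character(seq_len(nrow(df)))
  bd <- build_design(df, spec)
  X <- bd$X[, -1L, drop = FALSE]
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    abort(paste("constant design column(s):",
                paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  qr_full <- qr(cbind(1, X))
  if (qr_full$rank < ncol(X) + 1L) {
    keep <- qr_full$pivot[seq_len(qr_full$rank)]
    aliased <- setdiff(seq_len(ncol(X) + 1L), keep) - 1L
    abort(paste("rank-deficient design; aliased column(s):",
                paste(colnames(X)[aliased], collapse = ", ")),
          class = "svygap_rank_error")
  }
  Rcor <- stats::cor(X)
  vifs <- diag(solve(Rcor))
  info <- bd$info[match(colnames(X), bd$info$column), ]
  out <- tibble::tibble(term = colnames(X), variable = info$variable,
                        level = info$level, vif = as.numeric(vifs))
  attr(out, "summary") <- tibble::tibble(mean = mean(out$vif), min = min(out$vif),
                                         max = max(out$vif))
  out
}
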