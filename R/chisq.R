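#' Design-adjusted chi-square test of association with the outcome
#'
#' Tests independence between a categorical covariate and the binary outcome
#' under the complex sampling design, using the Rao-Scott second-order
#' (Satterthwaite) correction: the Pearson statistic is computed from the
#' design-weighted cell proportions, and its null distribution is corrected
#' by the eigenvalues of the generalized-design-effect matrix estimated by
#' Taylor linearization over PSUs within strata.
#'
#' With equal weights, one PSU per row and a single stratum the estimated
#' design-effect eigenvalues are exactly 1 (the SRS covariance is evaluated
#' with the same `n/(n-1)` small-sample factor as the linearized one), so
#' the statistic and p-value reduce exactly to the classical Pearson test.
#'
#' @param data Microdata table.
#' @param covariate Name of the categorical covariate column.
#' @param outcome,weight,stratum,psu Column names.
#' @return A one-row tibble: `covariate`, `statistic` (Pearson, weighted),
#'   `statistic_adj` (second-order corrected), `df`, `df_adjusted`,
#'   `design_effect` (mean eigenvalue), `p_value`, `correction`.
#' @export
svy_chisq <- function(data, covariate,
                      outcome = "outcome", weight = "weight",
                      stratum = "stratum", psu = "psu") {
  used <- c(covariate, outcome, weight, stratum, psu)
  missing_cols <- used[used %not_in% names(data)]
  if (length(missing_cols) > 0L) {
    abort(paste("column(s) not found:", paste(missing_cols, collapse = ", ")),
          class = "svygap_column_error")
  }
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) abort("outcome must be coded 0/1")
  v <- as.character(data[[covariate]])
  lev <- sort(unique(v))
  R <- length(lev)
  if (R < 2L) abort("degenerate table: covariate has fewer than 2 observed levels")
  if (length(unique(y)) < 2L) abort("degenerate table: outcome is constant")
  w <- data[[weight]]
  n <- length(y)
  st <- as.character(data[[stratum]])
  cl <- paste(st, data[[psu]], sep = "\r")

  # joint indicator matrix, columns ordered (level x outcome): R x 2 cells
  D <- matrix(0, n, 2L * R)
  for (r in seq_len(R)) {
    D[, r] <- as.numeric(v == lev[r] & y == 1)
    D[, R + r] <- as.numeric(v == lev[r] & y == 0)
  }
  phat <- as.numeric(crossprod(D, w)) / sum(w)
  p_r <- phat[seq_len(R)] + phat[R + seq_len(R)]   # row margins
  p_1 <- sum(phat[seq_len(R)])                     # outcome margin

  # Pearson X^2 on weighted proportions with nominal n
  e <- c(p_r * p_1, p_r * (1 - p_1))
  X2 <- n * sum((phat - e)^2 / e)

  # independence contrasts h_r = p_{r1} - p_r * p_1, r = 1..R-1 (full rank)
  H <- matrix(0, R - 1L, 2L * R)
  for (r in seq_len(R - 1L)) {
    H[r, r] <- 1 - p_1 - p_r[r]
    H[r, R + r] <- -p_1
    H[r, setdiff(seq_len(R), r)] <- -p_r[r]
  }
  # linearized design covariance of phat, PSU totals within strata
  U <- sweep(D, 2L, phat) * (w / sum(w))
  Vd <- psu_total_cov(U, st, cl)
  # multinomial covariance with the matching small-sample factor
  V0 <- (diag(phat) - tcrossprod(phat)) / (n - 1)
  Vh_d <- H %*% Vd %*% t(H)
  Vh_0 <- H %*% V0 %*% t(H)
  lam <- Re(eigen(solve(Vh_0, Vh_d), only.values = TRUE)$values)
  lam <- pmax(lam, 0)
  d <- R - 1L
  delta_bar <- mean(lam)
  a2 <- if (delta_bar > 0) sum((lam - delta_bar)^2) / (d * delta_bar^2) else 0
  stat_adj <- X2 / (delta_bar * (1 + a2))
  df_adj <- d / (1 + a2)
  tibble::tibble(
    covariate = covariate,
    statistic = X2,
    statistic_adj = stat_adj,
    df = d,
    df_adjusted = df_adj,
    design_effect = delta_bar,
    p_value = pchisq(stat_adj, df = df_adj, lower.tail = FALSE),
    correction = "Rao-Scott second order"
  )
}
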