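#' Survey-weighted binary logistic regression
#'
#' Fits a binary logit by pseudo-maximum-likelihood with the sampling
#' weights as estimating weights: weighted IRLS (via [stats::glm.fit()])
#' followed by Newton polishing with step-halving until the weighted score
#' norm falls below `tol` (default `1e-8`, at most 100 extra iterations).
#' The covariance is a design-based sandwich with PSU-aggregated score
#' contributions centered within design strata — the Taylor-linearization
#' estimator appropriate for stratified two-stage samples — so inference is
#' robust to intra-cluster correlation. At convergence the canonical-link
#' score identity holds: the weighted mean of fitted probabilities equals
#' the weighted outcome prevalence.
#'
#' Quasi-complete separation is detected as any coefficient exceeding 15 in
#' absolute value and raised as an error naming the term; `firth = TRUE`
#' switches to Jeffreys-prior (Firth) penalized scoring, which keeps small
#' or separated fixtures finite (the penalty uses the weighted information).
#'
#' @param data Microdata table.
#' @param terms Categorical covariates, in the fixed order shared across
#'   group fits.
#' @param outcome,refs,group,weight,stratum,psu See [design_spec()].
#' @param subset Optional value of the `group` column to fit on (e.g.
#'   `"rural"`); `NULL` fits all rows.
#' @param firth Use Firth-penalized scoring (default `FALSE`).
#' @param tol,maxit Score-norm convergence tolerance and Newton iteration cap.
#' @return An object of class `svy_logit`: coefficients (`beta`),
#'   cluster-robust covariance (`vcov`), design-weighted design-column means
#'   (`xbar`, with `xbar_full` covering reference levels too), sample sizes,
#'   convergence metadata, and the design bundle needed for prediction and
#'   decomposition. Methods: [tidy()], [glance()], [odds_ratio_table()],
#'   [predict_mean_prob()].
#' @examples
#' sim <- simulate_survey(default_scenario(seed = 9, clusters_per_country = 40))
#' fit <- svy_logit(sim, terms = c("wealth", "anc"), subset = "rural")
#' tidy(fit)
#' @export
svy_logit <- function(data, terms,
                      outcome = "outcome", refs = NULL, group = "group",
                      weight = "weight", stratum = "stratum", psu = "psu",
                      subset = NULL, firth = FALSE,
                      tol = 1e-8, maxit = 100L) {
  spec <- design_spec(terms, outcome = outcome, refs = refs, group = group,
                      weight = weight, stratum = stratum, psu = psu)
  if (!is.null(subset)) {
    if (group %not_in% names(data)) {
      abort(sprintf("group column `%s` not found", group), class = "svygap_column_error")
    }
    data <- data[data[[group]] == subset, , drop = FALSE]
  }
  if (nrow(data) == 0L) abort("subset is empty")
  bd <- build_design(data, spec)
  if (length(unique(bd$y)) < 2L) {
    abort("outcome has a single class in this subset; cannot fit a logit")
  }
  fit <- fit_pml(bd$X, bd$y, bd$w, firth = firth, tol = tol, maxit = maxit)
  mu <- fit$mu
  # stratified cluster-robust (sandwich) covariance
  S <- bd$X * (bd$w * (bd$y - mu))
  meat <- psu_total_cov(S, bd$stratum, bd$psu)
  vc <- fit$bread %*% meat %*% fit$bread
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(colnames(bd$X), colnames(bd$X))
  structure(
    list(beta = fit$beta,
         vcov = vc,
         xbar = wcolmeans(bd$X, bd$w),
         xbar_full = setNames(wcolmeans(bd$X_full, bd$w), colnames(bd$X_full)),
         beta_full = beta_to_full(fit$beta, bd$info),
         info = bd$info,
         n_raw = length(bd$y),
         n_weighted = sum(bd$w),
         n_psu = attr(meat, "n_psu"),
         converged = fit$converged,
         iterations = fit$iterations,
         score_norm = fit$score_norm,
         loglik_pseudo = sum(bd$w * (bd$y * log(mu) + (1 - bd$y) * log1p(-mu))),
         p_bar = wmean(bd$y, bd$w),
         firth = firth,
         design = bd,
         subset = subset),
    class = "svy_logit"
  )
}

# Weighted IRLS + Newton polish with step-halving. Errors on rank
# deficiency (naming aliased terms) and on separation (|beta| > 15, unless
# Firth-penalized).
fit_pml <- function(X, y, w, firth = FALSE, tol = 1e-8, maxit = 100L) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    abort(paste("rank-deficient design; aliased term(s):",
                paste(aliased, collapse = ", ")),
          class = "svygap_rank_error")
  }
  g0 <- suppressWarnings(stats::glm.fit(X, y, weights = w,
                                        family = stats::quasibinomial()))
  beta <- g0$coefficients
  pen_ll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    ll <- sum(w * (y * eta - log1p(exp(eta))))
    if (firth) {
      Wv <- w * mu * (1 - mu)
      ll <- ll + 0.5 * determinant(crossprod(X, X * Wv), logarithm = TRUE)$modulus
    }
    ll
  }
  score_hess <- function(beta) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    Wv <- w * mu * (1 - mu)
    Hm <- crossprod(X, X * Wv)
    sc <- as.numeric(crossprod(X, w * (y - mu)))
    if (firth) {
      Hi <- solve(Hm)
      h <- rowSums((X %*% Hi) * (X * Wv))   # generalized leverages
      sc <- sc + as.numeric(crossprod(X, h * (0.5 - mu)))
    }
    list(score = sc, H = Hm, mu = mu)
  }
  ll <- pen_ll(beta)
  it <- 0L
  sh <- score_hess(beta)
  while (max(abs(sh$score)) >= tol && it < maxit) {
    step <- solve(sh$H, sh$score)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta + lambda * step
    ll <- pen_ll(beta)
    sh <- score_hess(beta)
    it <- it + 1L
  }
  if (!firth && any(abs(beta) > 15)) {
    worst <- colnames(X)[which.max(abs(beta))]
    abort(sprintf(
      "separation detected: |coefficient| > 15 for term `%s`; consider firth = TRUE",
      worst), class = "svygap_separation_error")
  }
  converged <- max(abs(sh$score)) < tol
  if (!converged) {
    abort(sprintf("logit did not converge: score norm %.3g after %d iterations",
                  max(abs(sh$score)), it), class = "svygap_convergence_error")
  }
  list(beta = setNames(beta, colnames(X)), mu = sh$mu,
       bread = solve(sh$H), converged = converged, iterations = it,
       score_norm = max(abs(sh$score)))
}

#' @export
print.svy_logit <- function(x, ...) {
  cat(sprintf("Survey-weighted logit%s: %d rows (%d PSUs), %d terms, pseudo-logLik %.2f\n",
              if (is.null(x$subset)) "" else paste0(" [", x$subset, "]"),
              x$n_raw, x$n_psu, length(x$beta), x$loglik_pseudo))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.svy_logit <- function(x, conf_level = 0.95, exponentiate = FALSE, ...) {
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- x$beta
  lo <- est - z * se
  hi <- est + z * se
  stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  p <- 2 * pnorm(-abs(stat))
  if (exponentiate) { est <- exp(est); lo <- exp(lo); hi <- exp(hi) }
  tibble::tibble(term = names(x$beta), estimate = unname(est),
                 std.error = unname(se), statistic = unname(stat),
                 p.value = unname(p), conf.low = unname(lo),
                 conf.high = unname(hi))
}

#' @export
glance.svy_logit <- function(x, ...) {
  tibble::tibble(n_raw = x$n_raw, n_weighted = x$n_weighted, n_psu = x$n_psu,
                 n_terms = length(x$beta), logLik_pseudo = x$loglik_pseudo,
                 converged = x$converged, iterations = x$iterations,
                 score_norm = x$score_norm)
}

#' Adjusted odds-ratio table
#'
#' Exponentiates the fitted log-odds coefficients into adjusted odds ratios
#' with Wald confidence intervals `exp(beta +/- z * se)` and significance
#' stars (`*` p<0.05, `**` p<0.01, `***` p<0.001, two-sided normal
#' reference). Reference categories are listed explicitly as `1.00 [1.00,
#' 1.00]` so the table reads like a publication panel.
#'
#' @param fit A converged [svy_logit()] fit.
#' @param conf_level Confidence level.
#' @return A tibble: `term`, `variable`, `level`, `reference`, `aOR`,
#'   `ci_low`, `ci_high`, `p_value`, `stars`.
#' @export
odds_ratio_table <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "svy_logit"))
  if (!fit$converged) abort("fit did not converge")
  td <- tidy(fit, conf_level = conf_level)
  info <- fit$info[fit$info$variable != "(Intercept)", ]
  rows <- lapply(seq_len(nrow(info)), function(i) {
    if (info$is_ref[i]) {
      tibble::tibble(term = info$column[i], variable = info$variable[i],
                     level = info$level[i], reference = TRUE,
                     aOR = 1, ci_low = 1, ci_high = 1,
                     p_value = NA_real_, stars = "")
    } else {
      r <- td[td$term == info$treatment_column[i], ]
      tibble::tibble(term = info$column[i], variable = info$variable[i],
                     level = info$level[i], reference = FALSE,
                     aOR = exp(r$estimate), ci_low = exp(r$conf.low),
                     ci_high = exp(r$conf.high), p_value = r$p.value,
                     stars = stars_for(r$p.value))
    }
  })
  dplyr::bind_rows(rows)
}

stars_for <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' Design-weighted mean predicted probability at given coefficients
#'
#' Evaluates the weighted mean of `plogis(x_i' at_beta)` over the rows the
#' fit was estimated on (or over `newdata`, rebuilt with the fit's level
#' coding). This is the counterfactual building block of the non-linear
#' decomposition: the reference group's composition evaluated at the
#' comparison group's coefficients.
#'
#' @param fit A [svy_logit()] fit.
#' @param newdata Optional microdata table with the fit's columns.
#' @param at_beta Coefficient vector in the fit's term order (defaults to
#'   the fit's own coefficients).
#' @return A single probability.
#' @export
predict_mean_prob <- function(fit, newdata = NULL, at_beta = fit$beta) {
  stopifnot(inherits(fit, "svy_logit"))
  if (length(at_beta) != length(fit$beta)) {
    abort("`at_beta` does not match the fit's design columns")
  }
  if (is.null(newdata)) {
    X <- fit$design$X
    w <- fit$design$w
  } else {
    spec2 <- fit$design$spec
    # pin level order (hence reference) to the fit's coding
    refs <- vapply(fit$design$levels, `[`, character(1), 1L)
    spec2$refs <- refs
    bd <- build_design(newdata, spec2)
    if (!identical(colnames(bd$X), names(fit$beta))) {
      abort("`newdata` design columns do not match the fit")
    }
    X <- bd$X
    w <- bd$w
  }
  wmean(plogis(as.numeric(X %*% at_beta)), w)
}
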