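# Core arithmetic of the non-linear (logit) gap decomposition.
#
# Totals: with A the comparison group (urban) and B the reference (rural),
#   D = Pbar_A - Pbar_B          observed (weighted) outcome gap
#   Q = mean_B F(x' beta_A)      B's composition at A's coefficients
#   E = Pbar_A - Q               characteristics (endowment) component
#   C = Q - Pbar_B               coefficients component
# Detailed allocation uses first-moment (means-based) weight shares:
#   e_k = E * (xbar_Ak - xbar_Bk) beta_Ak / sum_l (xbar_Al - xbar_Bl) beta_Al
#   c_k = C * xbar_Bk (beta_Ak - beta_Bk) / sum_l xbar_Bl (beta_Al - beta_Bl)
# The intercept has no endowment difference (xbar = 1 in both groups) so it
# participates only in the C sums. Detailed shares are computed on the
# full-dummy representation; with `normalize = TRUE` each categorical block
# is first centered (deviation coding: level effects sum to zero, the shift
# absorbed into the intercept), which removes the dependence of the
# detailed rows on the fitting reference category while leaving the linear
# predictor — hence D, E, C — unchanged.

normalize_beta_full <- function(beta_full, info) {
  out <- beta_full
  shift <- 0
  for (v in setdiff(unique(info$variable), "(Intercept)")) {
    cols <- info$column[info$variable == v]
    m <- mean(beta_full[cols])
    out[cols] <- beta_full[cols] - m
    shift <- shift + m
  }
  out[["(Intercept)"]] <- out[["(Intercept)"]] + shift
  out
}

decomp_core <- function(beta_full_A, beta_full_B, xbar_A, xbar_B,
                        p_bar_A, p_bar_B, q, info, normalize = TRUE) {
  if (normalize) {
    beta_full_A <- normalize_beta_full(beta_full_A, info)
    beta_full_B <- normalize_beta_full(beta_full_B, info)
  }
  D <- p_bar_A - p_bar_B
  E <- p_bar_A - q
  C <- q - p_bar_B
  is_int <- info$variable == "(Intercept)"
  num_e <- (xbar_A - xbar_B) * beta_full_A
  num_e[is_int] <- 0                       # constant: no endowment difference
  num_c <- xbar_B * (beta_full_A - beta_full_B)
  den_e <- sum(num_e)
  den_c <- sum(num_c)
  if (abs(E) > 1e-12 && abs(den_e) < 1e-12) {
    abort(paste("vanishing endowment weight denominator:",
                "detailed E shares are unidentified; use bootstrap-only totals"),
          class = "svygap_denominator_error")
  }
  e_k <- if (abs(den_e) < 1e-12) rep(0, length(num_e)) else E * num_e / den_e
  c_k <- if (abs(den_c) < 1e-12) rep(0, length(num_c)) else C * num_c / den_c
  terms <- tibble::tibble(
    term = info$column, variable = info$variable, level = info$level,
    e_k = unname(e_k), c_k = unname(c_k),
    e_pct = if (D != 0) 100 * unname(e_k) / D else NA_real_,
    c_pct = if (D != 0) 100 * unname(c_k) / D else NA_real_
  )
  list(D = D, E = E, C = C, q = q, terms = terms, normalized = normalize)
}

#' Decompose a two-group disparity in a binary outcome
#'
#' Partitions the urban-rural (comparison-reference) gap in the
#' design-weighted outcome prevalence into a characteristics (endowment)
#' component `E` — what the gap would close by if the reference group had
#' the comparison group's covariate composition, evaluated at the
#' comparison group's logit coefficients — and a coefficients component `C`
#' (the remainder, including the intercept), with per-category detailed
#' contributions allocated by first-moment weight shares and, by default,
#' deviation-coding normalization over each categorical block. Uncertainty
#' for all components comes from a stratified PSU bootstrap.
#'
#' Because both group models are canonical-link logits with intercepts, the
#' decomposed total `D` equals the observed weighted prevalence gap, not a
#' model artifact, and `E + C = D`, `sum(e_k) = E`, `sum(c_k) = C` hold to
#' machine precision by construction.
#'
#' @param data Microdata with both groups.
#' @param terms Categorical covariates (shared order for both fits).
#' @param comparison,reference Values of `group` naming the comparison
#'   (advantaged) and reference groups; the conventional choice weights the
#'   endowment term by the comparison group's coefficients.
#' @param outcome,refs,group,weight,stratum,psu See [design_spec()].
#' @param normalize Deviation-coding normalization of detailed rows
#'   (default `TRUE`).
#' @param boot Number of bootstrap replicates (0 = point estimates only;
#'   at least 50 when positive).
#' @param seed Integer seed, required when `boot > 0`.
#' @param firth Passed to the group fits.
#' @return An object of class `svy_decomp`: totals `D`, `E`, `C`, tibbles
#'   `terms` (per term:level `e_k`, `c_k`, percents and, with bootstrap,
#'   `se_e`, `se_c`, `p_e`, `p_c`) and `variables` (per-covariate percent
#'   sums), the two group fits, and bootstrap metadata. Methods: [tidy()],
#'   [glance()], [autoplot()][ggplot2::autoplot()].
#' @examples
#' sim <- simulate_survey(default_scenario(seed = 5, clusters_per_country = 40))
#' dec <- svy_decompose(sim, terms = c("wealth", "anc", "insurance"))
#' glance(dec)
#' @export
svy_decompose <- function(data, terms,
                          comparison = "urban", reference = "rural",
                          outcome = "outcome", refs = NULL, group = "group",
                          weight = "weight", stratum = "stratum", psu = "psu",
                          normalize = TRUE, boot = 0L, seed = NULL,
                          firth = FALSE) {
  if (boot > 0L) {
    if (boot < 50L) abort("`boot` must be at least 50 replicates (or 0)")
    if (is.null(seed)) abort("`seed` is required when boot > 0")
  }
  fit_A <- svy_logit(data, terms, outcome = outcome, refs = refs, group = group,
                     weight = weight, stratum = stratum, psu = psu,
                     subset = comparison, firth = firth)
  fit_B <- svy_logit(data, terms, outcome = outcome, refs = refs, group = group,
                     weight = weight, stratum = stratum, psu = psu,
                     subset = reference, firth = firth)
  res <- decompose_fits(fit_A, fit_B, normalize = normalize)
  res$comparison <- comparison
  res$reference <- reference
  res$fit_comparison <- fit_A
  res$fit_reference <- fit_B
  res$n_boot <- 0L
  if (boot > 0L) {
    bt <- bootstrap_decomposition(data, terms, comparison, reference,
                                  outcome = outcome, refs = refs, group = group,
                                  weight = weight, stratum = stratum, psu = psu,
                                  normalize = normalize, B = boot, seed = seed,
                                  firth = firth)
    res$n_boot <- bt$n_ok
    res$n_boot_failed <- bt$n_failed
    res$boot_se <- bt$se_totals
    res$boot_mean <- bt$mean_totals
    res$terms <- dplyr::left_join(res$terms, bt$se_terms, by = "term")
    # normal-approximation p-values on the bootstrap bias-corrected
    # estimate 2*theta_hat - mean(replicates): the curvature bias of the
    # non-linear components re-occurs in each replicate, so subtracting the
    # replicate mean removes it from the test statistic
    res$terms$p_e <- 2 * pnorm(-abs((2 * res$terms$e_k - res$terms$mean_e) /
                                      res$terms$se_e))
    res$terms$p_c <- 2 * pnorm(-abs((2 * res$terms$c_k - res$terms$mean_c) /
                                      res$terms$se_c))
  }
  class(res) <- "svy_decomp"
  res$variables <- aggregate_contributions(res)
  res
}

# Decomposition from two fitted group models (must share the design).
# `link` switches to the identity-link linear-probability variant used as
# an internal closed-form oracle; not part of the user-facing analysis API.
decompose_fits <- function(fit_A, fit_B, normalize = TRUE, link = "logit") {
  if (!identical(names(fit_A$beta), names(fit_B$beta)) ||
      !identical(fit_A$info$column, fit_B$info$column)) {
    abort("the two fits do not share an identical design", class = "svygap_design_error")
  }
  q <- if (link == "identity") {
    sum(fit_B$xbar * fit_A$beta)
  } else {
    wmean(plogis(as.numeric(fit_B$design$X %*% fit_A$beta)), fit_B$design$w)
  }
  p_bar_A <- if (link == "identity") sum(fit_A$xbar * fit_A$beta) else fit_A$p_bar
  p_bar_B <- if (link == "identity") sum(fit_B$xbar * fit_B$beta) else fit_B$p_bar
  decomp_core(fit_A$beta_full, fit_B$beta_full,
              fit_A$xbar_full, fit_B$xbar_full,
              p_bar_A = p_bar_A, p_bar_B = p_bar_B, q = q,
              info = fit_A$info, normalize = normalize)
}

# Weighted least-squares linear probability fit sharing the svy_logit
# surface needed by decompose_fits(); internal oracle only.
fit_lpm <- function(data, terms, subset = NULL, outcome = "outcome",
                    group = "group", weight = "weight",
                    stratum = "stratum", psu = "psu", refs = NULL) {
  spec <- design_spec(terms, outcome = outcome, refs = refs, group = group,
                      weight = weight, stratum = stratum, psu = psu)
  if (!is.null(subset)) data <- data[data[[group]] == subset, , drop = FALSE]
  bd <- build_design(data, spec)
  beta <- setNames(as.numeric(solve(crossprod(bd$X, bd$X * bd$w),
                                    crossprod(bd$X, bd$w * bd$y))),
                   colnames(bd$X))
  list(beta = beta, beta_full = beta_to_full(beta, bd$info),
       xbar = wcolmeans(bd$X, bd$w),
       xbar_full = setNames(wcolmeans(bd$X_full, bd$w), colnames(bd$X_full)),
       info = bd$info, design = bd, p_bar = wmean(bd$y, bd$w))
}

#' Re-express a fitted logit in deviation (effects) coding
#'
#' Centers each categorical block of the full-dummy coefficient vector so
#' its level effects sum to zero, absorbing the shift into the intercept.
#' The linear predictor — and therefore every fitted probability and the
#' decomposition totals — is unchanged; only the allocation of detailed
#' contributions across levels is affected. [svy_decompose()] applies this
#' internally when `normalize = TRUE`.
#'
#' @param fit A [svy_logit()] fit (or the `fit_lpm` oracle analogue).
#' @return The fit with `beta_full` replaced by its deviation-coded form.
#' @export
normalize_coding <- function(fit) {
  fit$beta_full <- normalize_beta_full(fit$beta_full, fit$info)
  fit
}

#' Aggregate detailed contributions to the variable level
#'
#' Sums the per-category detailed contributions of a decomposition into one
#' row per covariate — the form in which explained shares are usually
#' quoted ("wealth explains 39% of the gap"). When coefficient columns
#' (`e_k`, `c_k`) and the total gap are available, variable percents are
#' recomputed from the coefficient sums (avoiding accumulation of per-row
#' rounding when the input is a printed table); otherwise the per-row
#' percents are summed directly.
#'
#' @param x A `svy_decomp`, or a data frame of detailed rows with a
#'   `variable` column and `e_pct`/`c_pct` (optionally `e_k`/`c_k`).
#' @param mapping Optional named character vector mapping term labels
#'   (values of `variable`, or `term`) to coarser variable groups; every
#'   non-intercept term must be covered.
#' @param D Total gap on the probability scale; needed only to convert
#'   coefficient sums to percents for plain data-frame input (defaults to
#'   `sum(e_k) + sum(c_k)` over all rows including the intercept).
#' @return A tibble: `variable`, `e_sum`, `c_sum` (when available),
#'   `e_pct`, `c_pct`, `total_pct`.
#' @export
aggregate_contributions <- function(x, mapping = NULL, D = NULL) {
  df <- if (inherits(x, "svy_decomp")) x$terms else tibble::as_tibble(x)
  if ("variable" %not_in% names(df)) abort("input needs a `variable` column")
  if ("e_k" %not_in% names(df) && "e_coef" %in% names(df)) {
    df <- dplyr::rename(df, e_k = "e_coef", c_k = "c_coef")
  }
  has_coef <- all(c("e_k", "c_k") %in% names(df))
  if (inherits(x, "svy_decomp")) D <- x$D
  if (has_coef && is.null(D)) D <- sum(df$e_k) + sum(df$c_k)
  df <- df[df$variable != "(Intercept)", , drop = FALSE]
  key <- df$variable
  if (!is.null(mapping)) {
    from <- if (all(key %in% names(mapping))) key else df$term
    unmapped <- unique(from[from %not_in% names(mapping)])
    if (length(unmapped) > 0L) {
      abort(paste("unmapped term(s):", paste(unmapped, collapse = ", ")))
    }
    key <- unname(mapping[from])
  }
  df$`..var` <- factor(key, levels = unique(key))
  out <- dplyr::summarise(
    dplyr::group_by(df, variable = .data$`..var`),
    e_sum = if (has_coef) sum(.data$e_k) else NA_real_,
    c_sum = if (has_coef) sum(.data$c_k) else NA_real_,
    e_pct = if (has_coef) 100 * sum(.data$e_k) / D else sum(.data$e_pct),
    c_pct = if (has_coef) 100 * sum(.data$c_k) / D else sum(.data$c_pct),
    .groups = "drop"
  )
  out$variable <- as.character(out$variable)
  out$total_pct <- out$e_pct + out$c_pct
  if (!has_coef) out$e_sum <- out$c_sum <- NULL
  out
}

#' @export
print.svy_decomp <- function(x, ...) {
  cat(sprintf("Two-group gap decomposition (%s vs %s)\n",
              x$comparison %||% "A", x$reference %||% "B"))
  cat(sprintf("  D = %.5f  E = %.5f (%.2f%%)  C = %.5f (%.2f%%)%s\n",
              x$D, x$E, 100 * x$E / x$D, x$C, 100 * x$C / x$D,
              if ((x$n_boot %||% 0L) > 0L) sprintf("  [%d bootstrap replicates]", x$n_boot) else ""))
  print(x$variables, ...)
  invisible(x)
}

#' @export
tidy.svy_decomp <- function(x, level = c("term", "variable"), ...) {
  level <- match.arg(level)
  if (level == "term") x$terms else x$variables
}

#' @export
glance.svy_decomp <- function(x, ...) {
  out <- tibble::tibble(D = x$D, E = x$E, C = x$C,
                        e_pct = 100 * x$E / x$D, c_pct = 100 * x$C / x$D,
                        normalized = x$normalized, n_boot = x$n_boot %||% 0L)
  if (!is.null(x$boot_se)) {
    out$se_D <- x$boot_se[["D"]]
    out$se_E <- x$boot_se[["E"]]
    out$se_C <- x$boot_se[["C"]]
    out$p_E <- 2 * pnorm(-abs((2 * x$E - x$boot_mean[["E"]]) / out$se_E))
    out$p_C <- 2 * pnorm(-abs((2 * x$C - x$boot_mean[["C"]]) / out$se_C))
  }
  out
}

# One bootstrap-replicate decomposition on a precomputed design bundle:
# refit both groups by PML on the resampled rows and rerun the core
# arithmetic. No covariance work — only the point decomposition is needed
# per replicate.
replicate_decomp <- function(bd, rows_A, rows_B, normalize, firth) {
  fit_g <- function(rows) {
    X <- bd$X[rows, , drop = FALSE]
    y <- bd$y[rows]
    w <- bd$w[rows]
    if (length(unique(y)) < 2L) abort("one-class outcome in replicate")
    f <- fit_pml(X, y, w, firth = firth)
    beta_full <- beta_to_full(f$beta, bd$info)
    list(beta = f$beta, beta_full = beta_full,
         xbar_full = wcolmeans(bd$X_full[rows, , drop = FALSE], w),
         p_bar = wmean(y, w), X = X, w = w)
  }
  fA <- fit_g(rows_A)
  fB <- fit_g(rows_B)
  q <- wmean(plogis(as.numeric(fB$X %*% fA$beta)), fB$w)
  decomp_core(fA$beta_full, fB$beta_full, fA$xbar_full, fB$xbar_full,
              p_bar_A = fA$p_bar, p_bar_B = fB$p_bar, q = q,
              info = bd$info, normalize = normalize)
}

# Stratified PSU bootstrap: resample n_h PSUs with replacement within each
# design stratum, refit both groups, re-decompose. The design matrix is
# built once; replicates only index rows. Replicates that fail
# (non-convergence, separation, lost design columns) are dropped and
# counted; more than 20% failures is an error.
bootstrap_decomposition <- function(data, terms, comparison, reference,
                                    outcome, refs, group, weight, stratum, psu,
                                    normalize, B, seed, firth = FALSE) {
  spec <- design_spec(terms, outcome = outcome, refs = refs, group = group,
                      weight = weight, stratum = stratum, psu = psu)
  bd <- build_design(data, spec, need_group = TRUE)
  psu_rows <- split(seq_len(nrow(data)), bd$psu)
  psu_stratum <- vapply(psu_rows, function(ix) bd$stratum[ix[1L]], character(1))
  strata <- split(names(psu_rows), psu_stratum)
  is_A <- bd$group == comparison
  is_B <- bd$group == reference
  draws <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      take <- unlist(lapply(strata, function(ids) {
        ids[sample.int(length(ids), length(ids), replace = TRUE)]
      }), use.names = FALSE)
      idx <- unlist(psu_rows[take], use.names = FALSE)
      tryCatch({
        r <- replicate_decomp(bd, idx[is_A[idx]], idx[is_B[idx]],
                              normalize = normalize, firth = firth)
        c(D = r$D, E = r$E, C = r$C,
          setNames(r$terms$e_k, paste0("e|", r$terms$term)),
          setNames(r$terms$c_k, paste0("c|", r$terms$term)))
      }, error = function(e) NULL)
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  n_ok <- sum(ok)
  if (n_ok < 0.8 * B) {
    abort(sprintf(
      "%d of %d bootstrap replicates failed; consider a simpler model",
      B - n_ok, B), class = "svygap_bootstrap_error")
  }
  M <- do.call(rbind, draws[ok])
  ses <- apply(M, 2L, sd)
  mns <- colMeans(M)
  term_names <- sub("^e\\|", "", grep("^e\\|", colnames(M), value = TRUE))
  list(
    n_ok = n_ok, n_failed = B - n_ok,
    se_totals = ses[c("D", "E", "C")],
    mean_totals = mns[c("D", "E", "C")],
    se_terms = tibble::tibble(term = term_names,
                              se_e = unname(ses[paste0("e|", term_names)]),
                              se_c = unname(ses[paste0("c|", term_names)]),
                              mean_e = unname(mns[paste0("e|", term_names)]),
                              mean_c = unname(mns[paste0("c|", term_names)]))
  )
}
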