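#' Random-effects pooling of prevalence estimates
#'
#' Pools per-country prevalence estimates by DerSimonian-Laird
#' inverse-variance random-effects meta-analysis on the proportion scale
#' (the estimator behind the usual forest-plot summary diamond), via
#' [metafor::rma()]. The between-country variance `tau2` is floored at 0 by
#' the DL moment estimator itself. Estimates with a zero standard error
#' (degenerate cells) enter with the configured minimum variance `min_var`
#' so they cannot receive infinite weight.
#'
#' @param estimates A tibble of per-stratum estimates as returned by
#'   [svy_prevalence()] (needs columns `p` and `se`; at least 2 rows).
#' @param min_var Minimum sampling variance substituted for `se^2 = 0`
#'   (default `1e-6` on the proportion scale).
#' @param conf_level Confidence level.
#' @return An object of class `svygap_pooled`: a list with `p_pooled`,
#'   `ci_low`, `ci_high`, `se`, `tau2`, `q`, `method`, and the input rows as
#'   `per_stratum`. Use [generics::tidy()] for the per-stratum rows and
#'   [generics::glance()] for the pooled summary.
#' @export
pool_prevalence <- function(estimates, min_var = 1e-6, conf_level = 0.95) {
  if (!all(c("p", "se") %in% names(estimates))) {
    abort("`estimates` needs columns `p` and `se` (see svy_prevalence())")
  }
  if (nrow(estimates) < 2L) abort("need at least 2 estimates to pool")
  if (any(!is.finite(estimates$se))) abort("all standard errors must be finite")
  vi <- pmax(estimates$se^2, min_var)
  fit <- metafor::rma(yi = estimates$p, vi = vi, method = "DL",
                      level = conf_level * 100)
  structure(
    list(p_pooled = as.numeric(fit$beta), se = fit$se,
         ci_low = fit$ci.lb, ci_high = fit$ci.ub,
         tau2 = max(fit$tau2, 0), q = fit$QE, q_p_value = fit$QEp,
         method = "DerSimonian-Laird", per_stratum = tibble::as_tibble(estimates)),
    class = "svygap_pooled"
  )
}

#' @export
print.svygap_pooled <- function(x, ...) {
  cat(sprintf("Pooled prevalence (%s): %.2f%% [%.2f, %.2f], tau^2 = %.3g, k = %d\n",
              x$method, 100 * x$p_pooled, 100 * x$ci_low, 100 * x$ci_high,
              x$tau2, nrow(x$per_stratum)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.svygap_pooled <- function(x, ...) x$per_stratum

#' @export
glance.svygap_pooled <- function(x, ...) {
  tibble::tibble(p_pooled = x$p_pooled, se = x$se, ci_low = x$ci_low,
                 ci_high = x$ci_high, tau2 = x$tau2, q = x$q,
                 q_p_value = x$q_p_value, k = nrow(x$per_stratum),
                 method = x$method)
}
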