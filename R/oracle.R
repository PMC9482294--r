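# Exact population oracle for the scenario: enumerate the finite covariate
# space cell by cell instead of simulating, so the true decomposition is
# known to numerical quadrature accuracy.

# All covariate cells with their per-residence probabilities and the full
# dummy design (intercept + every level of every covariate).
enumerate_cells <- function(covariates) {
  lev_list <- lapply(covariates, function(cv) cv$levels)
  cells <- do.call(expand.grid, c(lev_list, stringsAsFactors = FALSE))
  n <- nrow(cells)
  p_urban <- rep(1, n)
  p_rural <- rep(1, n)
  F_list <- list(`(Intercept)` = rep(1, n))
  info <- list(tibble::tibble(column = "(Intercept)", variable = "(Intercept)",
                              level = NA_character_, is_ref = FALSE))
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    pu <- setNames(cv$p_urban, cv$levels)
    pr <- setNames(cv$p_rural, cv$levels)
    p_urban <- p_urban * pu[cells[[nm]]]
    p_rural <- p_rural * pr[cells[[nm]]]
    for (i in seq_along(cv$levels)) {
      F_list[[paste0(nm, ":", cv$levels[i])]] <- as.numeric(cells[[nm]] == cv$levels[i])
      info[[length(info) + 1L]] <- tibble::tibble(
        column = paste0(nm, ":", cv$levels[i]), variable = nm,
        level = cv$levels[i], is_ref = (i == 1L))
    }
  }
  list(cells = cells, p_urban = unname(p_urban), p_rural = unname(p_rural),
       X_full = do.call(cbind, F_list), info = dplyr::bind_rows(info))
}

# Treatment-coded named beta -> full-dummy beta (reference levels at 0),
# aligned with the columns of enumerate_cells()/build_design() X_full.
beta_to_full <- function(beta, info) {
  b <- setNames(rep(0, nrow(info)), info$column)
  common <- intersect(names(beta), names(b))
  b[common] <- beta[common]
  b
}

# Population-averaged success probability at log-odds eta when a
# Normal(0, sigma) cluster intercept is present: Gauss-Hermite quadrature
# with 25 nodes (exact to machine precision at this smoothness).
marginal_plogis <- function(eta, sigma) {
  if (sigma == 0) return(plogis(eta))
  gh <- statmod::gauss.quad(25, kind = "hermite")
  z <- sqrt(2) * gh$nodes
  wq <- gh$weights / sqrt(pi)
  out <- numeric(length(eta))
  for (j in seq_along(z)) out <- out + wq[j] * plogis(eta + sigma * z[j])
  out
}

#' Exact population decomposition for a synthetic scenario
#'
#' Computes, by exact enumeration over the finite covariate space (with the
#' cluster random intercept integrated out by Gauss-Hermite quadrature), the
#' population values of the urban-rural gap `D`, its characteristics
#' component `E` and coefficients component `C`, and the per-term detailed
#' contributions under deviation-coding normalization — all using the TRUE
#' coefficient vectors of the scenario. Serves as the ground-truth oracle
#' against which the sample decomposition of [svy_decompose()] converges.
#'
#' @param scenario A `svygap_scenario` (all covariates categorical).
#' @param normalize Normalize categorical blocks to deviation coding before
#'   computing detailed contributions (default `TRUE`).
#' @return A list of class `svygap_truth` with elements `D`, `E`, `C`,
#'   `p_urban`, `p_rural`, and `terms` (tibble of per-term `e_k`, `c_k`).
#' @export
true_decomposition <- function(scenario, normalize = TRUE) {
  stopifnot(inherits(scenario, "svygap_scenario"))
  enum <- enumerate_cells(scenario$covariates)
  beta_A <- beta_to_full(scenario$beta_urban, enum$info)
  beta_B <- beta_to_full(scenario$beta_rural, enum$info)
  eta_A <- as.numeric(enum$X_full %*% beta_A)
  eta_B <- as.numeric(enum$X_full %*% beta_B)
  mu_A <- marginal_plogis(eta_A, scenario$sigma_cluster)
  mu_B <- marginal_plogis(eta_B, scenario$sigma_cluster)
  p_A <- sum(enum$p_urban * mu_A)   # urban prevalence
  p_B <- sum(enum$p_rural * mu_B)   # rural prevalence
  q <- sum(enum$p_rural * mu_A)     # rural composition at urban coefficients
  xbar_A <- as.numeric(crossprod(enum$X_full, enum$p_urban))
  xbar_B <- as.numeric(crossprod(enum$X_full, enum$p_rural))
  res <- decomp_core(beta_A, beta_B, xbar_A, xbar_B,
                     p_bar_A = p_A, p_bar_B = p_B, q = q,
                     info = enum$info, normalize = normalize)
  structure(c(res, list(p_urban = p_A, p_rural = p_B)), class = "svygap_truth")
}
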