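#' Define a synthetic two-stage cluster survey scenario
#'
#' A scenario is the full generative specification for multi-country,
#' two-stage cluster-sampled microdata with a binary outcome: cluster
#' counts, residence mix, residence-specific categorical covariate
#' distributions, residence-specific logit coefficient vectors, a sampling
#' weight model, and an optional cluster-level random intercept. The same
#' object drives both [simulate_survey()] and the exact population oracle
#' [true_decomposition()].
#'
#' Coefficients are named on the model scale (log-odds) with treatment
#' coding: `"(Intercept)"` plus one `"term:level"` entry for every
#' non-reference level (the first listed level of each covariate is the
#' reference). `beta_urban` and `beta_rural` must share the same names in
#' the same order.
#'
#' @param n_countries Number of countries.
#' @param clusters_per_country Primary sampling units (clusters) per country.
#' @param women_per_cluster Respondents drawn per cluster.
#' @param urban_fraction Probability that a cluster is urban; scalar or one
#'   value per country. Clusters are wholly urban or wholly rural.
#' @param covariates Named list; each element is a list with `levels`
#'   (character), `p_urban` and `p_rural` (probability vectors over the
#'   levels, each summing to 1).
#' @param beta_urban,beta_rural Named log-odds vectors (see Details).
#' @param weight_cv Coefficient of variation of the Gamma sampling weights
#'   (mean 1; normalized to mean 1 within country after draw).
#' @param sigma_cluster SD of the Normal cluster-level random intercept on
#'   the log-odds scale; positive values induce intra-cluster correlation
#'   and design effects above 1. Set 0 for independent responses.
#' @param informative_weights If `TRUE`, weights are additionally tilted by
#'   the level of the first covariate (then renormalized), making the
#'   weighted and unweighted estimators diverge.
#' @param seed Integer seed giving full reproducibility of the draw.
#' @return An object of class `svygap_scenario`.
#' @seealso [default_scenario()], [simulate_survey()], [true_decomposition()]
#' @export
scenario_config <- function(n_countries,
                            clusters_per_country,
                            women_per_cluster,
                            urban_fraction,
                            covariates,
                            beta_urban,
                            beta_rural,
                            weight_cv = 0.5,
                            sigma_cluster = 0.3,
                            informative_weights = FALSE,
                            seed = 1L) {
  for (fld in c("n_countries", "clusters_per_country", "women_per_cluster")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop_field(fld, "must be a strictly positive integer")
    }
  }
  if (!is.numeric(urban_fraction) || anyNA(urban_fraction) ||
      length(urban_fraction) %not_in% c(1L, n_countries) ||
      any(urban_fraction <= 0) || any(urban_fraction >= 1)) {
    stop_field("urban_fraction", "must lie strictly in (0, 1), length 1 or n_countries")
  }
  if (!is.list(covariates) || is.null(names(covariates)) || any(names(covariates) == "")) {
    stop_field("covariates", "must be a named list")
  }
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (!all(c("levels", "p_urban", "p_rural") %in% names(cv))) {
      stop_field(paste0("covariates$", nm), "needs `levels`, `p_urban`, `p_rural`")
    }
    k <- length(cv$levels)
    for (side in c("p_urban", "p_rural")) {
      p <- cv[[side]]
      if (length(p) != k || !all(is.finite(p)) || any(p < 0)) {
        stop_field(paste0("covariates$", nm, "$", side),
                   "must be a non-negative vector matching `levels`")
      }
      if (abs(sum(p) - 1) > 1e-12) {
        stop_field(paste0("covariates$", nm, "$", side),
                   sprintf("probabilities sum to %.15f, not 1", sum(p)))
      }
    }
  }
  expected <- scenario_term_names(covariates)
  for (side in c("beta_urban", "beta_rural")) {
    b <- get(side)
    if (!identical(names(b), expected)) {
      stop_field(side, paste0("coefficient names must be exactly: ",
                              paste(expected, collapse = ", ")))
    }
  }
  if (!is.numeric(weight_cv) || weight_cv < 0) stop_field("weight_cv", "must be >= 0")
  if (!is.numeric(sigma_cluster) || sigma_cluster < 0) {
    stop_field("sigma_cluster", "must be >= 0")
  }
  structure(
    list(n_countries = as.integer(n_countries),
         clusters_per_country = as.integer(clusters_per_country),
         women_per_cluster = as.integer(women_per_cluster),
         urban_fraction = rep_len(urban_fraction, n_countries),
         covariates = covariates,
         beta_urban = beta_urban,
         beta_rural = beta_rural,
         weight_cv = weight_cv,
         sigma_cluster = sigma_cluster,
         informative_weights = isTRUE(informative_weights),
         seed = as.integer(seed)),
    class = "svygap_scenario"
  )
}

# Treatment-coded coefficient names implied by a covariate list.
scenario_term_names <- function(covariates) {
  c("(Intercept)",
    unlist(lapply(names(covariates), function(nm) {
      lev <- covariates[[nm]]$levels
      paste0(nm, ":", lev[-1L])
    }), use.names = FALSE))
}

#' Default DHS-like disparity scenario
#'
#' Four countries with the covariate mix that dominates rural-urban
#' caesarean-delivery disparities in sub-Saharan African household surveys:
#' household wealth (5 levels), antenatal-care attendance (3), parity (4),
#' maternal education (4) and health-insurance coverage (2). Urban covariate
#' distributions are shifted toward high wealth, more antenatal care, lower
#' parity and more schooling, and the two residence strata have different
#' coefficient vectors, so both a characteristics and a coefficients
#' component of the outcome gap are present. Intercepts are set so the true
#' population prevalences sit near 10% urban and 4% rural, with roughly a
#' third of clusters urban — the order of magnitude seen for facility-birth
#' caesarean sections in the region.
#'
#' @param seed Integer seed.
#' @param clusters_per_country Clusters per country (default 100).
#' @param women_per_cluster Respondents per cluster (default 25).
#' @param ... Further arguments passed to [scenario_config()] to override
#'   defaults (e.g. `sigma_cluster`, `weight_cv`).
#' @return An object of class `svygap_scenario`.
#' @export
default_scenario <- function(seed = 1L, clusters_per_country = 100L,
                             women_per_cluster = 25L, ...) {
  covariates <- list(
    wealth = list(
      levels  = c("poorest", "poorer", "middle", "richer", "richest"),
      p_rural = c(0.305, 0.285, 0.224, 0.140, 0.046),
      p_urban = c(0.039, 0.072, 0.155, 0.300, 0.434)
    ),
    anc = list(
      levels  = c("none", "1-3", "4+"),
      p_rural = c(0.136, 0.372, 0.492),
      p_urban = c(0.042, 0.236, 0.722)
    ),
    parity = list(
      levels  = c("1", "2", "3", "4+"),
      p_rural = c(0.154, 0.168, 0.157, 0.521),
      p_urban = c(0.202, 0.225, 0.189, 0.384)
    ),
    education = list(
      levels  = c("none", "primary", "secondary", "higher"),
      p_rural = c(0.500, 0.335, 0.154, 0.011),
      p_urban = c(0.234, 0.240, 0.430, 0.096)
    ),
    insurance = list(
      levels  = c("no", "yes"),
      p_rural = c(0.953, 0.047),
      p_urban = c(0.897, 0.103)
    )
  )
  beta_rural <- c(
    "(Intercept)" = -4.35,
    "wealth:poorer" = 0.30, "wealth:middle" = 0.65, "wealth:richer" = 1.00,
    "wealth:richest" = 1.45,
    "anc:1-3" = 0.90, "anc:4+" = 1.50,
    "parity:2" = -0.35, "parity:3" = -0.70, "parity:4+" = -1.40,
    "education:primary" = 0.15, "education:secondary" = 0.30,
    "education:higher" = 0.35,
    "insurance:yes" = 0.50
  )
  beta_urban <- c(
    "(Intercept)" = -3.50,
    "wealth:poorer" = 0.27, "wealth:middle" = 0.54, "wealth:richer" = 0.85,
    "wealth:richest" = 1.23,
    "anc:1-3" = 0.42, "anc:4+" = 0.77,
    "parity:2" = -0.23, "parity:3" = -0.46, "parity:4+" = -0.96,
    "education:primary" = 0.08, "education:secondary" = 0.15,
    "education:higher" = 0.23,
    "insurance:yes" = 0.35
  )
  scenario_config(
    n_countries = 4L,
    clusters_per_country = clusters_per_country,
    women_per_cluster = women_per_cluster,
    urban_fraction = 0.36,
    covariates = covariates,
    beta_urban = beta_urban,
    beta_rural = beta_rural,
    seed = seed,
    ...
  )
}

#' Read / write a scenario as YAML
#'
#' @param scenario A `svygap_scenario`.
#' @param path File path.
#' @return `read_scenario()` returns a `svygap_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "svygap_scenario"))
  x <- unclass(scenario)
  x$beta_urban <- as.list(x$beta_urban)
  x$beta_rural <- as.list(x$beta_rural)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(scenario_config, c(
    x[c("n_countries", "clusters_per_country", "women_per_cluster",
        "urban_fraction", "covariates", "weight_cv", "sigma_cluster",
        "informative_weights", "seed")],
    list(beta_urban = unlist(x$beta_urban), beta_rural = unlist(x$beta_rural))
  ))
}
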