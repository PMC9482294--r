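# Small scenario builders shared across tests. All fixtures are generated
# in code; nothing is read from disk except the packaged example table.

# One binary covariate, no cluster effect, unit-ish weights: the covariate
# space has two cells, so every population quantity can be enumerated by
# hand in the tests.
binary_scenario <- function(seed = 1L,
                            p_urban = 0.7, p_rural = 0.3,
                            beta_urban = c(`(Intercept)` = -2, `x:b` = 1),
                            beta_rural = c(`(Intercept)` = -2, `x:b` = 1),
                            clusters_per_country = 50L,
                            women_per_cluster = 25L,
                            n_countries = 1L,
                            sigma_cluster = 0,
                            weight_cv = 0.2) {
  scenario_config(
    n_countries = n_countries,
    clusters_per_country = clusters_per_country,
    women_per_cluster = women_per_cluster,
    urban_fraction = 0.5,
    covariates = list(x = list(levels = c("a", "b"),
                               p_urban = c(1 - p_urban, p_urban),
                               p_rural = c(1 - p_rural, p_rural))),
    beta_urban = beta_urban,
    beta_rural = beta_rural,
    weight_cv = weight_cv,
    sigma_cluster = sigma_cluster,
    seed = seed
  )
}

# Two covariates (3 + 2 levels): the workhorse for decomposition property
# loops; cheap to simulate and fit.
small_scenario <- function(seed = 1L,
                           clusters_per_country = 30L,
                           women_per_cluster = 20L,
                           n_countries = 2L,
                           sigma_cluster = 0.3,
                           beta_shift = 0.4,
                           same_composition = FALSE,
                           same_beta = FALSE,
                           weight_cv = 0.3) {
  p_u_w <- c(0.2, 0.3, 0.5)
  p_r_w <- if (same_composition) p_u_w else c(0.5, 0.3, 0.2)
  p_u_i <- c(0.8, 0.2)
  p_r_i <- if (same_composition) p_u_i else c(0.95, 0.05)
  beta_rural <- c(`(Intercept)` = -2.2, `wealth:mid` = 0.5, `wealth:high` = 1.1,
                  `insurance:yes` = 0.5)
  beta_urban <- if (same_beta) beta_rural else
    beta_rural + c(beta_shift, -0.1, 0.15, -0.2)
  names(beta_urban) <- names(beta_rural)
  scenario_config(
    n_countries = n_countries,
    clusters_per_country = clusters_per_country,
    women_per_cluster = women_per_cluster,
    urban_fraction = 0.5,
    covariates = list(
      wealth = list(levels = c("low", "mid", "high"),
                    p_urban = p_u_w, p_rural = p_r_w),
      insurance = list(levels = c("no", "yes"),
                       p_urban = p_u_i, p_rural = p_r_i)
    ),
    beta_urban = beta_urban,
    beta_rural = beta_rural,
    weight_cv = weight_cv,
    sigma_cluster = sigma_cluster,
    seed = seed
  )
}

small_terms <- c("wealth", "insurance")

# Hand-built SRS-like frame: equal weights, one row per PSU, one stratum.
srs_frame <- function(y, x, w = rep(1, length(y))) {
  tibble::tibble(outcome = y, x = x, weight = w, stratum = "s1",
                 psu = sprintf("p%03d", seq_along(y)), group = "all",
                 country = "c1")
}
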