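test_that("simulation is byte-identical given the same seed", {
  sc <- small_scenario(seed = 7L)
  d1 <- simulate_survey(sc)
  d2 <- simulate_survey(sc)
  expect_identical(d1, d2)
  d3 <- simulate_survey(small_scenario(seed = 8L))
  expect_false(identical(d1, d3))
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(binary_scenario(p_urban = NA), "p_urban")
  sc_args <- function(...) {
    args <- list(n_countries = 1, clusters_per_country = 2, women_per_cluster = 2,
                 urban_fraction = 0.5,
                 covariates = list(x = list(levels = c("a", "b"),
                                            p_urban = c(0.5, 0.5),
                                            p_rural = c(0.5, 0.5))),
                 beta_urban = c(`(Intercept)` = 0, `x:b` = 1),
                 beta_rural = c(`(Intercept)` = 0, `x:b` = 1))
    utils::modifyList(args, list(...))
  }
  expect_error(do.call(scenario_config, sc_args(
    covariates = list(x = list(levels = c("a", "b"),
                               p_urban = c(0.6, 0.5), p_rural = c(0.5, 0.5))))),
    "p_urban")
  expect_error(do.call(scenario_config, sc_args(
    beta_rural = c(`(Intercept)` = 0, `x:wrong` = 1))), "beta_rural")
  expect_error(do.call(scenario_config, sc_args(clusters_per_country = 0)),
               "clusters_per_country")
  expect_error(do.call(scenario_config, sc_args(urban_fraction = 1.2)),
               "urban_fraction")
})

test_that("exchangeable groups produce a near-zero outcome gap", {
  # identical betas and identical covariate distributions: the residence
  # label is exchangeable, so the empirical gap is pure noise
  sc <- binary_scenario(seed = 21L, p_urban = 0.4, p_rural = 0.4,
                        clusters_per_country = 2000L, women_per_cluster = 25L)
  d <- simulate_survey(sc)
  expect_gte(nrow(d), 50000L)
  pr <- svy_prevalence(d, by = "group")
  gap <- pr$p[pr$group == "urban"] - pr$p[pr$group == "rural"]
  se <- sqrt(sum(pr$se^2))
  expect_lt(abs(gap), 3 * se)
})

test_that("empirical group prevalence matches the enumeration oracle", {
  # single binary covariate: the analytic prevalence is the 2-cell sum
  # sum_x P_g(x) plogis(beta0 + beta1 x), computed here by hand
  sc <- binary_scenario(seed = 5L, p_urban = 0.7, p_rural = 0.3,
                        beta_urban = c(`(Intercept)` = -2, `x:b` = 1.2),
                        beta_rural = c(`(Intercept)` = -2.5, `x:b` = 0.8),
                        clusters_per_country = 2000L, women_per_cluster = 25L)
  hand <- c(
    urban = 0.3 * plogis(-2) + 0.7 * plogis(-2 + 1.2),
    rural = 0.7 * plogis(-2.5) + 0.3 * plogis(-2.5 + 0.8)
  )
  d <- simulate_survey(sc)
  for (g in c("urban", "rural")) {
    rows <- d$group == g
    n_g <- sum(rows)
    p_emp <- mean(d$outcome[rows])  # unweighted: weights are non-informative
    se <- sqrt(hand[[g]] * (1 - hand[[g]]) / n_g)
    expect_lt(abs(p_emp - hand[[g]]), 3 * se)
  }
})

test_that("cluster random intercept induces design effects above 1", {
  sc <- small_scenario(seed = 31L, sigma_cluster = 0.6,
                       clusters_per_country = 60L, weight_cv = 0)
  d <- simulate_survey(sc)
  pr <- svy_prevalence(d)
  deff <- pr$se^2 / (pr$p * (1 - pr$p) / pr$n_raw)
  expect_gt(deff, 1)
})

test_that("microdata round-trips losslessly through CSV", {
  sc <- small_scenario(seed = 3L, clusters_per_country = 5L)
  d <- simulate_survey(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_microdata(d, path)
  d2 <- read_microdata(path)
  expect_equal(attr(d2, "n_dropped"), 0L)
  d_chr <- dplyr::mutate(d, dplyr::across(c(wealth, insurance), as.character))
  expect_equal(as.data.frame(d2), as.data.frame(d_chr), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("scenario round-trips through YAML", {
  sc <- small_scenario(seed = 12L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2$beta_urban, sc$beta_urban)
  expect_equal(sc2$covariates, sc$covariates, tolerance = 1e-12)
  expect_identical(simulate_survey(sc2), simulate_survey(sc))
})

test_that("reader applies complete-case filtering and reports drops", {
  sc <- small_scenario(seed = 3L, clusters_per_country = 5L)
  d <- simulate_survey(sc)
  d$wealth[c(2, 5)] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_microdata(d, path)
  d2 <- read_microdata(path)
  expect_equal(attr(d2, "n_dropped"), 2L)
  expect_equal(nrow(d2), nrow(d) - 2L)
  expect_error(read_microdata(path, mapping = c(outcome = "nope")), "nope")
})

test_that("population oracle: equal coefficients kill C, equal margins kill E", {
  tr_c <- true_decomposition(small_scenario(same_beta = TRUE))
  expect_equal(tr_c$C, 0, tolerance = 1e-12)
  expect_true(all(abs(tr_c$terms$c_k) < 1e-12))
  expect_equal(tr_c$E, tr_c$D, tolerance = 1e-12)

  tr_e <- true_decomposition(small_scenario(same_composition = TRUE))
  expect_equal(tr_e$E, 0, tolerance = 1e-12)
  expect_equal(tr_e$C, tr_e$D, tolerance = 1e-12)
})

test_that("population oracle matches the hand-enumerated 2-cell formula", {
  # one binary covariate, p_urban = 0.7, p_rural = 0.3, shared beta (-2, 1):
  # E = [0.7 F(-1) + 0.3 F(-2)] - [0.3 F(-1) + 0.7 F(-2)], C = 0
  sc <- binary_scenario(p_urban = 0.7, p_rural = 0.3,
                        beta_urban = c(`(Intercept)` = -2, `x:b` = 1),
                        beta_rural = c(`(Intercept)` = -2, `x:b` = 1))
  tr <- true_decomposition(sc)
  E_hand <- (0.7 * plogis(-1) + 0.3 * plogis(-2)) -
            (0.3 * plogis(-1) + 0.7 * plogis(-2))
  expect_equal(tr$E, E_hand, tolerance = 1e-12)
  expect_equal(tr$C, 0, tolerance = 1e-12)
  expect_equal(tr$D, E_hand, tolerance = 1e-12)
})

test_that("oracle integrates the cluster effect by quadrature", {
  # against an independent Monte-Carlo integral of plogis(eta + sigma Z)
  sc <- binary_scenario(sigma_cluster = 0.5)
  tr <- true_decomposition(sc)
  set.seed(99)
  z <- rnorm(4e5)
  mc <- function(eta) mean(plogis(eta + 0.5 * z))
  p_u_mc <- 0.3 * mc(-2) + 0.7 * mc(-1)
  expect_lt(abs(tr$p_urban - p_u_mc), 1e-3)
})
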