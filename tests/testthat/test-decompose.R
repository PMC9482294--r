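test_that("identical coefficient vectors put the whole gap into E", {
  d <- simulate_survey(small_scenario(seed = 41L))
  fit_A <- svy_logit(d, small_terms, subset = "urban")
  res <- svygap:::decompose_fits(fit_A, fit_A)
  expect_lt(abs(res$C), 1e-10)
  expect_true(all(abs(res$terms$c_k) < 1e-12))
  expect_equal(res$E, res$D, tolerance = 1e-10)
})

test_that("additivity holds to machine precision across random scenarios", {
  for (s in 1:8) {
    d <- simulate_survey(small_scenario(seed = 800L + s,
                                        beta_shift = runif(1, -0.6, 0.6)))
    for (nm in c(TRUE, FALSE)) {
      dec <- svy_decompose(d, small_terms, normalize = nm)
      expect_lt(abs(dec$E + dec$C - dec$D), 1e-10)
      expect_lt(abs(sum(dec$terms$e_k) - dec$E), 1e-10)
      expect_lt(abs(sum(dec$terms$c_k) - dec$C), 1e-10)
      expect_lt(abs(sum(dec$terms$e_pct) + sum(dec$terms$c_pct) - 100), 1e-8)
    }
  }
})

test_that("identity-link variant equals the closed-form linear decomposition", {
  d <- simulate_survey(small_scenario(seed = 51L))
  fA <- svygap:::fit_lpm(d, small_terms, subset = "urban")
  fB <- svygap:::fit_lpm(d, small_terms, subset = "rural")
  res <- svygap:::decompose_fits(fA, fB, link = "identity")
  # classic Blinder-Oaxaca closed form on the treatment-coded design
  E_hand <- sum((fA$xbar - fB$xbar) * fA$beta)
  C_hand <- sum(fB$xbar * (fA$beta - fB$beta))
  expect_equal(res$E, E_hand, tolerance = 1e-10)
  expect_equal(res$C, C_hand, tolerance = 1e-10)
  expect_equal(res$D, E_hand + C_hand, tolerance = 1e-10)
})

test_that("totals are invariant to reference recoding; detailed rows after normalization", {
  d <- simulate_survey(small_scenario(seed = 61L))
  refsets <- list(NULL,
                  c(wealth = "mid", insurance = "yes"),
                  c(wealth = "high", insurance = "no"))
  runs <- lapply(refsets, function(rf) {
    svy_decompose(d, small_terms, refs = rf, normalize = TRUE)
  })
  for (i in 2:3) {
    expect_equal(runs[[i]]$D, runs[[1]]$D, tolerance = 1e-10)
    expect_equal(runs[[i]]$E, runs[[1]]$E, tolerance = 1e-10)
    expect_equal(runs[[i]]$C, runs[[1]]$C, tolerance = 1e-10)
    # after deviation-coding normalization the per-level rows agree too
    a <- dplyr::arrange(runs[[i]]$terms, term)
    b <- dplyr::arrange(runs[[1]]$terms, term)
    expect_equal(a$e_k, b$e_k, tolerance = 1e-8)
    expect_equal(a$c_k, b$c_k, tolerance = 1e-8)
  }
  # without normalization the detailed rows DO depend on the reference
  raw <- lapply(refsets[c(1, 3)], function(rf) {
    svy_decompose(d, small_terms, refs = rf, normalize = FALSE)
  })
  expect_gt(max(abs(dplyr::arrange(raw[[1]]$terms, term)$e_k -
                    dplyr::arrange(raw[[2]]$terms, term)$e_k)), 1e-6)
})

test_that("an inert covariate contributes nothing in the population decomposition", {
  sc <- small_scenario()
  # make `insurance` inert: same distribution and same effect in both groups
  sc$covariates$insurance$p_rural <- sc$covariates$insurance$p_urban
  sc$beta_urban["insurance:yes"] <- sc$beta_rural["insurance:yes"]
  tr <- true_decomposition(sc)
  ins <- tr$terms[tr$terms$variable == "insurance", ]
  expect_true(all(abs(ins$e_k) < 1e-10))
  expect_true(all(abs(ins$c_k) < 1e-10))
})

test_that("swapping comparison and reference groups negates the total gap", {
  d <- simulate_survey(small_scenario(seed = 71L))
  ab <- svy_decompose(d, small_terms, comparison = "urban", reference = "rural")
  ba <- svy_decompose(d, small_terms, comparison = "rural", reference = "urban")
  expect_equal(ba$D, -ab$D, tolerance = 1e-10)
})

test_that("redrawing the reference group with the comparison composition drives E to 0", {
  sc <- small_scenario(seed = 81L, same_composition = TRUE,
                       clusters_per_country = 1000L, women_per_cluster = 25L,
                       n_countries = 2L, sigma_cluster = 0.2)
  d <- simulate_survey(sc)
  expect_gte(nrow(d), 50000L)
  dec <- svy_decompose(d, small_terms)
  expect_lt(abs(dec$E), 0.005)
})

test_that("a vanishing endowment-weight denominator is reported as unidentified", {
  info <- tibble::tibble(
    column = c("(Intercept)", "x:a", "x:b"),
    variable = c("(Intercept)", "x", "x"),
    level = c(NA, "a", "b"), is_ref = c(FALSE, TRUE, FALSE))
  beta_A <- c(`(Intercept)` = -1, `x:a` = 0.5, `x:b` = 0.5)
  xbar_A <- c(1, 0.6, 0.4)
  xbar_B <- c(1, 0.4, 0.6)  # shifts cancel exactly against beta_A
  expect_error(
    svygap:::decomp_core(beta_A, beta_A * 0.5, xbar_A, xbar_B,
                         p_bar_A = 0.30, p_bar_B = 0.20, q = 0.24,
                         info = info, normalize = FALSE),
    class = "svygap_denominator_error")
})

test_that("sample decomposition converges to the enumeration oracle", {
  sc <- small_scenario(seed = 91L, clusters_per_country = 400L,
                       women_per_cluster = 25L)
  d <- simulate_survey(sc)
  dec <- svy_decompose(d, small_terms)
  tr <- true_decomposition(sc)
  expect_lt(abs(dec$E - tr$E), 0.01)
  expect_lt(abs(dec$C - tr$C), 0.015)
  expect_lt(abs(dec$D - tr$D), 0.015)
})

test_that("variable aggregation reproduces published percent groupings", {
  ex <- example_decomposition_table()
  agg <- aggregate_contributions(ex$terms,
                                 D = ex$totals$e_coef + ex$totals$c_coef)
  pick <- function(v) agg$e_pct[agg$variable == v]
  # antenatal-care rows 6.39, -2.37, 9.42 aggregate to 13.4
  expect_equal(round(pick("anc"), 1), 13.4, tolerance = 1e-8)
  # parity rows 3.36, 1.02, -0.64, 9.08 aggregate to 12.8
  expect_equal(round(pick("parity"), 1), 12.8, tolerance = 1e-8)
  # percent-only input falls back to summing the printed percents
  agg2 <- aggregate_contributions(ex$terms[, c("variable", "level",
                                               "e_pct", "c_pct")])
  expect_equal(agg2$e_pct[agg2$variable == "anc"], 6.39 - 2.37 + 9.42,
               tolerance = 1e-8)
})

test_that("aggregation cancels opposite contributions and validates mappings", {
  df <- tibble::tibble(variable = c("v", "v"), level = c("a", "b"),
                       e_pct = c(3.2, -3.2), c_pct = c(1, 1))
  agg <- aggregate_contributions(df)
  expect_equal(agg$e_pct, 0)
  d <- simulate_survey(small_scenario(seed = 3L))
  dec <- svy_decompose(d, small_terms)
  expect_error(aggregate_contributions(dec, mapping = c(wealth = "ses")),
               "unmapped")
  merged <- aggregate_contributions(dec, mapping = c(wealth = "ses",
                                                     insurance = "ses"))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$e_pct, 100 * dec$E / dec$D, tolerance = 1e-8)
})
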