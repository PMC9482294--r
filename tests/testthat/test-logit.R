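test_that("single binary covariate recovers the 2x2 cross-product odds ratio", {
  # counts: (y=1,x=b)=30, (y=0,x=b)=70, (y=1,x=a)=10, (y=0,x=a)=90
  d <- srs_frame(
    y = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)),
    x = c(rep("b", 100), rep("a", 100))
  )
  fit <- svy_logit(d, "x")
  or_hand <- (30 * 90) / (70 * 10)
  expect_equal(exp(unname(fit$beta[["x:b"]])), or_hand, tolerance = 1e-8)
  expect_equal(unname(fit$beta[["(Intercept)"]]), qlogis(10 / 100),
               tolerance = 1e-8)
})

test_that("estimates and cluster-robust SEs are invariant to weight scale", {
  d <- simulate_survey(small_scenario(seed = 6L))
  f1 <- svy_logit(d, small_terms, subset = "rural")
  d10 <- dplyr::mutate(d, weight = weight * 10)
  f2 <- svy_logit(d10, small_terms, subset = "rural")
  expect_equal(f2$beta, f1$beta, tolerance = 1e-9)
  expect_equal(sqrt(diag(f2$vcov)), sqrt(diag(f1$vcov)), tolerance = 1e-9)
})

test_that("canonical-link score identity anchors fitted means to prevalence", {
  d <- simulate_survey(small_scenario(seed = 13L))
  fit <- svy_logit(d, small_terms, subset = "urban")
  expect_lt(abs(predict_mean_prob(fit) - fit$p_bar), 1e-10)
  # all-zero coefficients predict exactly 1/2
  expect_equal(predict_mean_prob(fit, at_beta = rep(0, length(fit$beta))), 0.5)
})

test_that("mean predicted probability equals the 4-row hand sum", {
  d <- srs_frame(y = c(1, 0, 1, 0), x = c("a", "b", "b", "a"),
                 w = c(1, 2, 3, 4))
  fit <- svy_logit(d, "x")
  at <- c(`(Intercept)` = -0.4, `x:b` = 0.9)
  hand <- (1 * plogis(-0.4) + 2 * plogis(0.5) + 3 * plogis(0.5) +
             4 * plogis(-0.4)) / 10
  expect_equal(predict_mean_prob(fit, at_beta = at), hand, tolerance = 1e-12)
})

test_that("errors: one-class outcome, separation, rank deficiency", {
  d0 <- srs_frame(y = rep(0, 20), x = rep(c("a", "b"), 10))
  expect_error(svy_logit(d0, "x"), "single class")
  # x = "b" perfectly predicts y = 1
  dsep <- srs_frame(y = c(rep(1, 10), rep(0, 10)),
                    x = c(rep("b", 10), rep("a", 10)))
  expect_error(svy_logit(dsep, "x"), class = "svygap_separation_error")
  ffirth <- svy_logit(dsep, "x", firth = TRUE)
  expect_true(ffirth$converged && all(is.finite(ffirth$beta)))
  expect_lt(max(abs(ffirth$beta)), 15)
  dal <- srs_frame(y = rbinom(40, 1, 0.5), x = rep(c("a", "b"), 20))
  dal$x2 <- dal$x
  expect_error(svy_logit(dal, c("x", "x2")), class = "svygap_rank_error")
})

test_that("fitted probabilities are invariant to the reference category", {
  d <- simulate_survey(small_scenario(seed = 19L))
  f1 <- svy_logit(d, small_terms, subset = "rural")
  f2 <- svy_logit(d, small_terms, subset = "rural",
                  refs = c(wealth = "high", insurance = "yes"))
  expect_lt(abs(predict_mean_prob(f1) - predict_mean_prob(f2)), 1e-10)
  mu1 <- plogis(as.numeric(f1$design$X %*% f1$beta))
  mu2 <- plogis(as.numeric(f2$design$X %*% f2$beta))
  expect_lt(max(abs(mu1 - mu2)), 1e-10)
})

test_that("coefficients recover the generating values within robust SEs", {
  n_rep <- 30L
  ok <- 0L
  for (r in seq_len(n_rep)) {
    sc <- small_scenario(seed = 300L + r, clusters_per_country = 120L,
                         women_per_cluster = 25L, sigma_cluster = 0.2)
    d <- simulate_survey(sc)
    fit <- svy_logit(d, small_terms, subset = "rural")
    z <- abs(fit$beta - sc$beta_rural[names(fit$beta)]) / sqrt(diag(fit$vcov))
    if (all(z < 3)) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.8)
})

test_that("cluster-robust SEs exceed model-based SEs under positive ICC", {
  n_ge <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    sc <- small_scenario(seed = 700L + r, sigma_cluster = 0.7, weight_cv = 0,
                         clusters_per_country = 40L)
    d <- simulate_survey(sc)
    fit <- svy_logit(d, small_terms, subset = "rural")
    X <- fit$design$X
    mu <- plogis(as.numeric(X %*% fit$beta))
    info <- crossprod(X, X * (fit$design$w * mu * (1 - mu)))
    se_model <- sqrt(diag(solve(info)))
    if (sqrt(fit$vcov[1, 1]) >= se_model[1]) n_ge <- n_ge + 1L
  }
  expect_gte(n_ge / n_rep, 0.9)
})

test_that("odds-ratio table formats references, CIs and stars", {
  d <- simulate_survey(small_scenario(seed = 4L))
  fit <- svy_logit(d, small_terms)
  tab <- odds_ratio_table(fit)
  ref <- tab[tab$reference, ]
  expect_true(all(ref$aOR == 1 & ref$ci_low == 1 & ref$ci_high == 1))
  nonref <- tab[!tab$reference, ]
  td <- tidy(fit)
  for (i in seq_len(nrow(nonref))) {
    row <- td[td$term == nonref$term[i], ]
    expect_equal(nonref$aOR[i], exp(row$estimate), tolerance = 1e-10)
    expect_equal(nonref$ci_low[i],
                 exp(row$estimate - qnorm(0.975) * row$std.error),
                 tolerance = 1e-10)
  }
  # star conventions on synthetic p-values
  expect_equal(svygap:::stars_for(c(0.2, 0.04, 0.009, 0.0009, NA)),
               c("", "*", "**", "***", ""))
})
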