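#' Simulate two-stage cluster survey microdata
#'
#' Draws one woman-level dataset from a [scenario_config()]: clusters are
#' assigned wholly to the rural or urban stratum, covariate categories come
#' from the residence-specific distributions, the outcome is Bernoulli with
#' log-odds `x'beta_g` (plus the cluster random intercept when
#' `sigma_cluster > 0`), and Gamma sampling weights with the configured
#' coefficient of variation are normalized to mean 1 within country. The
#' draw is fully determined by `scenario$seed`.
#'
#' @param scenario A `svygap_scenario`.
#' @return A tibble with columns `outcome`, `group`, `country`, `stratum`,
#'   `psu`, `weight`, then one column per covariate. Strata are
#'   country-by-residence; PSUs nest within strata.
#' @examples
#' sim <- simulate_survey(default_scenario(seed = 42, clusters_per_country = 8))
#' dplyr::count(sim, group, wt = weight)
#' @export
simulate_survey <- function(scenario) {
  stopifnot(inherits(scenario, "svygap_scenario"))
  cov_names <- names(scenario$covariates)
  with_seed(scenario$seed, {
    out <- vector("list", scenario$n_countries)
    for (i in seq_len(scenario$n_countries)) {
      country <- sprintf("country%02d", i)
      n_cl <- scenario$clusters_per_country
      m <- scenario$women_per_cluster
      urban_cl <- rbinom(n_cl, 1L, scenario$urban_fraction[i]) == 1L
      b_cl <- rnorm(n_cl, 0, scenario$sigma_cluster)
      cl_idx <- rep(seq_len(n_cl), each = m)
      grp <- ifelse(urban_cl[cl_idx], "urban", "rural")
      n <- n_cl * m
      df <- tibble::tibble(
        country = country,
        group = grp,
        stratum = paste(country, grp, sep = "_"),
        psu = sprintf("%s_c%03d", country, cl_idx)
      )
      eta <- numeric(n)
      is_urban <- grp == "urban"
      for (g in c("rural", "urban")) {
        rows <- if (g == "urban") is_urban else !is_urban
        if (!any(rows)) next
        eta[rows] <- scenario[[paste0("beta_", g)]][["(Intercept)"]]
      }
      for (nm in cov_names) {
        cv <- scenario$covariates[[nm]]
        val <- character(n)
        for (g in c("rural", "urban")) {
          rows <- if (g == "urban") is_urban else !is_urban
          if (!any(rows)) next
          p <- cv[[paste0("p_", g)]]
          val[rows] <- sample(cv$levels, sum(rows), replace = TRUE, prob = p)
          beta <- scenario[[paste0("beta_", g)]]
          eff <- c(setNames(0, cv$levels[1L]),
                   beta[paste0(nm, ":", cv$levels[-1L])])
          names(eff) <- cv$levels
          eta[rows] <- eta[rows] + eff[val[rows]]
        }
        df[[nm]] <- factor(val, levels = cv$levels)
      }
      eta <- eta + b_cl[cl_idx]
      df$outcome <- rbinom(n, 1L, plogis(eta))
      w <- if (scenario$weight_cv > 0) {
        shp <- 1 / scenario$weight_cv^2
        rgamma(n, shape = shp, rate = shp)
      } else {
        rep(1, n)
      }
      if (scenario$informative_weights) {
        first <- cov_names[1L]
        w <- w * (1 + 0.5 * (as.integer(df[[first]]) - 1))
      }
      df$weight <- w / mean(w)
      out[[i]] <- df
    }
    dplyr::bind_rows(out)[, c("outcome", "group", "country", "stratum",
                              "psu", "weight", cov_names)]
  })
}

#' Write / read survey microdata as CSV
#'
#' The CSV carries a header row with columns `outcome, group, country,
#' stratum, psu, weight` followed by the covariates; [read_microdata()]
#' validates types, applies complete-case filtering (reporting the number of
#' dropped rows as the `n_dropped` attribute), and can rename columns via
#' `mapping`.
#'
#' @param data Microdata tibble (e.g. from [simulate_survey()]).
#' @param path CSV path.
#' @param mapping Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(outcome = "cs_delivery")`.
#' @return `read_microdata()` returns a tibble; `write_microdata()` returns
#'   `path` invisibly.
#' @export
write_microdata <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_microdata
#' @export
read_microdata <- function(path, mapping = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(mapping)) {
    missing_cols <- unname(mapping)[unname(mapping) %not_in% names(df)]
    if (length(missing_cols) > 0L) {
      abort(paste("mapped column(s) not found:", paste(missing_cols, collapse = ", ")),
            class = "svygap_column_error")
    }
    for (canonical in names(mapping)) {
      names(df)[names(df) == mapping[[canonical]]] <- canonical
    }
  }
  required <- c("outcome", "group", "country", "stratum", "psu", "weight")
  missing_cols <- required[required %not_in% names(df)]
  if (length(missing_cols) > 0L) {
    abort(paste("required column(s) not found:", paste(missing_cols, collapse = ", ")),
          class = "svygap_column_error")
  }
  cc <- complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (!all(df$outcome %in% c(0, 1))) abort("outcome must be coded 0/1")
  if (any(df$weight <= 0)) abort("weights must be strictly positive")
  for (col in setdiff(names(df), c("outcome", "weight"))) {
    df[[col]] <- as.character(df[[col]])
  }
  attr(df, "n_dropped") <- n_dropped
  df
}
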