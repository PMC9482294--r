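#' Describe the survey design and model terms of a microdata table
#'
#' A design specification names the columns of a woman-level (or generally
#' respondent-level) table that carry the outcome, the sampling design
#' (weight, stratum, primary sampling unit), the equity-stratifier group, and
#' the ordered list of categorical model terms with their reference
#' categories. All model terms must be categorical; the reference category of
#' each term defaults to its first observed level (alphabetical for character
#' columns, factor order for factors).
#'
#' @param terms Character vector of covariate column names (categorical).
#' @param outcome Name of the 0/1 outcome column.
#' @param refs Optional named character vector `c(term = "reference level")`.
#' @param group,weight,stratum,psu,country Design column names.
#' @return An object of class `svygap_design` (a list).
#' @export
design_spec <- function(terms,
                        outcome = "outcome",
                        refs = NULL,
                        group = "group",
                        weight = "weight",
                        stratum = "stratum",
                        psu = "psu",
                        country = "country") {
  if (length(terms) < 1L) stop_field("terms", "at least one model term is required")
  if (!is.null(refs)) {
    bad <- names(refs) %not_in% terms
    if (any(bad)) {
      stop_field("refs", paste("reference given for unknown term(s):",
                               paste(names(refs)[bad], collapse = ", ")))
    }
  }
  structure(
    list(outcome = outcome, terms = terms, refs = refs, group = group,
         weight = weight, stratum = stratum, psu = psu, country = country),
    class = "svygap_design"
  )
}

# Validate presence and types of the mapped columns; returns data with
# factors resolved (reference level first) and an attribute recording the
# per-term level sets. Rows with missing values in used columns are an error
# here; complete-case filtering is the reader's job.
check_design_data <- function(data, spec, need_group = FALSE) {
  used <- c(spec$outcome, spec$terms, spec$weight, spec$stratum, spec$psu)
  if (need_group) used <- c(used, spec$group)
  missing_cols <- used[used %not_in% names(data)]
  if (length(missing_cols) > 0L) {
    abort(paste("column(s) not found in data:", paste(missing_cols, collapse = ", ")),
          class = "svygap_column_error")
  }
  if (anyNA(data[used])) {
    abort("missing values in mapped columns; apply complete-case filtering first",
          class = "svygap_na_error")
  }
  y <- data[[spec$outcome]]
  if (!all(y %in% c(0, 1))) {
    abort(sprintf("outcome column `%s` must be coded 0/1", spec$outcome))
  }
  w <- data[[spec$weight]]
  if (!is.numeric(w) || any(w <= 0)) {
    abort(sprintf("weight column `%s` must be strictly positive", spec$weight))
  }
  for (tm in spec$terms) {
    v <- data[[tm]]
    if (is.numeric(v)) {
      abort(sprintf("term `%s` is numeric; only categorical covariates are supported", tm))
    }
    lev <- if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
    ref <- spec$refs[[tm]] %||% lev[1L]
    if (ref %not_in% lev) {
      stop_field("refs", sprintf("reference `%s` is not a level of `%s`", ref, tm))
    }
    data[[tm]] <- factor(as.character(v), levels = c(ref, setdiff(lev, ref)))
  }
  data
}

# Build the model-matrix bundle used by the logit and the decomposition:
#   X      treatment-coded full-rank matrix (intercept first),
#   X_full all-level dummy matrix (intercept + one column per term level),
#   info   per-column metadata tying X_full columns to X columns.
build_design <- function(data, spec, need_group = FALSE) {
  data <- check_design_data(data, spec, need_group = need_group)
  n <- nrow(data)
  X_list <- list(`(Intercept)` = rep(1, n))
  F_list <- list(`(Intercept)` = rep(1, n))
  info <- list(tibble::tibble(column = "(Intercept)", variable = "(Intercept)",
                              level = NA_character_, is_ref = FALSE,
                              treatment_column = "(Intercept)"))
  for (tm in spec$terms) {
    v <- data[[tm]]
    lev <- levels(v)
    for (i in seq_along(lev)) {
      col_full <- paste0(tm, ":", lev[i])
      F_list[[col_full]] <- as.numeric(v == lev[i])
      if (i > 1L) X_list[[col_full]] <- F_list[[col_full]]
      info[[length(info) + 1L]] <- tibble::tibble(
        column = col_full, variable = tm, level = lev[i], is_ref = (i == 1L),
        treatment_column = if (i == 1L) NA_character_ else col_full
      )
    }
  }
  list(
    y = as.numeric(data[[spec$outcome]]),
    X = do.call(cbind, X_list),
    X_full = do.call(cbind, F_list),
    info = dplyr::bind_rows(info),
    w = as.numeric(data[[spec$weight]]),
    stratum = as.character(data[[spec$stratum]]),
    psu = paste(data[[spec$stratum]], data[[spec$psu]], sep = "\r"),
    group = if (need_group) as.character(data[[spec$group]]) else NULL,
    spec = spec,
    levels = lapply(data[spec$terms], levels)
  )
}

# Design-weighted column means of a matrix.
wcolmeans <- function(X, w) as.numeric(crossprod(X, w)) / sum(w)

# Stratified between-PSU covariance of score/residual contributions `S`
# (n x p): Taylor-linearization building block shared by the prevalence SEs,
# the chi-square, and the cluster-robust logit covariance. Strata with a
# single PSU fall back to centering that PSU's total at the grand mean of
# all PSU totals (Stata's singleunit(centered) analogue) and are reported
# via the `single_psu` attribute.
psu_total_cov <- function(S, stratum, psu) {
  S <- as.matrix(S)
  totals <- rowsum(S, group = psu, reorder = FALSE)
  psu_stratum <- stratum[!duplicated(psu)]
  grand_mean <- colMeans(totals)
  V <- matrix(0, ncol(S), ncol(S))
  n_single <- 0L
  for (h in unique(psu_stratum)) {
    Th <- totals[psu_stratum == h, , drop = FALSE]
    nh <- nrow(Th)
    if (nh == 1L) {
      d <- sweep(Th, 2L, grand_mean)
      V <- V + crossprod(d)
      n_single <- n_single + 1L
    } else {
      d <- sweep(Th, 2L, colMeans(Th))
      V <- V + nh / (nh - 1) * crossprod(d)
    }
  }
  attr(V, "single_psu") <- n_single
  attr(V, "n_psu") <- nrow(totals)
  V
}
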