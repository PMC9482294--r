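#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats plogis qlogis pnorm qnorm pchisq rbinom rnorm rgamma
#'   setNames weighted.mean sd complete.cases
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "svygap_config_error")
}

`%not_in%` <- function(x, table) !(x %in% table)

# weighted mean that tolerates zero-row input
wmean <- function(x, w) {
  if (length(x) == 0L) return(NA_real_)
  sum(w * x) / sum(w)
}
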