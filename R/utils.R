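#' @importFrom stats median qlogis plogis rbinom runif setNames var
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Deterministic sub-seed for a named operation within a bundle's RNG stream.
# Keeps every operation reproducible from config$seed alone while decoupling
# the draws of independent stages.
subseed <- function(seed, op, extra = 0L) {
  h <- sum(utf8ToInt(op)) %% 1000L
  as.integer((as.numeric(seed) * 7919 + h * 131 + as.numeric(extra)) %% 2147483629)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_subseed <- function(seed, op, expr, extra = 0L) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(subseed(seed, op, extra))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
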