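#' @importFrom rlang abort warn .data %||%
#' @importFrom stats median quantile rnorm runif rgamma rbinom sd var fft
#'   approx optimize qnorm setNames predict
#' @importFrom utils head tail
NULL

# Deterministic substream seeding: one user-facing seed fans out to
# per-patient / per-purpose seeds via an integer mix, so a cohort is
# reproducible regardless of the order patients are generated in.
# All arithmetic stays below 2^53 (exact in doubles); result < 2^31.
substream_seed <- function(seed, index, purpose = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483629 # largest prime < 2^31
  s <- (abs(seed) %% m)
  s <- (s * 69621 + 1013904223) %% m
  s <- (s + (index %% m) * 40014) %% m
  s <- (s * 40692 + purpose * 52774 + 3791) %% m
  as.integer(s %% m)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a finite number in [%s, %s]", name, lo, hi),
          class = "afbnp_config_error")
  }
  invisible(x)
}

# Stable content hash used for the LOOCV no-leakage audit trail.
content_hash <- function(x) rlang::hash(x)
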