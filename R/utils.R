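#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif rbinom quantile sd coef optim plogis qlogis
#'   lm cor.test complete.cases
#' @importFrom utils combn head tail
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic operations in the package funnel
# through this so (config, seed) -> bit-identical output.
with_seed <- function(seed, expr) {
  # reduce any numeric seed into the valid 32-bit range, deterministically
  seed <- as.integer(abs(as.numeric(seed)) %% 2147483646) + 1L
  withr::with_seed(seed, expr)
}

# Derive a child seed from a parent seed and a stage label, stably: adding a
# new stage never perturbs the randomness consumed by existing stages.
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(label, ":", seed))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483547L
  as.integer(h + 1L)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(min), format(max), format(x)))
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
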