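#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rlnorm rbinom setNames
#' @importFrom utils read.table write.csv read.csv head tail
NULL

# Logistic function; clamped argument keeps exp() finite for extreme logits.
sigmoid <- function(x) {
  x <- pmin(pmax(x, -700), 700)
  1 / (1 + exp(-x))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic entry points route through this so that a seed in a config
# fully determines the result without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying well
# below .Machine$integer.max.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %% 2147483L + 1L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
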