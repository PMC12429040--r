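#' @importFrom stats median pchisq pt quantile rnorm runif sd setNames cor
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `code` under a fixed, pinned RNG state, restoring the caller's
# stream afterwards. All stochastic code in the package funnels through this
# so that results are reproducible bit-for-bit across platforms.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Derive a child seed from a base seed and an index, kept inside the 32-bit
# integer range.
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assertScalarNumeric <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

cosineSimilarity <- function(a, b) {
  if (length(a) != length(b))
    stop("feature vectors have mismatched dimensions", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
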