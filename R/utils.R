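# internal helpers

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr with the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a stream-specific 31-bit sub-seed from a user seed (double
# arithmetic: the product stays below 2^53, so the modulus is exact)
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 101) %% 2147483647)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# sign with random tie-break at 0
rand_sign <- function(x) {
  s <- sign(x)
  z <- s == 0
  if (any(z)) s[z] <- ifelse(runif(sum(z)) < 0.5, 1, -1)
  s
}
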