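## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a local seed when one is given, untouched RNG otherwise
withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# permutation p-value with the observed arrangement counted in both the
# numerator and the denominator
permPValue <- function(permStats, observed, tol = 1e-12) {
  (1 + sum(permStats >= observed - tol)) / (1 + length(permStats))
}

# all permutations of 1..n as a matrix (n! rows); guard keeps this for
# exact small-n enumeration only
allPermutations <- function(n) {
  stopifnot(n >= 1L, n <= 8L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  # insert n at every position of each (n-1)-permutation
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

upperTri <- function(m) m[upper.tri(m)]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
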