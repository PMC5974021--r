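#' @include utils.R
NULL

mantelR <- function(a, b) stats::cor(a, b)

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the `n(n-1)/2` off-diagonal pairs, with a
#' one-tailed (positive association) permutation test applying random
#' joint row/column relabelings to the second matrix.  The observed
#' arrangement is counted in both the numerator and the denominator of
#' the p-value.  With `exact = TRUE` (or automatically when
#' `factorial(n) <= nPermutations`), all `n!` relabelings are enumerated
#' instead.
#'
#' @param matA,matB Symmetric numeric matrices with the same labels.
#'   When both have dimnames, `matB` is reordered to match `matA`.
#' @param nPermutations Number of random permutations.
#' @param seed Optional integer seed.
#' @param exact Force exhaustive enumeration (requires `n <= 8`).
#' @return A [MantelResult-class].
#' @export
mantelTest <- function(matA, matB, nPermutations = 9999L, seed = NULL, exact = FALSE) {
  matA <- as.matrix(matA); matB <- as.matrix(matB)
  n <- nrow(matA)
  if (n < 4L) stopf("Mantel test needs n >= 4 populations (got %d)", n)
  if (!isTRUE(all.equal(matA, t(matA), tolerance = 1e-8)))
    stopf("first matrix is not symmetric")
  if (!isTRUE(all.equal(matB, t(matB), tolerance = 1e-8)))
    stopf("second matrix is not symmetric")
  if (!is.null(rownames(matA)) && !is.null(rownames(matB))) {
    if (!setequal(rownames(matA), rownames(matB)))
      stopf("matrices have different labels")
    matB <- matB[rownames(matA), rownames(matA)]
  } else if (!all(dim(matA) == dim(matB))) stopf("matrices have different sizes")
  a <- upperTri(matA)
  if (stats::sd(a) == 0) stopf("constant matrix: first matrix has no variation")
  if (stats::sd(upperTri(matB)) == 0) stopf("constant matrix: second matrix has no variation")
  rObs <- mantelR(a, upperTri(matB))
  if (exact || (n <= 8L && factorial(n) <= nPermutations)) {
    if (n > 8L) stopf("exact enumeration limited to n <= 8")
    perms <- allPermutations(n)
    rs <- vapply(seq_len(nrow(perms)), function(i) {
      pm <- perms[i, ]
      mantelR(a, upperTri(matB[pm, pm]))
    }, 0)
    # the identity permutation is among the enumerated relabelings
    p <- sum(rs >= rObs - 1e-12) / length(rs)
    return(methods::new("MantelResult", r = rObs, p = p,
                        nPermutations = nrow(perms), exact = TRUE))
  }
  p <- withSeed(seed, {
    rs <- vapply(seq_len(nPermutations), function(b) {
      pm <- sample.int(n)
      mantelR(a, upperTri(matB[pm, pm]))
    }, 0)
    permPValue(rs, rObs)
  })
  methods::new("MantelResult", r = rObs, p = p,
               nPermutations = as.integer(nPermutations), exact = FALSE)
}

#' Great-circle distance matrix between populations
#'
#' Haversine distances (Earth radius 6371 km) between population
#' coordinates in decimal degrees.
#'
#' @param popmap A [PopulationMap-class] with coordinates for every
#'   population.
#' @return Symmetric matrix of distances in kilometres, zero diagonal,
#'   labeled by population.
#' @export
greatCircleMatrix <- function(popmap) {
  pops <- populations(popmap)
  cc <- popmap@coords
  miss <- setdiff(pops, cc$population)
  if (length(miss))
    stopf("populations without coordinates: %s", paste(miss, collapse = ", "))
  cc <- cc[match(pops, cc$population), ]
  m <- geosphere::distm(cbind(cc$lon, cc$lat),
                        fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371000))
  m <- m / 1000
  dimnames(m) <- list(pops, pops)
  diag(m) <- 0
  m
}

#' Haplotype sharing matrix
#'
#' Haplotype classes are computed on the pooled alignment; entry `(i,j)`
#' for `i != j` is the number of distinct haplotypes present in both
#' populations, and the diagonal counts the haplotypes private to each
#' population.
#'
#' @param aln Pooled [MtAlignment-class].
#' @param popmap A [PopulationMap-class].
#' @return Symmetric integer matrix labeled by population.
#' @export
haplotypeSharingMatrix <- function(aln, popmap) {
  pop <- populationFactor(aln, popmap)
  cls <- countHaplotypes(aln)$assignment
  lev <- levels(pop)
  # presence matrix: haplotype class x population
  pres <- table(cls, pop) > 0
  k <- length(lev)
  out <- matrix(0L, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) {
      out[i, i] <- sum(pres[, i] & rowSums(pres) == 1L)
    } else out[i, j] <- sum(pres[, i] & pres[, j])
  }
  out
}

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("Mantel test: r = %.4f, P = %.4g (%s, %d permutations)\n",
              object@r, object@p,
              if (object@exact) "exact enumeration" else "one-tailed permutation",
              object@nPermutations))
})
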