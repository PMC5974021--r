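#' @include stats-distance.R
NULL

#' Diversity summary of a population sample
#'
#' Computes the per-population summary statistics: sample size `n`,
#' number of haplotypes, segregating sites `S`, haplotype (gene)
#' diversity `h = n(1 - sum p_i^2)/(n - 1)` with its Nei (1987) SD, mean
#' pairwise differences `MPD` (over all `C(n,2)` pairs, pairwise
#' deletion) with the Tajima (1983) total-variance SD, and nucleotide
#' diversity `pi = MPD / L_eff` (with `L_eff` the mean number of
#' comparable sites over pairs) with the Nei (1987, eq. 10.7) SD.
#'
#' @param aln An [MtAlignment-class] with at least 2 sequences.
#' @return A [DiversitySummary-class].
#' @examples
#' aln <- mtAlignment(c(a = "ACGT", b = "ACGT", c = "AGGT", d = "AGGT"))
#' diversitySummary(aln)  # h = (4/3)(1 - 0.5) = 0.6667
#' @export
diversitySummary <- function(aln) {
  stopifnot(methods::is(aln, "MtAlignment"))
  n <- nSamples(aln)
  if (n < 2L) stopf("diversity summary needs n >= 2 sequences (got %d)", n)
  M <- alignmentMatrix(aln)
  pw <- pairwiseFromMatrix(M)
  hap <- countHaplotypes(aln)
  counts <- hap$counts
  p <- counts / n
  sp2 <- sum(p^2)
  h <- n * (1 - sp2) / (n - 1)
  # Nei (1987) sampling variance of gene diversity
  hVar <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sp2^2) + sp2 - sp2^2)
  ut <- upper.tri(pw$diff)
  MPD <- mean(pw$diff[ut])
  Leff <- mean(pw$comparable[ut])
  # Tajima (1983) total (stochastic + sampling) variance of the mean
  # number of pairwise differences: b1*k + b2*k^2
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  MPDVar <- b1 * MPD + b2 * MPD^2
  pi <- MPD / Leff
  # Nei (1987) eq. 10.7 total variance of nucleotide diversity
  piVar <- b1 * pi / Leff + b2 * pi^2
  methods::new("DiversitySummary",
               n = n, nHaplotypes = length(counts), S = segregatingSites(M),
               h = h, hSD = sqrt(max(hVar, 0)),
               MPD = MPD, MPDSD = sqrt(max(MPDVar, 0)),
               pi = pi, piSD = sqrt(max(piVar, 0)), Leff = Leff)
}

#' Per-population diversity table
#'
#' Applies [diversitySummary()] to every population of an alignment.
#'
#' @param aln Pooled [MtAlignment-class].
#' @param popmap A [PopulationMap-class] covering every sample.
#' @return data.frame with one row per population (columns `population`,
#'   `n`, `n_haplotypes`, `S`, `h`, `h_sd`, `MPD`, `MPD_sd`, `pi`,
#'   `pi_sd`).
#' @export
diversityTable <- function(aln, popmap) {
  byPop <- splitByPopulation(aln, popmap)
  rows <- lapply(names(byPop), function(p) {
    d <- diversitySummary(byPop[[p]])
    data.frame(population = p, n = d@n, n_haplotypes = d@nHaplotypes, S = d@S,
               h = d@h, h_sd = d@hSD, MPD = d@MPD, MPD_sd = d@MPDSD,
               pi = d@pi, pi_sd = d@piSD)
  })
  do.call(rbind, rows)
}

#' Tajima's D
#'
#' Standard Tajima (1989) D from the mean pairwise differences and the
#' number of segregating sites, both under pairwise deletion.  Returns
#' `NaN` when `S = 0` or `n < 4`.
#'
#' @param aln An [MtAlignment-class].
#' @return Numeric scalar.
#' @export
tajimasD <- function(aln) {
  n <- nSamples(aln)
  if (n < 4L) return(NaN)
  M <- alignmentMatrix(aln)
  S <- segregatingSites(M)
  if (S == 0L) return(NaN)
  pw <- pairwiseFromMatrix(M)
  k <- mean(pw$diff[upper.tri(pw$diff)])
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

setMethod("show", "DiversitySummary", function(object) {
  cat(sprintf("DiversitySummary: n=%d, haplotypes=%d, S=%d\n",
              object@n, object@nHaplotypes, object@S))
  cat(sprintf("  h   = %.4f (SD %.4f)\n", object@h, object@hSD))
  cat(sprintf("  MPD = %.2f (SD %.2f)\n", object@MPD, object@MPDSD))
  cat(sprintf("  pi  = %.6f (SD %.6f)  [L_eff = %.1f]\n",
              object@pi, object@piSD, object@Leff))
})
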