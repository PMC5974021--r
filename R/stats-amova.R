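#' @include stats-distance.R
NULL

# Core Excoffier-style decomposition on a matrix of squared inter-
# haplotype distances.  Under the "pairwise difference" convention the
# count of differing sites is itself the squared Euclidean distance
# (each site contributes (x_i - x_j)^2 in {0,1}), so callers pass the
# difference-count matrix directly.  pop: factor over individuals;
# group: optional named map population -> group.
amovaCore <- function(D2, pop, group = NULL) {
  pop <- droplevels(as.factor(pop))
  N <- length(pop); P <- nlevels(pop)
  np <- as.numeric(table(pop))
  idx <- split(seq_len(N), pop)
  ssdTotal <- sum(D2) / (2 * N)
  ssdWP <- sum(vapply(idx, function(i) sum(D2[i, i, drop = FALSE]), 0) / (2 * np))
  flags <- character()
  if (is.null(group)) {
    dfW <- N - P; dfA <- P - 1
    if (dfW <= 0) stopf("AMOVA needs at least one population with n >= 2")
    sigW <- ssdWP / dfW
    ssdAP <- ssdTotal - ssdWP
    n0 <- (N - sum(np^2) / N) / dfA
    sigA <- (ssdAP / dfA - sigW) / n0
    tot <- sigA + sigW
    if (abs(tot) < 1e-300) {
      phiST <- 0
      flags <- c(flags, "degenerate: zero total variance, Phi_ST defined as 0")
      tot <- 1  # keep pct finite: all-zero components
      pct <- c(0, 0)
    } else pct <- 100 * c(sigA, sigW) / tot
    if (sigA < 0) flags <- c(flags, "negative among-population variance component")
    phiST <- if (!length(grep("degenerate", flags))) sigA / (sigA + sigW) else 0
    comp <- data.frame(
      source = c("Among populations", "Within populations"),
      df = c(dfA, dfW), SSD = c(ssdAP, ssdWP), sigma2 = c(sigA, sigW),
      pct = pct)
    return(list(components = comp, phi = c(phiST = phiST), flags = flags))
  }
  gOfPop <- group[levels(pop)]
  if (anyNA(gOfPop)) stopf("grouping does not cover all populations")
  gFac <- factor(unname(gOfPop))
  G <- nlevels(gFac)
  if (G < 2) stopf("two-level AMOVA needs >= 2 groups")
  if (any(table(gFac) == 1L))
    flags <- c(flags, "group with a single population: Phi_SC uninformative for that stratum")
  popsOfGroup <- split(levels(pop), gFac)
  Ng <- vapply(popsOfGroup, function(ps) sum(np[match(ps, levels(pop))]), 0)
  ssdTotG <- vapply(popsOfGroup, function(ps) {
    i <- unlist(idx[ps], use.names = FALSE)
    sum(D2[i, i, drop = FALSE])
  }, 0) / (2 * Ng)
  ssdWPG <- vapply(popsOfGroup, function(ps) {
    sum(vapply(ps, function(p) sum(D2[idx[[p]], idx[[p]], drop = FALSE]) /
                 (2 * length(idx[[p]])), 0))
  }, 0)
  ssdAPWG <- sum(ssdTotG - ssdWPG)
  ssdAG <- ssdTotal - ssdWP - ssdAPWG
  dfW <- N - P; dfB <- P - G; dfA <- G - 1
  if (dfW <= 0) stopf("AMOVA needs at least one population with n >= 2")
  if (dfB == 0) {
    # every group holds a single population: the within-group stratum is
    # degenerate; the design collapses to a one-level AMOVA on groups
    flags <- c(flags, "degenerate within-group stratum (one population per group)")
    one <- amovaCore(D2, pop, NULL)
    comp <- data.frame(
      source = c("Among groups", "Among populations within groups", "Within populations"),
      df = c(one$components$df[1], 0, one$components$df[2]),
      SSD = c(one$components$SSD[1], 0, one$components$SSD[2]),
      sigma2 = c(one$components$sigma2[1], 0, one$components$sigma2[2]),
      pct = c(one$components$pct[1], 0, one$components$pct[2]))
    return(list(components = comp,
                phi = c(phiST = unname(one$phi["phiST"]), phiSC = 0,
                        phiCT = unname(one$phi["phiST"])),
                flags = c(flags, one$flags)))
  }
  sigW <- ssdWP / dfW
  # unequal-sample-size coefficients (Excoffier et al. 1992)
  Sg <- vapply(popsOfGroup, function(ps) sum(np[match(ps, levels(pop))]^2), 0)
  nC <- (N - sum(Sg / Ng)) / dfB
  nPrime <- (sum(Sg / Ng) - sum(np^2) / N) / dfA
  nDblPrime <- (N - sum(Ng^2) / N) / dfA
  sigB <- (ssdAPWG / dfB - sigW) / nC
  sigA <- (ssdAG / dfA - sigW - nPrime * sigB) / nDblPrime
  tot <- sigA + sigB + sigW
  if (abs(tot) < 1e-300) {
    flags <- c(flags, "degenerate: zero total variance, Phi statistics defined as 0")
    phi <- c(phiST = 0, phiSC = 0, phiCT = 0)
    pct <- c(0, 0, 0)
  } else {
    phi <- c(phiST = (sigA + sigB) / tot,
             phiSC = if (abs(sigB + sigW) < 1e-300) 0 else sigB / (sigB + sigW),
             phiCT = sigA / tot)
    pct <- 100 * c(sigA, sigB, sigW) / tot
  }
  if (sigA < 0) flags <- c(flags, "negative among-group variance component")
  if (sigB < 0) flags <- c(flags, "negative among-population-within-group variance component")
  comp <- data.frame(
    source = c("Among groups", "Among populations within groups", "Within populations"),
    df = c(dfA, dfB, dfW), SSD = c(ssdAG, ssdAPWG, ssdWP),
    sigma2 = c(sigA, sigB, sigW), pct = pct)
  list(components = comp, phi = phi, flags = flags)
}

#' Analysis of molecular variance
#'
#' Distance-based AMOVA on squared pairwise differences with one level
#' (populations in total) or two hierarchical levels (populations within
#' groups), with unequal-sample-size coefficients.  Permutation p-values
#' use three schemes: individuals among populations overall (for
#' `phiST`), individuals among populations within groups (for `phiSC`),
#' and whole populations among groups (for `phiCT`); each p-value counts
#' the observed arrangement in numerator and denominator.
#'
#' @param aln Pooled [MtAlignment-class].
#' @param popmap A [PopulationMap-class].
#' @param scheme Optional grouping-scheme name for a two-level design.
#' @param nPermutations Number of permutations per scheme (0 disables
#'   testing).
#' @param seed Optional integer seed for the permutation stream.
#' @return An [AmovaResult-class].
#' @export
amova <- function(aln, popmap, scheme = NULL, nPermutations = 10000L, seed = NULL) {
  pop <- populationFactor(aln, popmap)
  if (nlevels(pop) < 2L) stopf("AMOVA needs >= 2 populations")
  D2 <- pairwiseDifferenceMatrix(aln)$diff
  group <- if (!is.null(scheme)) groupOf(popmap, scheme) else NULL
  obs <- amovaCore(D2, pop, group)
  p <- stats::setNames(rep(NA_real_, length(obs$phi)), names(obs$phi))
  nPermutations <- as.integer(nPermutations)
  if (nPermutations > 0L) {
    withSeed(seed, {
      if (is.null(group)) {
        perm <- vapply(seq_len(nPermutations), function(b)
          amovaCore(D2, sample(pop), NULL)$phi["phiST"], 0)
        p["phiST"] <- permPValue(perm, obs$phi["phiST"])
      } else {
        gFac <- factor(unname(group[levels(pop)]), exclude = NULL)
        # (1) individuals among populations overall -> Phi_ST
        permST <- vapply(seq_len(nPermutations), function(b)
          amovaCore(D2, sample(pop), group)$phi["phiST"], 0)
        p["phiST"] <- permPValue(permST, obs$phi["phiST"])
        # (2) individuals among populations within groups -> Phi_SC
        popLevels <- levels(pop)
        popGroup <- unname(group[popLevels])
        permSC <- vapply(seq_len(nPermutations), function(b) {
          newPop <- pop
          for (g in unique(popGroup)) {
            i <- which(popGroup[as.integer(pop)] == g)
            newPop[i] <- sample(pop[i])
          }
          amovaCore(D2, newPop, group)$phi["phiSC"]
        }, 0)
        p["phiSC"] <- permPValue(permSC, obs$phi["phiSC"])
        # (3) whole populations among groups -> Phi_CT
        permCT <- vapply(seq_len(nPermutations), function(b) {
          shuffled <- stats::setNames(sample(popGroup), popLevels)
          amovaCore(D2, pop, shuffled)$phi["phiCT"]
        }, 0)
        p["phiCT"] <- permPValue(permCT, obs$phi["phiCT"])
      }
    })
  }
  for (f in obs$flags) warnf("%s", f)
  methods::new("AmovaResult", components = obs$components, phi = obs$phi,
               p = p, nPermutations = nPermutations, flags = obs$flags)
}

#' Pairwise Phi-st between two population samples
#'
#' The among-population fraction of molecular variance from a one-level
#' AMOVA on the two samples, with a permutation test shuffling
#' individuals between the populations.
#'
#' @param alnA,alnB [MtAlignment-class] objects (each `n >= 2`), with
#'   disjoint sample IDs.
#' @param nPermutations Number of permutations (0 disables the test).
#' @param seed Optional integer seed.
#' @return List with `phiST` and `p` (NA when no permutations).
#' @export
phiStPair <- function(alnA, alnB, nPermutations = 0L, seed = NULL) {
  if (nSamples(alnA) < 2L || nSamples(alnB) < 2L)
    stopf("each population needs n >= 2")
  pooled <- poolAlignments(list(alnA, alnB))
  pop <- factor(rep(c("A", "B"), c(nSamples(alnA), nSamples(alnB))))
  D2 <- pairwiseDifferenceMatrix(pooled)$diff
  obs <- amovaCore(D2, pop, NULL)
  pv <- NA_real_
  if (nPermutations > 0L) {
    pv <- withSeed(seed, {
      perm <- vapply(seq_len(nPermutations), function(b)
        amovaCore(D2, sample(pop), NULL)$phi["phiST"], 0)
      permPValue(perm, obs$phi["phiST"])
    })
  }
  if (length(obs$flags)) for (f in obs$flags) warnf("%s", f)
  list(phiST = unname(obs$phi["phiST"]), p = pv)
}

#' Pairwise Phi-st matrix over all populations
#'
#' @param aln Pooled [MtAlignment-class].
#' @param popmap A [PopulationMap-class].
#' @return Symmetric matrix of pairwise Phi-st point estimates (zero
#'   diagonal), labeled by population.
#' @export
phiStMatrix <- function(aln, popmap) {
  pop <- populationFactor(aln, popmap)
  D2 <- pairwiseDifferenceMatrix(aln)$diff
  lev <- levels(pop)
  k <- length(lev)
  out <- matrix(0, k, k, dimnames = list(lev, lev))
  idx <- split(seq_along(pop), pop)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sel <- c(idx[[lev[i]]], idx[[lev[j]]])
    subPop <- factor(rep(c("a", "b"), c(length(idx[[lev[i]]]), length(idx[[lev[j]]]))))
    res <- amovaCore(D2[sel, sel, drop = FALSE], subPop, NULL)
    out[i, j] <- out[j, i] <- unname(res$phi["phiST"])
  }
  out
}

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA\n")
  df <- object@components
  df$pct <- sprintf("%.2f", df$pct)
  print(df, row.names = FALSE)
  for (nm in names(object@phi)) {
    cat(sprintf("  %s = %.4f", nm, object@phi[nm]))
    if (!is.na(object@p[nm])) cat(sprintf("  (P = %.4g)", object@p[nm]))
    cat("\n")
  }
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})
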