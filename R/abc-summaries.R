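#' @include stats-diversity.R stats-amova.R stats-mantel.R
NULL

#' Summary-statistic vector of a multi-deme dataset
#'
#' The fixed summary schema used identically for observed and simulated
#' data: per deme `n_hap` (haplotype count), `h`, `S`, `MPD`, `pi` and
#' Tajima's D; per deme pair the point-estimate `phist`, the mean
#' between-deme pairwise difference `dxy`, and the number of shared
#' haplotype classes.  Statistics undefined for a deme with `n < 2` are
#' `NaN` (flagged via attribute `"flagged"`).
#'
#' @param alnByDeme Named list of [MtAlignment-class] objects (>= 2
#'   demes), as returned by [simulateDataset()] or [splitByPopulation()].
#' @return Named numeric vector with a fixed name order determined by
#'   the deme names in list order.
#' @export
computeSummaryVector <- function(alnByDeme) {
  demes <- names(alnByDeme)
  if (length(demes) < 2L) stopf("summary vector needs >= 2 demes")
  pooled <- poolAlignments(alnByDeme)
  M <- alignmentMatrix(pooled)
  pw <- pairwiseFromMatrix(M)
  sizes <- vapply(alnByDeme, nSamples, 1L)
  idx <- split(seq_len(sum(sizes)), rep(demes, sizes))[demes]
  out <- numeric(0)
  flagged <- character(0)
  for (d in demes) {
    i <- idx[[d]]
    if (length(i) >= 2L) {
      dv <- diversitySummary(alnByDeme[[d]])
      vals <- c(dv@nHaplotypes / dv@n, dv@h, dv@S, dv@MPD, dv@pi,
                tajimasD(alnByDeme[[d]]))
    } else {
      vals <- rep(NaN, 6)
      flagged <- c(flagged, d)
    }
    names(vals) <- paste0(c("hapfrac_", "h_", "S_", "mpd_", "pi_", "tajd_"), d)
    out <- c(out, vals)
  }
  # pooled haplotype classes for sharing counts
  cls <- countHaplotypes(pooled)$assignment
  for (a in seq_len(length(demes) - 1L)) for (b in (a + 1L):length(demes)) {
    da <- demes[a]; db <- demes[b]
    ia <- idx[[da]]; ib <- idx[[db]]
    pairName <- paste0(da, "_", db)
    if (length(ia) >= 2L && length(ib) >= 2L) {
      sel <- c(ia, ib)
      subPop <- factor(rep(c("a", "b"), c(length(ia), length(ib))))
      phist <- unname(amovaCore(pw$diff[sel, sel], subPop, NULL)$phi["phiST"])
    } else {
      phist <- NaN
      flagged <- unique(c(flagged, pairName))
    }
    dxy <- if (length(ia) && length(ib)) mean(pw$diff[ia, ib]) else NaN
    shared <- length(intersect(unique(cls[ia]), unique(cls[ib])))
    vals <- c(phist, dxy, shared)
    names(vals) <- paste0(c("phist_", "dxy_", "shared_"), pairName)
    out <- c(out, vals)
  }
  if (length(flagged)) attr(out, "flagged") <- flagged
  out
}

#' Observed summary vector from data and metadata
#'
#' Pools populations into scenario demes under a grouping scheme whose
#' group labels are the deme names, then computes the same summary
#' schema as for simulated data.
#'
#' @param aln Pooled [MtAlignment-class] of the observed data.
#' @param popmap A [PopulationMap-class].
#' @param scheme Grouping scheme mapping populations to deme labels.
#' @param demes Optional character vector fixing the deme order (must
#'   match the scenario's deme order for schema compatibility).
#' @return Named numeric summary vector.
#' @export
observedSummaryVector <- function(aln, popmap, scheme, demes = NULL) {
  g <- groupOf(popmap, scheme)
  pop <- populationFactor(aln, popmap)
  demeOfSample <- unname(g[as.character(pop)])
  demes <- demes %||% unique(demeOfSample)
  alnByDeme <- lapply(demes, function(d) aln[which(demeOfSample == d)])
  names(alnByDeme) <- demes
  computeSummaryVector(alnByDeme)
}

#' Build an ABC reference table
#'
#' Simulates `nPerModel` datasets per scenario model (drawing parameters
#' from the priors), computes the summary vector for each, and stacks
#' rows into a balanced [ReferenceTable-class].  Failed simulations are
#' redrawn up to 5 times before erroring.  Deterministic given `seed`.
#'
#' @param set A [ScenarioSet-class].
#' @param nPerModel Simulations per model (>= 1).
#' @param mutationModel A [MutationModel-class].
#' @param sampleSizes Optional override of the set's per-deme sample
#'   sizes.
#' @param seed Optional integer seed.
#' @param verbose Log progress every 100 rows.
#' @return A [ReferenceTable-class].
#' @export
buildReferenceTable <- function(set, nPerModel, mutationModel,
                                sampleSizes = NULL, seed = NULL,
                                verbose = FALSE) {
  stopifnot(nPerModel >= 1L)
  labels <- names(set@models)
  withSeed(seed, {
    rows <- vector("list", length(labels) * nPerModel)
    parNames <- unique(unlist(lapply(set@models, function(m) m$priors$name)))
    k <- 0L
    for (lab in labels) {
      for (r in seq_len(nPerModel)) {
        res <- NULL
        for (try in 1:5) {
          res <- tryCatch({
            p <- drawOne(set@models[[lab]]$priors)
            model <- buildScenarioModel(set, lab, p, sampleSizes)
            s <- computeSummaryVector(simulateDataset(model, mutationModel))
            list(p = p, s = s)
          }, error = function(e) NULL)
          if (!is.null(res)) break
        }
        if (is.null(res))
          stopf("simulation failed 5 times for model '%s'", lab)
        k <- k + 1L
        pFull <- stats::setNames(rep(NA_real_, length(parNames)), parNames)
        pFull[names(res$p)] <- res$p
        rows[[k]] <- list(model = lab, p = pFull, s = res$s)
        if (verbose && k %% 100L == 0L)
          message(sprintf("reference table: %d / %d rows",
                          k, length(labels) * nPerModel))
      }
    }
    params <- as.data.frame(do.call(rbind, lapply(rows, function(x) x$p)))
    stats <- as.data.frame(do.call(rbind, lapply(rows, function(x) x$s)))
    referenceTable(vapply(rows, function(x) x$model, ""), params, stats)
  })
}
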