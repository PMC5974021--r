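#' @include sim-demography.R utils.R
NULL

# waiting time (years) to the next coalescence in a deme with k lineages,
# size N at current time, forward growth r per year, generation time g:
# hazard per year lam(s) = C(k,2) / (g * N * exp(-r s)); inverting the
# cumulative hazard for E ~ Exp(1) gives a closed form
.coalWait <- function(k, N, r, g, E) {
  ck <- k * (k - 1) / 2
  if (ck == 0) return(Inf)
  if (r == 0) return(E * g * N / ck)
  arg <- 1 + r * g * N * E / ck
  log(arg) / r
}

#' Simulate a genealogy under a structured demography
#'
#' Backward-in-time structured coalescent: within each deme, pairs
#' coalesce at rate `C(k,2)/N_f(t)` per generation; lineages migrate
#' between demes at the backward per-generation rates of the model's
#' migration edges; at a split time all lineages of the derived deme move
#' into the ancestral deme; exponential growth is handled by
#' time-rescaled (closed-form) waiting times.
#'
#' @param model A [DemographicModel-class].
#' @param seed Optional integer seed.
#' @return A [Genealogy-class] with node times in years.
#' @export
simulateGenealogy <- function(model, seed = NULL) {
  methods::validObject(model)
  withSeed(seed, .simulateGenealogy(model))
}

.simulateGenealogy <- function(model) {
  g <- model@generationTime
  demes <- model@demes
  ss <- model@sampleSizes[demes]
  n <- sum(ss)
  if (n < 2L) stopf("need at least 2 sampled lineages")
  epochsByDeme <- lapply(demes, function(d) {
    ep <- model@epochs[model@epochs$deme == d, , drop = FALSE]
    ep[order(ep$start), , drop = FALSE]
  })
  names(epochsByDeme) <- demes
  splits <- model@splits[order(model@splits$time), , drop = FALSE]
  mig <- model@migrations
  breaks <- sort(unique(c(model@epochs$start, splits$time,
                          mig$start, mig$end[is.finite(mig$end)])))
  breaks <- breaks[breaks > 0]

  tipDeme <- rep(demes, ss)
  tipLabel <- unlist(lapply(demes, function(d)
    if (ss[d] > 0) paste0(d, "_", seq_len(ss[d])) else character()),
    use.names = FALSE)
  # integer-coded state for the event loop
  D <- length(demes)
  epStart <- lapply(epochsByDeme, function(ep) ep$start)
  epN <- lapply(epochsByDeme, function(ep) ep$N)
  epG <- lapply(epochsByDeme, function(ep) ep$growth)
  spTime <- splits$time
  spDer <- match(splits$derived, demes)
  spAnc <- match(splits$ancestral, demes)
  migFrom <- match(mig$from, demes); migTo <- match(mig$to, demes)
  migRate <- mig$rate; migStart <- mig$start; migEnd <- mig$end
  linNode <- seq_len(n)
  linDeme <- match(tipDeme, demes)
  nodeTime <- numeric(2L * n - 1L)
  coalDeme <- character(n - 1L)
  parentOf <- integer(2L * n - 2L)   # indexed by child node (internal order: n+1..2n-1 in creation order)
  nextNode <- n + 1L
  t <- 0
  splitIdx <- 1L
  nSplits <- length(spTime)
  repeat {
    nl <- length(linNode)
    if (nl <= 1L) break
    # process any splits at exactly the current time
    while (splitIdx <= nSplits && spTime[splitIdx] <= t + 1e-9) {
      linDeme[linDeme == spDer[splitIdx]] <- spAnc[splitIdx]
      splitIdx <- splitIdx + 1L
    }
    tNext <- breaks[breaks > t + 1e-9][1]
    if (is.na(tNext)) tNext <- Inf
    # per-deme coalescence candidates (closed-form time-rescaled waits)
    ks <- tabulate(linDeme, D)
    waits <- rep(Inf, D)
    for (d in which(ks >= 2L)) {
      i <- sum(epStart[[d]] <= t + 1e-9)
      N <- epN[[d]][i] * exp(-epG[[d]][i] * (t - epStart[[d]][i]))
      waits[d] <- .coalWait(ks[d], N, epG[[d]][i], g, stats::rexp(1))
    }
    # migration: constant rates within the interval
    demeOut <- rep(0, D)
    if (length(migRate)) {
      act <- which(migStart <= t + 1e-9 & migEnd > t + 1e-9 & migRate > 0)
      for (j in act) demeOut[migFrom[j]] <- demeOut[migFrom[j]] + migRate[j]
    }
    outRate <- demeOut[linDeme]
    totMig <- sum(outRate) / g   # per year
    migWait <- if (totMig > 0) stats::rexp(1) / totMig else Inf
    wMin <- min(waits)
    if (is.infinite(wMin) && is.infinite(migWait) && is.infinite(tNext) &&
        splitIdx > nSplits)
      stopf("model validation error: %d lineages stranded with no coalescence, migration or split ahead",
            nl)
    if (min(wMin, migWait) + t >= tNext) { t <- tNext; next }
    if (wMin <= migWait) {
      t <- t + wMin
      d <- which.min(waits)
      here <- which(linDeme == d)
      pair <- sample(here, 2L)
      newNode <- nextNode; nextNode <- nextNode + 1L
      nodeTime[newNode] <- t
      coalDeme[newNode - n] <- demes[d]
      parentOf[linNode[pair]] <- newNode
      linNode[pair[1L]] <- newNode
      linNode <- linNode[-pair[2L]]
      linDeme <- linDeme[-pair[2L]]
    } else {
      t <- t + migWait
      i <- sample.int(nl, 1L, prob = outRate)
      d <- linDeme[i]
      act <- which(migStart <= t + 1e-9 & migEnd > t - 1e-9 & migFrom == d &
                     migRate > 0)
      if (length(act)) {
        dest <- if (length(act) == 1L) migTo[act] else
          migTo[sample(act, 1L, prob = migRate[act])]
        linDeme[i] <- dest
      }
    }
  }
  # renumber internal nodes to ape convention: root (oldest, created last) = n+1
  nInternal <- n - 1L
  created <- seq.int(n + 1L, 2L * n - 1L)       # creation order, increasing time
  apeId <- stats::setNames(c(seq_len(n), rev(created)), c(seq_len(n), created))
  edge <- cbind(parent = unname(apeId[as.character(parentOf)]),
                child = unname(apeId[as.character(seq_len(2L * n - 2L))]))
  newTime <- numeric(2L * n - 1L)
  newTime[unname(apeId[as.character(seq_len(2L * n - 1L))])] <- nodeTime
  newCoal <- character(nInternal)
  newCoal[unname(apeId[as.character(created)]) - n] <- coalDeme
  methods::new("Genealogy", nTips = n, edge = edge, nodeTime = newTime,
               tipLabel = tipLabel,
               tipDeme = stats::setNames(tipDeme, tipLabel),
               coalDeme = newCoal)
}

#' Time to the most recent common ancestor
#' @param genealogy A [Genealogy-class].
#' @return Root time in years.
#' @export
tmrca <- function(genealogy) max(genealogy@nodeTime)

#' Total branch length of a genealogy
#' @param genealogy A [Genealogy-class].
#' @return Sum of branch lengths in years.
#' @export
totalBranchLength <- function(genealogy) {
  sum(genealogy@nodeTime[genealogy@edge[, 1L]] -
        genealogy@nodeTime[genealogy@edge[, 2L]])
}

#' @describeIn Genealogy-class convert to an [ape::phylo] (branch lengths
#'   in years)
#' @param x A `Genealogy`.
#' @export
setMethod("asPhylo", "Genealogy", function(x) {
  phy <- list(edge = unname(x@edge),
              edge.length = x@nodeTime[x@edge[, 1L]] - x@nodeTime[x@edge[, 2L]],
              tip.label = x@tipLabel, Nnode = x@nTips - 1L)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
})

#' Drop mutations on a genealogy
#'
#' Poisson mutations on branches with partition-specific per-year rates;
#' finite sites: each mutation hits a uniformly chosen site of its
#' partition and substitutes the current base by one of the other three
#' (Jukes-Cantor).  Sites `1..sitesNoncoding` form the noncoding block,
#' the remainder the coding block; site order is exchangeable for all
#' downstream statistics.  The ancestral sequence is all-A.
#'
#' @param genealogy A [Genealogy-class].
#' @param mutationModel A [MutationModel-class].
#' @param seed Optional integer seed.
#' @return An [MtAlignment-class] of the tip sequences, named by tip
#'   label.
#' @export
dropMutations <- function(genealogy, mutationModel, seed = NULL) {
  L <- totalSites(mutationModel)
  if (L < 1L) stopf("mutation model covers zero sites")
  withSeed(seed, .dropMutations(genealogy, mutationModel))
}

.dropMutations <- function(gen, mm) {
  n <- gen@nTips
  L <- totalSites(mm)
  nNc <- mm@sitesNoncoding
  wNc <- mm@rateNoncoding * nNc
  wC <- mm@rateCoding * mm@sitesCoding
  edge <- gen@edge
  lens <- gen@nodeTime[edge[, 1L]] - gen@nodeTime[edge[, 2L]]
  nMut <- stats::rpois(nrow(edge), lens * (wNc + wC))
  seqs <- vector("list", 2L * n - 1L)
  root <- n + 1L
  seqs[[root]] <- rep.int(1L, L)    # ancestral all-A
  # preorder: parents appear before children when edges sorted by
  # decreasing parent time (root has the max time)
  ord <- order(gen@nodeTime[edge[, 1L]], decreasing = TRUE)
  bases <- 1:4
  for (e in ord) {
    par <- edge[e, 1L]; chd <- edge[e, 2L]
    s <- seqs[[par]]
    m <- nMut[e]
    if (m > 0L) {
      nc <- stats::rbinom(1L, m, if (wNc + wC > 0) wNc / (wNc + wC) else 0)
      sites <- c(if (nc > 0L) sample.int(nNc, nc, replace = TRUE) else integer(),
                 if (m - nc > 0L) nNc + sample.int(mm@sitesCoding, m - nc, replace = TRUE)
                 else integer())
      for (site in sites) {
        cur <- s[site]
        s[site] <- sample(bases[-cur], 1L)
      }
    }
    seqs[[chd]] <- s
  }
  chars <- c("A", "C", "G", "T")
  tipSeqs <- vapply(seq_len(n),
                    function(i) paste(chars[seqs[[i]]], collapse = ""), "")
  names(tipSeqs) <- gen@tipLabel
  mtAlignment(tipSeqs)
}

#' Simulate a dataset of per-population alignments
#'
#' Simulates one shared genealogy under the demography, drops mutations,
#' and splits the resulting alignment by deme.  Deterministic given
#' `seed`.
#'
#' @param model A [DemographicModel-class].
#' @param mutationModel A [MutationModel-class].
#' @param seed Optional integer seed.
#' @return Named list of [MtAlignment-class] objects, one per sampled
#'   deme, with attribute `"genealogy"` carrying the [Genealogy-class].
#' @export
simulateDataset <- function(model, mutationModel, seed = NULL) {
  withSeed(seed, {
    gen <- .simulateGenealogy(model)
    aln <- .dropMutations(gen, mutationModel)
    out <- lapply(names(model@sampleSizes)[model@sampleSizes > 0L], function(d) {
      aln[names(gen@tipDeme)[gen@tipDeme == d]]
    })
    names(out) <- names(model@sampleSizes)[model@sampleSizes > 0L]
    attr(out, "genealogy") <- gen
    out
  })
}

setMethod("show", "Genealogy", function(object) {
  cat(sprintf("Genealogy: %d tips, TMRCA = %.1f years\n",
              object@nTips, tmrca(object)))
  tab <- table(object@tipDeme)
  cat("  tips per deme:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})
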