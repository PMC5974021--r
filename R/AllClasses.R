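#' @importClassesFrom Biostrings DNAStringSet
#' @import methods
NULL

#' Aligned haploid mtDNA sequences
#'
#' An `MtAlignment` holds equal-length, uppercase, haploid mitochondrial
#' sequences over the alphabet `{A,C,G,T,N,-}`, with unique sample
#' identifiers.  It is the atomic input of every statistic in the package.
#' Use [mtAlignment()] or [readFastaAlignment()] to construct one; other
#' IUPAC ambiguity codes are converted to `N` on construction (with a
#' reported count), since downstream statistics treat only `{A,C,G,T}` as
#' informative.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width sequences with
#'   unique, non-empty names.
#' @seealso [sampleIDs()], [seqLength()], [nSamples()], [alignmentMatrix()]
#' @export
setClass("MtAlignment", slots = c(seqs = "DNAStringSet"))

setValidity("MtAlignment", function(object) {
  x <- object@seqs
  if (length(x) == 0L) return("alignment must contain at least one sequence")
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1L])[1L]
    return(sprintf("sequences are not aligned: record %d ('%s') has length %d, expected %d",
                   bad, names(x)[bad], w[bad], w[1L]))
  }
  nm <- names(x)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    return("all sequences must be named with sample IDs")
  if (anyDuplicated(nm))
    return(sprintf("duplicated sample IDs: %s",
                   paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  af <- Biostrings::alphabetFrequency(x, collapse = TRUE)
  allowed <- c("A", "C", "G", "T", "N", "-")
  extra <- af[setdiff(names(af), allowed)]
  if (sum(extra) > 0)
    return(sprintf("alphabet violation: %d characters outside {A,C,G,T,N,-} (%s)",
                   sum(extra), paste(names(extra)[extra > 0], collapse = ",")))
  TRUE
})

#' Sample-to-population and population-to-group structure
#'
#' Maps every sample to a population, populations to higher-level groups
#' under one or more named grouping schemes (e.g. `"language_family"`,
#' `"region"`), and optionally populations to geographic coordinates in
#' decimal degrees (WGS84).
#'
#' @slot samples Character vector of sample IDs.
#' @slot population Named character vector, sample ID -> population code.
#' @slot groupings Named list of grouping schemes; each scheme is a named
#'   character vector, population code -> group label.
#' @slot coords A data.frame with columns `population`, `lat`, `lon`
#'   (possibly zero rows).
#' @seealso [populationMap()], [readPopulationTable()]
#' @export
setClass("PopulationMap",
         slots = c(samples = "character", population = "character",
                   groupings = "list", coords = "data.frame"))

setValidity("PopulationMap", function(object) {
  if (length(object@samples) == 0L) return("no samples")
  if (anyDuplicated(object@samples))
    return(sprintf("duplicated sample IDs: %s",
                   paste(unique(object@samples[duplicated(object@samples)]), collapse = ", ")))
  miss <- setdiff(object@samples, names(object@population))
  if (length(miss))
    return(sprintf("samples without a population: %s", paste(miss, collapse = ", ")))
  pops <- unique(unname(object@population[object@samples]))
  for (scheme in names(object@groupings)) {
    g <- object@groupings[[scheme]]
    miss <- setdiff(pops, names(g))
    if (length(miss))
      return(sprintf("grouping '%s' is missing populations: %s",
                     scheme, paste(miss, collapse = ", ")))
  }
  cc <- object@coords
  if (nrow(cc)) {
    if (!all(c("population", "lat", "lon") %in% names(cc)))
      return("coords must have columns population, lat, lon")
    if (any(abs(cc$lat) > 90, na.rm = TRUE))
      return("latitude out of range [-90, 90]")
    if (any(abs(cc$lon) > 180, na.rm = TRUE))
      return("longitude out of range [-180, 180]")
  }
  TRUE
})

#' A parameterized structured demography
#'
#' Describes a matrilineal (haploid) demography: demes with piecewise
#' exponential-growth epochs of effective female size `N_f`, population
#' splits (backward-in-time merges of a derived deme into its ancestor),
#' and interval-bounded backward migration.  Times are in years before
#' present; sizes are effective numbers of females; growth rates are per
#' year (forward in time, so backward the size shrinks as
#' `N(t) = N_start * exp(-r * (t - t_start))`); migration rates are
#' per-lineage per-generation backward rates.
#'
#' @slot demes Character vector of deme labels.
#' @slot sampleSizes Named integer vector of haploid samples per deme.
#' @slot epochs data.frame with columns `deme`, `start` (years), `N`,
#'   `growth` (per year).
#' @slot splits data.frame with columns `time` (years), `derived`,
#'   `ancestral`; the derived deme's lineages merge into the ancestral
#'   deme at `time`.
#' @slot migrations data.frame with columns `from`, `to`, `rate`
#'   (per generation), `start`, `end` (years; `Inf` allowed).
#' @slot generationTime Numeric, years per generation.
#' @seealso [demographicModel()], [simulateGenealogy()]
#' @export
setClass("DemographicModel",
         slots = c(demes = "character", sampleSizes = "integer",
                   epochs = "data.frame", splits = "data.frame",
                   migrations = "data.frame", generationTime = "numeric"))

setValidity("DemographicModel", function(object) {
  d <- object@demes
  if (length(d) == 0L || anyDuplicated(d)) return("demes must be unique and non-empty")
  if (!setequal(names(object@sampleSizes), d)) return("sampleSizes must be named by deme")
  if (any(object@sampleSizes < 0L)) return("sample sizes must be >= 0")
  ep <- object@epochs
  if (!all(c("deme", "start", "N", "growth") %in% names(ep)))
    return("epochs needs columns deme, start, N, growth")
  if (!all(ep$deme %in% d)) return("epoch for unknown deme")
  if (any(ep$N <= 0)) return("all N_f must be > 0")
  if (any(ep$start < 0)) return("epoch start times must be >= 0")
  for (dd in d) if (!any(ep$deme == dd & ep$start == 0))
    return(sprintf("deme '%s' has no epoch starting at time 0", dd))
  sp <- object@splits
  if (nrow(sp)) {
    if (!all(c("time", "derived", "ancestral") %in% names(sp)))
      return("splits needs columns time, derived, ancestral")
    if (any(sp$time < 0)) return("split times must be >= 0")
    if (anyDuplicated(sp$derived)) return("a deme can be derived in at most one split")
    if (any(sp$derived == sp$ancestral)) return("a deme cannot split from itself")
    if (!all(c(sp$derived, sp$ancestral) %in% d)) return("split references unknown deme")
    # the ancestral deme must still exist (not itself merged) at the split time
    mergeTime <- structure(rep(Inf, length(d)), names = d)
    mergeTime[sp$derived] <- sp$time
    if (any(sp$time > mergeTime[sp$ancestral] + 1e-9))
      return("a deme receives lineages after it has merged")
  }
  surviving <- setdiff(d, if (nrow(sp)) sp$derived else character())
  if (length(surviving) != 1L) {
    # no single root: permissible only if open-ended migration connects all
    # surviving demes (e.g. an island model), so the coalescent terminates
    mig <- object@migrations
    ok <- FALSE
    if (nrow(mig)) {
      mig <- mig[is.infinite(mig$end) & mig$rate > 0, , drop = FALSE]
      if (nrow(mig)) {
        reach <- surviving[1L]
        repeat {
          nxt <- unique(c(reach,
                          mig$to[mig$from %in% reach], mig$from[mig$to %in% reach]))
          if (length(nxt) == length(reach)) break
          reach <- nxt
        }
        ok <- all(surviving %in% reach)
      }
    }
    if (!ok)
      return("demography must leave exactly one root deme (or connect surviving demes by open-ended migration)")
  }
  mig <- object@migrations
  if (nrow(mig)) {
    if (!all(c("from", "to", "rate", "start", "end") %in% names(mig)))
      return("migrations needs columns from, to, rate, start, end")
    if (any(mig$rate < 0)) return("migration rates must be >= 0")
    if (!all(c(mig$from, mig$to) %in% d)) return("migration references unknown deme")
    if (any(mig$end <= mig$start)) return("migration end must exceed start")
  }
  if (length(object@generationTime) != 1L || object@generationTime <= 0)
    return("generationTime must be a single positive number")
  TRUE
})

#' Two-partition mutation model
#'
#' Partition-specific substitution rates for the coding and noncoding
#' compartments of the mtDNA genome, in substitutions per site per year.
#' The default rates are 1.708e-8 (coding) and 9.883e-8 (noncoding), and
#' the default full-genome partition is 15,447 coding + 1,122 noncoding
#' sites.  Mutations follow a finite-sites Jukes-Cantor scheme.
#'
#' @slot rateCoding,rateNoncoding Substitutions per site per year.
#' @slot sitesCoding,sitesNoncoding Number of sites per partition; the
#'   alignment length is their sum.
#' @seealso [mtMutationModel()], [dropMutations()]
#' @export
setClass("MutationModel",
         slots = c(rateCoding = "numeric", rateNoncoding = "numeric",
                   sitesCoding = "integer", sitesNoncoding = "integer"))

setValidity("MutationModel", function(object) {
  if (object@rateCoding < 0 || object@rateNoncoding < 0) return("rates must be >= 0")
  if (object@sitesCoding < 0L || object@sitesNoncoding < 0L) return("site counts must be >= 0")
  if (object@sitesCoding + object@sitesNoncoding < 1L) return("partition must cover at least one site")
  TRUE
})

#' A simulated matrilineal genealogy
#'
#' Rooted binary tree over sampled lineages with node times in years
#' (tips at 0) and the deme occupied by each coalescing pair.  Convert to
#' an [ape::phylo] with [asPhylo()].
#'
#' @slot nTips Number of sampled lineages.
#' @slot edge Two-column integer matrix (parent, child), ape numbering
#'   (tips `1..n`, root `n+1`).
#' @slot nodeTime Numeric vector of node times in years, length `2n-1`.
#' @slot tipLabel,tipDeme Character vectors over tips.
#' @slot coalDeme Deme in which each internal node's coalescence happened.
#' @export
setClass("Genealogy",
         slots = c(nTips = "integer", edge = "matrix", nodeTime = "numeric",
                   tipLabel = "character", tipDeme = "character",
                   coalDeme = "character"))

setValidity("Genealogy", function(object) {
  n <- object@nTips
  if (n < 2L) return("a genealogy needs at least 2 tips")
  if (length(object@nodeTime) != 2L * n - 1L) return("nodeTime has wrong length")
  if (any(abs(object@nodeTime[seq_len(n)]) > 1e-9)) return("tips must be at time 0")
  pt <- object@nodeTime[object@edge[, 1L]]
  ct <- object@nodeTime[object@edge[, 2L]]
  if (any(pt < ct - 1e-9)) return("parent nodes must be older than their children")
  TRUE
})

#' ABC reference table
#'
#' Rows of (model label, drawn parameters, summary statistics): the
#' substrate of random-forest ABC.  Balanced by construction (equal rows
#' per model) when built with [buildReferenceTable()].
#'
#' @slot model Factor of model labels, one per row.
#' @slot params data.frame of drawn parameters (NA where a parameter does
#'   not apply to a model).
#' @slot stats data.frame of summary statistics (fixed column order).
#' @slot lda Optional list describing a fitted LDA projection (see
#'   [appendLdaAxes()]); empty list if absent.
#' @export
setClass("ReferenceTable",
         slots = c(model = "factor", params = "data.frame",
                   stats = "data.frame", lda = "list"))

setValidity("ReferenceTable", function(object) {
  n <- length(object@model)
  if (n == 0L) return("reference table is empty")
  if (nrow(object@params) != n || nrow(object@stats) != n)
    return("model, params and stats must have the same number of rows")
  TRUE
})

#' Result of an AMOVA
#'
#' Variance components from the Excoffier-style sum-of-squared-distance
#' decomposition, their percentages of total (unclamped: components may be
#' negative), Phi statistics and permutation p-values.
#'
#' @slot components data.frame with columns `source`, `df`, `SSD`,
#'   `sigma2`, `pct`.
#' @slot phi Named numeric vector (`phiST`, and for two-level designs
#'   `phiSC`, `phiCT`).
#' @slot p Named numeric vector of permutation p-values (NA when no
#'   permutations were run).
#' @slot nPermutations Integer.
#' @slot flags Character vector of warnings (negative components,
#'   degenerate strata).
#' @export
setClass("AmovaResult",
         slots = c(components = "data.frame", phi = "numeric", p = "numeric",
                   nPermutations = "integer", flags = "character"))

#' Result of a Mantel test
#'
#' @slot r Pearson correlation over off-diagonal entries.
#' @slot p One-tailed (greater) permutation p-value, observed arrangement
#'   included in numerator and denominator.
#' @slot nPermutations Number of random permutations (or the number of
#'   enumerated relabelings in exact mode).
#' @slot exact Logical, whether all relabelings were enumerated.
#' @export
setClass("MantelResult",
         slots = c(r = "numeric", p = "numeric", nPermutations = "integer",
                   exact = "logical"))

#' Per-population diversity summary
#'
#' Sample size, haplotype count, segregating sites, haplotype (gene)
#' diversity, mean pairwise differences and nucleotide diversity, each
#' with its standard estimator SD.
#'
#' @slot n,nHaplotypes,S Integers.
#' @slot h,hSD,MPD,MPDSD,pi,piSD,Leff Numerics; `Leff` is the mean number
#'   of comparable sites over pairs (pairwise deletion), so
#'   `pi = MPD / Leff`.
#' @export
setClass("DiversitySummary",
         slots = c(n = "integer", nHaplotypes = "integer", S = "integer",
                   h = "numeric", hSD = "numeric", MPD = "numeric",
                   MPDSD = "numeric", pi = "numeric", piSD = "numeric",
                   Leff = "numeric"))

#' A set of demographic scenarios with parameter priors
#'
#' Named collection of (model label, prior specification, model builder);
#' the unit of ABC model choice.  Construct with [scenarioSet()],
#' [ctOriginModels()] or [languageFamilyModels()].
#'
#' @slot name Scenario-set name.
#' @slot models Named list; each element has `$priors` (data.frame with
#'   columns `name`, `dist` in `{"uniform","loguniform","fixed"}`, `min`,
#'   `max`) and `$build` (function mapping a named parameter vector to a
#'   [DemographicModel-class]).
#' @slot sampleSizes Named integer vector of default haploid sample sizes
#'   per deme.
#' @slot generationTime Years per generation used by the builders.
#' @export
setClass("ScenarioSet",
         slots = c(name = "character", models = "list",
                   sampleSizes = "integer", generationTime = "numeric"))

setValidity("ScenarioSet", function(object) {
  if (length(object@models) == 0L) return("scenario set has no models")
  if (is.null(names(object@models)) || anyDuplicated(names(object@models)))
    return("model labels must be unique and non-empty")
  for (lab in names(object@models)) {
    m <- object@models[[lab]]
    if (!is.function(m$build)) return(sprintf("model '%s' has no build function", lab))
    pr <- m$priors
    if (!is.data.frame(pr) || !all(c("name", "dist", "min", "max") %in% names(pr)))
      return(sprintf("model '%s': priors must be a data.frame with name, dist, min, max", lab))
    if (!all(pr$dist %in% c("uniform", "loguniform", "fixed")))
      return(sprintf("model '%s': unknown prior distribution", lab))
    if (any(pr$min > pr$max)) return(sprintf("model '%s': prior min > max", lab))
    if (any(pr$dist == "loguniform" & pr$min <= 0))
      return(sprintf("model '%s': log-uniform priors need min > 0", lab))
  }
  TRUE
})

#' Result of random-forest ABC model choice
#'
#' @slot votes Named numeric vector of tree-vote fractions, summing to 1.
#' @slot selected Label of the winning model (argmax of votes).
#' @slot posteriorProbability Estimated posterior probability that the
#'   selected model is the true one, from a regression forest on the
#'   out-of-bag misclassification indicator evaluated at the observed
#'   summary vector.
#' @slot priorErrorRate data.frame with columns `trees`, `error`:
#'   out-of-bag misclassification rate as the forest grows.
#' @slot confusion Out-of-bag confusion matrix (rows: true model).
#' @export
setClass("ModelChoiceResult",
         slots = c(votes = "numeric", selected = "character",
                   posteriorProbability = "numeric",
                   priorErrorRate = "data.frame", confusion = "matrix"))

#' Posterior parameter estimates from regression forests
#'
#' @slot estimates data.frame with columns `parameter`, `mean`, `median`,
#'   `q025`, `q975`.
#' @slot model The model label the estimates condition on.
#' @export
setClass("ParameterEstimate",
         slots = c(estimates = "data.frame", model = "character"))
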