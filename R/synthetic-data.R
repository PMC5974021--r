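#' @include sim-coalescent.R io-metadata.R
NULL

#' Simulate a finite-island dataset
#'
#' Symmetric island model: `nDemes` demes of constant haploid size `N`,
#' each lineage emigrating backward at total rate `Nm / N` per
#' generation (uniformly to the other demes), with no splits.  The
#' classical expectation for the among-deme fixation index is
#' `1 / (1 + 2Nm)` in the many-demes limit.
#'
#' @param nDemes Number of demes.
#' @param samplesPerDeme Haploid samples per deme.
#' @param N Effective female size per deme.
#' @param Nm Scaled migration (migrants per deme per generation).
#' @param L Alignment length in sites (mutation model rescaled from the
#'   full-genome two-partition defaults).
#' @param generationTime Years per generation.
#' @param seed Optional integer seed (identical datasets under identical
#'   seeds).
#' @return List with `alignment` (pooled [MtAlignment-class]), `popmap`
#'   (a [PopulationMap-class]), `alignments` (per-deme list) and
#'   `truth` (the generating parameters).
#' @export
generateIslandDataset <- function(nDemes = 8L, samplesPerDeme = 20L, N = 1000,
                                  Nm = 0.5, L = 2000L, generationTime = 25,
                                  seed = NULL) {
  stopifnot(nDemes >= 2L, samplesPerDeme >= 1L, N > 0, Nm > 0)
  demes <- sprintf("island%02d", seq_len(nDemes))
  m <- Nm / N
  pairs <- expand.grid(from = demes, to = demes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  mig <- data.frame(from = pairs$from, to = pairs$to,
                    rate = m / (nDemes - 1), start = 0, end = Inf)
  model <- demographicModel(
    demes, stats::setNames(rep(as.integer(samplesPerDeme), nDemes), demes),
    stats::setNames(rep(N, nDemes), demes), migrations = mig,
    generationTime = generationTime)
  mut <- scaleMutationModel(mtMutationModel(), L)
  alns <- simulateDataset(model, mut, seed = seed)
  pooled <- poolAlignments(alns)
  popmap <- populationMap(
    sampleIDs(pooled),
    rep(demes, vapply(alns, nSamples, 1L)))
  list(alignment = pooled, popmap = popmap, alignments = alns,
       truth = list(nDemes = nDemes, N = N, Nm = Nm, m = m, L = L))
}

#' Simulate a hierarchically structured study-like fixture
#'
#' Emulates the shape of a multi-population mtDNA survey: groups of
#' populations (e.g. language families) whose member populations
#' diverged recently, while the groups themselves diverged much earlier,
#' so the among-group variance stratum is positive by construction when
#' `groupSplit >> popSplit`.  Two grouping schemes are attached:
#' `family` matches the generating hierarchy; `region` cuts across it
#' (population j of every group shares a region), so region explains
#' essentially nothing.  Synthetic coordinates (family-clustered, in
#' Thailand-like ranges) support great-circle/Mantel analyses.
#'
#' @param nGroups Number of groups (default 4).
#' @param popsPerGroup Populations per group (default 4).
#' @param samplesPerPop Haploid samples per population (default 20).
#' @param N Effective female size per population; the default 1,500 is
#'   calibrated so that full-length (`L = 16569`) per-population mean
#'   pairwise differences average in the 30-39 range typical of complete
#'   mtDNA surveys (a single non-recombining locus, so individual
#'   datasets vary widely around that).
#' @param popSplit Years before present at which populations within a
#'   group diverged (default 2,000).
#' @param groupSplit Years at which groups diverged (default 20,000).
#' @param L Alignment length in sites.
#' @param generationTime Years per generation.
#' @param seed Optional integer seed.
#' @return List with `alignment`, `popmap` (schemes `family`, `region`,
#'   plus coordinates), `alignments` (per population) and `truth`.
#' @export
generateStudyLikeFixture <- function(nGroups = 4L, popsPerGroup = 4L,
                                     samplesPerPop = 20L, N = 1500,
                                     popSplit = 2000, groupSplit = 20000,
                                     L = 2000L, generationTime = 25,
                                     seed = NULL) {
  stopifnot(nGroups >= 1L, popsPerGroup >= 1L, samplesPerPop >= 1L,
            groupSplit > popSplit)
  pops <- character(0); splits <- NULL
  for (gI in seq_len(nGroups)) {
    gp <- sprintf("G%dP%d", gI, seq_len(popsPerGroup))
    pops <- c(pops, gp)
    if (popsPerGroup > 1L)
      splits <- rbind(splits, data.frame(time = popSplit, derived = gp[-1L],
                                         ancestral = gp[1L]))
    if (gI > 1L)
      splits <- rbind(splits, data.frame(time = groupSplit, derived = gp[1L],
                                         ancestral = "G1P1"))
  }
  model <- demographicModel(
    pops, stats::setNames(rep(as.integer(samplesPerPop), length(pops)), pops),
    stats::setNames(rep(N, length(pops)), pops), splits = splits,
    generationTime = generationTime)
  mut <- scaleMutationModel(mtMutationModel(), L)
  alns <- simulateDataset(model, mut, seed = seed)
  pooled <- poolAlignments(alns)
  family <- stats::setNames(rep(sprintf("family%d", seq_len(nGroups)),
                                each = popsPerGroup), pops)
  region <- stats::setNames(rep(sprintf("region%d", seq_len(popsPerGroup)),
                                times = nGroups), pops)
  gIdx <- rep(seq_len(nGroups), each = popsPerGroup)
  pIdx <- rep(seq_len(popsPerGroup), times = nGroups)
  coords <- data.frame(population = pops,
                       lat = 12 + 2.0 * gIdx + 0.3 * pIdx,
                       lon = 98 + 1.5 * pIdx + 0.2 * gIdx)
  popmap <- populationMap(
    sampleIDs(pooled), rep(pops, vapply(alns, nSamples, 1L)),
    groupings = list(family = family, region = region), coords = coords)
  list(alignment = pooled, popmap = popmap, alignments = alns,
       truth = list(nGroups = nGroups, popsPerGroup = popsPerGroup, N = N,
                    popSplit = popSplit, groupSplit = groupSplit, L = L))
}

#' Simulate an observed-like dataset under a scenario model
#'
#' Draws (or accepts) parameters for one scenario model, simulates a
#' dataset at the scenario's sample sizes, and returns it with the
#' ground-truth parameters — the input for model-recovery and
#' parameter-recovery experiments.
#'
#' @param set A [ScenarioSet-class].
#' @param label Model label.
#' @param mutationModel A [MutationModel-class].
#' @param params Optional fixed parameter vector; drawn from the priors
#'   when omitted.
#' @param sampleSizes Optional sample-size override.
#' @param seed Optional integer seed.
#' @return List with `alignments` (per-deme), `summary` (the summary
#'   vector) and `truth` (parameters).
#' @export
generateScenarioFixture <- function(set, label, mutationModel, params = NULL,
                                    sampleSizes = NULL, seed = NULL) {
  withSeed(seed, {
    p <- params %||% drawOne(set@models[[label]]$priors)
    model <- buildScenarioModel(set, label, p, sampleSizes)
    alns <- simulateDataset(model, mutationModel)
    list(alignments = alns, summary = computeSummaryVector(alns), truth = p)
  })
}
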