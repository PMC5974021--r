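#' @include synthetic-data.R abc-rf.R
NULL

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates the stages end to end: load (or synthesize) data,
#' descriptive statistics (diversity table, AMOVA, Mantel when
#' coordinates are present), scenario construction, reference-table
#' simulation, random-forest model choice, and parameter estimation for
#' the selected model.  All randomness flows from one master seed via
#' fixed per-stage offsets; rerunning with the same configuration and
#' seed reproduces the report exactly.
#'
#' @param config A named list or the path of a YAML file with fields:
#'   \describe{
#'     \item{seed}{Integer master seed (required).}
#'     \item{out_dir}{Output directory for artifacts (required).}
#'     \item{fasta, pops}{Paths of the observed alignment and metadata
#'       table; omit to use a synthetic fixture.}
#'     \item{fixture}{List of arguments for
#'       [generateScenarioFixture()]-based synthetic observed data:
#'       `scenario` (`"ct_origins"` or `"language_families"`), `label`,
#'       and optional `sample_sizes` (named list).}
#'     \item{grouping}{Grouping scheme for the AMOVA / deme pooling
#'       (observed-data mode).}
#'     \item{scenario}{Scenario template name (default `"ct_origins"`)
#'       or path of a YAML scenario config.}
#'     \item{n_per_model}{Simulations per model (default 300).}
#'     \item{n_trees}{Forest size (default 200).}
#'     \item{n_permutations}{Permutations for AMOVA/Mantel (default
#'       1000).}
#'     \item{seq_length}{Simulated alignment length (default 2000).}
#'     \item{estimate}{Logical: run parameter estimation for the
#'       selected model (default TRUE when enough rows).}
#'   }
#' @param resume Reuse an existing reference-table CSV in `out_dir`
#'   instead of re-simulating (the expensive stage); lighter stages are
#'   recomputed.
#' @return The run report (named list), invisibly also written as
#'   `report.json` in `out_dir`.
#' @export
runPipeline <- function(config, resume = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("validation error: config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg$seed)) stopf("validation error: config$seed is required")
  if (is.null(cfg$out_dir)) stopf("validation error: config$out_dir is required")
  for (f in c("fasta", "pops"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stopf("validation error: file not found: %s", cfg[[f]])
  if (is.character(cfg$scenario) && grepl("\\.ya?ml$", cfg$scenario) &&
      !file.exists(cfg$scenario))
    stopf("validation error: scenario file not found: %s", cfg$scenario)
  seed <- as.integer(cfg$seed)
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nPerModel <- as.integer(cfg$n_per_model %||% 300L)
  nTrees <- as.integer(cfg$n_trees %||% 200L)
  nPerms <- as.integer(cfg$n_permutations %||% 1000L)
  L <- as.integer(cfg$seq_length %||% 2000L)
  log <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  cfgHash <- configHash(cfg)
  report <- list(config_hash = cfgHash, seed = seed)

  # stage: scenario set
  set <- if (is.character(cfg$scenario) && grepl("\\.ya?ml$", cfg$scenario %||% "")) {
    readScenarioConfig(cfg$scenario)
  } else switch(cfg$scenario %||% "ct_origins",
                ct_origins = ctOriginModels(),
                language_families = languageFamilyModels(),
                stopf("validation error: unknown scenario '%s'", cfg$scenario))
  mut <- scaleMutationModel(mtMutationModel(), L)

  # stage: data
  if (!is.null(cfg$fasta)) {
    aln <- readFastaAlignment(cfg$fasta)
    popmap <- readPopulationTable(cfg$pops)
    demeScheme <- cfg$grouping %||% groupingSchemes(popmap)[1]
    observed <- observedSummaryVector(aln, popmap, demeScheme,
                                      demes = names(set@sampleSizes))
    sampleSizes <- NULL
    report$data <- list(mode = "observed", n = nSamples(aln), L = seqLength(aln))
  } else {
    fx <- cfg$fixture %||% list()
    label <- fx$label %||% names(set@models)[1]
    ss <- if (!is.null(fx$sample_sizes)) {
      v <- unlist(fx$sample_sizes); storage.mode(v) <- "integer"; v
    } else set@sampleSizes
    fixture <- generateScenarioFixture(set, label, mut, sampleSizes = ss,
                                       seed = seed + 1L)
    alnByDeme <- fixture$alignments
    aln <- poolAlignments(alnByDeme)
    pops <- rep(names(alnByDeme), vapply(alnByDeme, nSamples, 1L))
    popmap <- populationMap(sampleIDs(aln), pops)
    observed <- fixture$summary
    sampleSizes <- ss
    report$data <- list(mode = "synthetic", generating_model = label,
                        truth = as.list(fixture$truth),
                        n = nSamples(aln), L = seqLength(aln))
    log("data", "synthetic fixture under model '%s': %d sequences x %d sites",
        label, nSamples(aln), seqLength(aln))
  }

  # stage: descriptive statistics
  log("stats", "diversity / AMOVA (%d permutations)", nPerms)
  div <- diversityTable(aln, popmap)
  utils::write.csv(div, file.path(outDir, "diversity.csv"), row.names = FALSE)
  amv <- if (length(populations(popmap)) >= 2L) {
    suppressWarnings(amova(aln, popmap, nPermutations = nPerms, seed = seed + 2L))
  } else NULL
  report$stats <- list(
    diversity = div,
    amova = if (!is.null(amv)) list(components = amv@components,
                                    phi = as.list(amv@phi), p = as.list(amv@p)))
  if (nrow(popmap@coords) && length(populations(popmap)) >= 4L) {
    gcd <- greatCircleMatrix(popmap)
    gen <- phiStMatrix(aln, popmap)
    mt <- mantelTest(gen, gcd, nPermutations = nPerms, seed = seed + 3L)
    report$stats$mantel <- list(r = mt@r, p = mt@p)
  }

  # stage: reference table (resumable)
  refPath <- file.path(outDir, "reftable.csv")
  if (resume && file.exists(refPath)) {
    log("reftable", "reusing %s", refPath)
    ref <- readReferenceTable(refPath)
  } else {
    log("reftable", "simulating %d x %d rows", length(set@models), nPerModel)
    ref <- buildReferenceTable(set, nPerModel, mut, sampleSizes = sampleSizes,
                               seed = seed + 4L)
    writeReferenceTable(ref, refPath)
  }

  # stage: model choice
  log("abc", "LDA + random forest (%d trees)", nTrees)
  ref <- appendLdaAxes(ref)
  fit <- fitModelChoice(ref, nTrees = nTrees, seed = seed + 5L)
  mc <- predictModel(fit, observed)
  report$model_choice <- list(
    votes = as.list(mc@votes), selected = mc@selected,
    posterior_probability = mc@posteriorProbability,
    prior_error_rate = fit$priorErrorRate,
    confusion = as.data.frame.matrix(as.matrix(fit$confusion)))

  # stage: parameter estimation
  doEst <- cfg$estimate %||% TRUE
  if (isTRUE(doEst) && sum(ref@model == mc@selected) >= 200L) {
    log("estimate", "posterior quantiles for model '%s'", mc@selected)
    est <- estimateParameters(ref, mc@selected, observed, nTrees = nTrees,
                              seed = seed + 6L)
    report$estimates <- est@estimates
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(report)
}

# stable hash of the analytic configuration (order-normalized; the
# output location does not affect the result, so it is excluded)
configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg$out_dir <- NULL
  cfg <- cfg[order(names(cfg))]
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
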