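#' @include sim-demography.R utils.R
NULL

#' Construct a custom scenario set
#'
#' @param name Name of the set.
#' @param models Named list; each element is a list with `priors` (a
#'   data.frame with columns `name`, `dist` in
#'   `{"uniform","loguniform","fixed"}`, `min`, `max`) and `build` (a
#'   function taking a named parameter vector and returning a
#'   [DemographicModel-class]).
#' @param sampleSizes Named integer vector of default haploid sample
#'   sizes per deme.
#' @param generationTime Years per generation.
#' @return A [ScenarioSet-class].
#' @export
scenarioSet <- function(name, models, sampleSizes, generationTime = 25) {
  ss <- sampleSizes; storage.mode(ss) <- "integer"
  methods::new("ScenarioSet", name = name, models = models,
               sampleSizes = ss, generationTime = generationTime)
}

#' @describeIn ScenarioSet-class the model labels
#' @param x A `ScenarioSet`.
#' @export
setMethod("modelLabels", "ScenarioSet", function(x) names(x@models))

prior <- function(name, dist, min, max = min)
  data.frame(name = name, dist = dist, min = min, max = max)

drawOne <- function(pr) {
  vals <- vapply(seq_len(nrow(pr)), function(i) {
    switch(pr$dist[i],
           uniform = stats::runif(1, pr$min[i], pr$max[i]),
           loguniform = exp(stats::runif(1, log(pr$min[i]), log(pr$max[i]))),
           fixed = pr$min[i])
  }, 0)
  stats::setNames(vals, pr$name)
}

#' Draw parameters from a scenario's priors
#'
#' @param set A [ScenarioSet-class].
#' @param label A model label of the set.
#' @param seed Optional integer seed (reproducible draw).
#' @return Named numeric vector of parameter values within prior support.
#' @export
drawParameters <- function(set, label, seed = NULL) {
  if (!label %in% names(set@models))
    stopf("unknown model label '%s' (available: %s)", label,
          paste(names(set@models), collapse = ", "))
  withSeed(seed, drawOne(set@models[[label]]$priors))
}

#' Build the DemographicModel of a scenario at given parameter values
#'
#' @inheritParams drawParameters
#' @param params Named numeric vector (as from [drawParameters()]).
#' @param sampleSizes Optional override of the set's default sample sizes.
#' @return A validated [DemographicModel-class].
#' @export
buildScenarioModel <- function(set, label, params, sampleSizes = NULL) {
  if (!label %in% names(set@models)) stopf("unknown model label '%s'", label)
  m <- set@models[[label]]$build(params, sampleSizes %||% set@sampleSizes,
                                 set@generationTime)
  methods::validObject(m)
  m
}

## ---- CT-origin scenarios --------------------------------------------------

# default priors shared by the three CT-origin models: effective female
# sizes log-uniform [1e2, 1e5]; the recent CT founding split uniform
# [0.5, 3] kya (southward Tai-Kadai expansion); the deep split between
# the southern-Chinese TK source and the local AA deme uniform [5, 30]
# kya; per-year growth rates uniform [0, 1e-3]; continuous-migration
# rate log-uniform [1e-6, 1e-2] per generation
ctBasePriors <- function() rbind(
  prior("N_TK", "loguniform", 1e2, 1e5),
  prior("N_AA", "loguniform", 1e2, 1e5),
  prior("N_CT", "loguniform", 1e2, 1e5),
  prior("r_TK", "uniform", 0, 1e-3),
  prior("r_AA", "uniform", 0, 1e-3),
  prior("r_CT", "uniform", 0, 1e-3),
  prior("T_CT", "uniform", 500, 3000),
  prior("T_ROOT", "uniform", 5000, 30000))

ctBuilder <- function(ctAncestor, migration = FALSE) {
  force(ctAncestor); force(migration)
  function(p, ss, g) {
    epochs <- data.frame(
      deme = c("TK", "AA", "CT"), start = 0,
      N = unname(p[c("N_TK", "N_AA", "N_CT")]),
      growth = unname(p[c("r_TK", "r_AA", "r_CT")]))
    splits <- data.frame(
      time = c(unname(p["T_CT"]), unname(p["T_ROOT"])),
      derived = c("CT", "AA"), ancestral = c(ctAncestor, "TK"))
    mig <- NULL
    if (migration && p["m"] > 0) {
      mig <- data.frame(from = c("CT", "AA"), to = c("AA", "CT"),
                        rate = unname(p["m"]), start = 0,
                        end = unname(p["T_CT"]))
    }
    demographicModel(c("TK", "AA", "CT"), ss[c("TK", "AA", "CT")], epochs,
                     splits = splits, migrations = mig, generationTime = g)
  }
}

#' The three demographic scenarios for the origin of central Thai groups
#'
#' Three models over demes `TK` (the southern-Chinese Tai-Kadai source),
#' `AA` (local Austroasiatic residents) and `CT` (central Thai):
#' \describe{
#'   \item{demic}{CT splits from the TK source; no AA gene flow
#'     (a migration of people who become the CT ancestors).}
#'   \item{cultural}{CT splits from the AA deme (language shift without
#'     gene flow: demic and cultural differ only in the CT founding
#'     ancestor).}
#'   \item{continuous}{CT splits from the TK source with ongoing
#'     symmetric migration `CT <-> AA` since the split; with migration
#'     rate 0 this collapses to the demic topology.}
#' }
#' In all models AA merges with TK at the deep root split, and all demes
#' carry post-split exponential growth parameters.
#'
#' @param priorConfig Optional named list overriding individual priors:
#'   each element a list/row with `dist`, `min`, `max` for a parameter
#'   name.
#' @param sampleSizes Named integer vector (default `TK=150, AA=150,
#'   CT=210` haploid genomes, stand-ins for the pooled study groups).
#' @param generationTime Years per generation (default 25).
#' @return A [ScenarioSet-class] with labels `demic`, `cultural`,
#'   `continuous`.
#' @export
ctOriginModels <- function(priorConfig = NULL,
                           sampleSizes = c(TK = 150L, AA = 150L, CT = 210L),
                           generationTime = 25) {
  base <- applyPriorConfig(ctBasePriors(), priorConfig)
  contPriors <- applyPriorConfig(
    rbind(ctBasePriors(), prior("m", "loguniform", 1e-6, 1e-2)), priorConfig)
  models <- list(
    demic = list(priors = base, build = ctBuilder("TK", migration = FALSE)),
    cultural = list(priors = base, build = ctBuilder("AA", migration = FALSE)),
    continuous = list(priors = contPriors, build = ctBuilder("TK", migration = TRUE)))
  scenarioSet("ct_origins", models, sampleSizes, generationTime)
}

applyPriorConfig <- function(pr, cfg) {
  if (is.null(cfg)) return(pr)
  for (nm in names(cfg)) {
    i <- which(pr$name == nm)
    if (!length(i)) next
    spec <- cfg[[nm]]
    if (!is.null(spec$dist)) pr$dist[i] <- spec$dist
    if (!is.null(spec$min)) pr$min[i] <- spec$min
    if (!is.null(spec$max)) pr$max[i] <- spec$max
    if (!pr$dist[i] %in% c("uniform", "loguniform", "fixed"))
      stopf("malformed prior for '%s': unknown distribution '%s'", nm, pr$dist[i])
    if (pr$min[i] > pr$max[i]) stopf("malformed prior for '%s': min > max", nm)
  }
  pr
}

## ---- language-family scenarios -------------------------------------------

# topologies over demes AA, AN, ST, TK; each row: derived deme and the
# split index (1 = shallowest) at which it merges into TK (used as the
# bookkeeping root lineage)
lfTopologies <- list(
  model1 = data.frame(derived = c("AN", "ST", "AA"), level = 1:3),  # (((TK,AN),ST),AA)
  model2 = data.frame(derived = c("AN", "AA", "ST"), level = 1:3),  # (((TK,AN),AA),ST)
  model3 = data.frame(derived = c("ST", "AA", "AN"), level = 1:3),  # ((AA,(ST,TK)),AN)
  model4 = data.frame(derived = c("AA", "ST", "AN"), level = 1:3),  # (((AA,TK),ST),AN)
  model5 = data.frame(derived = c("AA", "ST", "AN"), level = c(1, 1, 2)))  # trifurcation

lfPriors <- function(trifurcation = FALSE) {
  pr <- rbind(
    prior("N_AA", "loguniform", 1e2, 1e5),
    prior("N_AN", "loguniform", 1e2, 1e5),
    prior("N_ST", "loguniform", 1e2, 1e5),
    prior("N_TK", "loguniform", 1e2, 1e5),
    prior("T1", "uniform", 3000, 8000))
  if (trifurcation) rbind(pr, prior("DT2", "uniform", 500, 8000))
  else rbind(pr, prior("DT2", "uniform", 500, 8000),
             prior("DT3", "uniform", 500, 8000))
}

lfBuilder <- function(topology) {
  force(topology)
  function(p, ss, g) {
    nLevels <- max(topology$level)
    times <- cumsum(c(unname(p["T1"]),
                      if (nLevels >= 2) unname(p["DT2"]),
                      if (nLevels >= 3) unname(p["DT3"])))
    demes <- c("AA", "AN", "ST", "TK")
    epochs <- data.frame(deme = demes, start = 0,
                         N = unname(p[paste0("N_", demes)]), growth = 0)
    splits <- data.frame(time = times[topology$level],
                         derived = topology$derived, ancestral = "TK")
    demographicModel(demes, ss[demes], epochs, splits = splits,
                     generationTime = g)
  }
}

#' Five population-tree models for the four MSEA language families
#'
#' Rooted population-tree demographies over demes `AA`, `AN`, `ST`,
#' `TK`.  Models 1 and 2 share a TK-AN cherry and differ in the deeper
#' branching (Model 1: `(((TK,AN),ST),AA)`; Model 2: `(((TK,AN),AA),ST)`);
#' Model 3 is `((AA,(ST,TK)),AN)`; Model 4 postulates an AA-TK affinity,
#' `(((AA,TK),ST),AN)`; Model 5 is a trifurcation of AA, TK and ST with
#' AN as outgroup (the two shallow splits happen simultaneously).
#' Internal split times are free parameters ordered root-to-tip
#' (parameterized as a shallowest time plus positive increments).
#'
#' @inheritParams ctOriginModels
#' @param sampleSizes Named integer vector (default 100 per family).
#' @return A [ScenarioSet-class] with labels `model1` .. `model5`.
#' @export
languageFamilyModels <- function(priorConfig = NULL,
                                 sampleSizes = c(AA = 100L, AN = 100L,
                                                 ST = 100L, TK = 100L),
                                 generationTime = 25) {
  models <- lapply(names(lfTopologies), function(lab) {
    tri <- max(lfTopologies[[lab]]$level) == 2L
    list(priors = applyPriorConfig(lfPriors(tri), priorConfig),
         build = lfBuilder(lfTopologies[[lab]]))
  })
  names(models) <- names(lfTopologies)
  scenarioSet("language_families", models, sampleSizes, generationTime)
}

## ---- serialization --------------------------------------------------------

#' Write a scenario configuration to YAML
#'
#' Serializes the priors, sample sizes and generation time of a scenario
#' set built from one of the registered templates (`ct_origins`,
#' `language_families`); the topology is rebuilt from the registry on
#' read, so the round trip is lossless.
#'
#' @param set A [ScenarioSet-class].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
writeScenarioConfig <- function(set, path) {
  cfg <- list(
    name = set@name,
    generation_time = set@generationTime,
    sample_sizes = as.list(set@sampleSizes),
    priors = lapply(set@models, function(m) {
      pr <- m$priors
      lapply(seq_len(nrow(pr)), function(i)
        list(name = pr$name[i], dist = pr$dist[i],
             min = pr$min[i], max = pr$max[i]))
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML written by [writeScenarioConfig()].
#' @return A [ScenarioSet-class].
#' @export
readScenarioConfig <- function(path) {
  if (!file.exists(path)) stopf("input error: file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  ss <- unlist(cfg$sample_sizes)
  storage.mode(ss) <- "integer"
  set <- switch(cfg$name,
                ct_origins = ctOriginModels(sampleSizes = ss,
                                            generationTime = cfg$generation_time),
                language_families = languageFamilyModels(sampleSizes = ss,
                                                         generationTime = cfg$generation_time),
                stopf("unknown scenario template '%s'", cfg$name))
  for (lab in names(cfg$priors)) {
    pr <- do.call(rbind, lapply(cfg$priors[[lab]], function(x)
      prior(x$name, x$dist, x$min, x$max)))
    set@models[[lab]]$priors <- pr
  }
  methods::validObject(set)
  set
}

setMethod("show", "ScenarioSet", function(object) {
  cat(sprintf("ScenarioSet '%s': %d models (%s)\n", object@name,
              length(object@models), paste(names(object@models), collapse = ", ")))
  cat(sprintf("  sample sizes: %s; g = %g yr/gen\n",
              paste(sprintf("%s=%d", names(object@sampleSizes), object@sampleSizes),
                    collapse = ", "), object@generationTime))
})
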