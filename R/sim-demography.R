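#' @include AllClasses.R
NULL

#' Construct a DemographicModel
#'
#' @param demes Character vector of deme labels.
#' @param sampleSizes Named integer vector (haploid samples per deme).
#' @param epochs data.frame with columns `deme`, `start` (years before
#'   present), `N` (effective female size at `start`), `growth` (per-year
#'   forward growth rate; backward in time the size shrinks as
#'   `N(t) = N * exp(-growth * (t - start))`).  May be given as a named
#'   numeric vector of constant sizes per deme.
#' @param splits data.frame with columns `time`, `derived`, `ancestral`
#'   (optional).
#' @param migrations data.frame with columns `from`, `to`, `rate`
#'   (backward per-lineage per-generation), `start`, `end` (optional;
#'   `end = Inf` allowed).
#' @param generationTime Years per generation (default 25).
#' @return A validated [DemographicModel-class].
#' @examples
#' m <- demographicModel("popA", c(popA = 2L), c(popA = 1000))
#' @export
demographicModel <- function(demes, sampleSizes, epochs, splits = NULL,
                             migrations = NULL, generationTime = 25) {
  if (is.numeric(epochs) && !is.data.frame(epochs)) {
    epochs <- data.frame(deme = names(epochs), start = 0,
                         N = unname(epochs), growth = 0)
  }
  if (is.null(splits))
    splits <- data.frame(time = numeric(), derived = character(),
                         ancestral = character())
  if (is.null(migrations))
    migrations <- data.frame(from = character(), to = character(),
                             rate = numeric(), start = numeric(), end = numeric())
  ss <- sampleSizes
  storage.mode(ss) <- "integer"
  methods::new("DemographicModel", demes = as.character(demes),
               sampleSizes = ss, epochs = as.data.frame(epochs),
               splits = as.data.frame(splits),
               migrations = as.data.frame(migrations),
               generationTime = as.numeric(generationTime))
}

#' Construct a two-partition mutation model
#'
#' Defaults correspond to the full mitochondrial genome: 15,447 coding
#' sites at 1.708e-8 and 1,122 noncoding sites at 9.883e-8 substitutions
#' per site per year.
#'
#' @param rateCoding,rateNoncoding Substitutions/site/year.
#' @param sitesCoding,sitesNoncoding Sites per partition.
#' @return A [MutationModel-class].
#' @export
mtMutationModel <- function(rateCoding = 1.708e-8, rateNoncoding = 9.883e-8,
                            sitesCoding = 15447L, sitesNoncoding = 1122L) {
  methods::new("MutationModel", rateCoding = rateCoding,
               rateNoncoding = rateNoncoding,
               sitesCoding = as.integer(sitesCoding),
               sitesNoncoding = as.integer(sitesNoncoding))
}

#' Rescale a mutation model to a shorter alignment
#'
#' Keeps the partition rates and the coding/noncoding site proportions
#' while reducing the total length; used for desk-scale simulation.
#'
#' @param model A [MutationModel-class].
#' @param L New total number of sites.
#' @export
scaleMutationModel <- function(model, L) {
  L <- as.integer(L)
  frac <- model@sitesNoncoding / (model@sitesCoding + model@sitesNoncoding)
  nNc <- as.integer(round(L * frac))
  mtMutationModel(model@rateCoding, model@rateNoncoding,
                  sitesCoding = L - nNc, sitesNoncoding = nNc)
}

#' Build a MutationModel from a per-site partition map
#'
#' @param labels Character vector over sites with values `"coding"` /
#'   `"noncoding"`, covering every site exactly once.
#' @param rateCoding,rateNoncoding Substitutions/site/year.
#' @return A [MutationModel-class] whose partition sizes are the label
#'   counts.  Site order is exchangeable for every statistic in the
#'   package, so only the counts are retained.
#' @export
mutationModelFromPartition <- function(labels, rateCoding = 1.708e-8,
                                       rateNoncoding = 9.883e-8) {
  if (!all(labels %in% c("coding", "noncoding")))
    stopf("partition labels must be 'coding' or 'noncoding'")
  if (length(labels) < 1L) stopf("empty partition map")
  mtMutationModel(rateCoding, rateNoncoding,
                  sitesCoding = sum(labels == "coding"),
                  sitesNoncoding = sum(labels == "noncoding"))
}

#' Total alignment length of a mutation model
#' @param model A [MutationModel-class].
#' @export
totalSites <- function(model) model@sitesCoding + model@sitesNoncoding

setMethod("show", "DemographicModel", function(object) {
  cat(sprintf("DemographicModel: %d demes (%s), g = %g yr/gen\n",
              length(object@demes), paste(object@demes, collapse = ", "),
              object@generationTime))
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s=%d", names(object@sampleSizes), object@sampleSizes),
                    collapse = ", ")))
  if (nrow(object@splits))
    cat(sprintf("  splits: %s\n",
                paste(sprintf("%s->%s @ %g yr", object@splits$derived,
                              object@splits$ancestral, object@splits$time),
                      collapse = "; ")))
  if (nrow(object@migrations))
    cat(sprintf("  migration edges: %d\n", nrow(object@migrations)))
})

setMethod("show", "MutationModel", function(object) {
  cat(sprintf("MutationModel: %d coding sites @ %.3e/yr, %d noncoding @ %.3e/yr\n",
              object@sitesCoding, object@rateCoding,
              object@sitesNoncoding, object@rateNoncoding))
})
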