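#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a PopulationMap
#'
#' @param samples Character vector of sample IDs.
#' @param population Population code per sample (same order as `samples`),
#'   or a named vector over sample IDs.
#' @param groupings Named list of grouping schemes; each a named character
#'   vector population -> group.
#' @param coords Optional data.frame with columns `population`, `lat`,
#'   `lon` in decimal degrees (WGS84).
#' @return A validated [PopulationMap-class].
#' @export
populationMap <- function(samples, population, groupings = list(), coords = NULL) {
  if (is.null(names(population))) {
    stopifnot(length(population) == length(samples))
    names(population) <- samples
  }
  if (is.null(coords))
    coords <- data.frame(population = character(), lat = numeric(), lon = numeric())
  methods::new("PopulationMap", samples = as.character(samples),
               population = vapply(population, as.character, ""),
               groupings = groupings, coords = coords)
}

#' Read a delimited population metadata table
#'
#' Expects a header with required columns `sample_id` and `population`;
#' optional columns `lat`/`lon` (decimal degrees) and any number of
#' additional columns, each of which becomes a grouping scheme under its
#' column name (e.g. `language_family`, `region`).  TSV/CSV is
#' autodetected from the file extension.
#'
#' @param path Path to the table.
#' @return A [PopulationMap-class].
#' @export
readPopulationTable <- function(path) {
  if (!file.exists(path)) stopf("input error: file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "population")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("schema error: missing required column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample_id: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  hasCoord <- all(c("lat", "lon") %in% names(df))
  coords <- NULL
  if (hasCoord) {
    cc <- unique(df[, c("population", "lat", "lon")])
    if (anyDuplicated(cc$population))
      stopf("inconsistent coordinates within a population")
    if (any(abs(cc$lat) > 90, na.rm = TRUE) || any(abs(cc$lon) > 180, na.rm = TRUE))
      stopf("coordinate-range error: lat must be in [-90,90], lon in [-180,180]")
    coords <- cc
  }
  groupCols <- setdiff(names(df), c("sample_id", "population", "lat", "lon"))
  groupings <- list()
  for (g in groupCols) {
    m <- unique(df[, c("population", g)])
    if (anyDuplicated(m$population))
      stopf("grouping '%s' assigns a population to more than one group", g)
    groupings[[g]] <- stats::setNames(as.character(m[[g]]), m$population)
  }
  populationMap(df$sample_id, stats::setNames(as.character(df$population), df$sample_id),
                groupings = groupings, coords = coords)
}

#' Join an alignment with a PopulationMap
#'
#' Checks that every sample of the alignment has a population and returns
#' the population factor in alignment order.
#'
#' @param aln An [MtAlignment-class].
#' @param popmap A [PopulationMap-class].
#' @return Factor of population codes, one per sequence.
#' @export
populationFactor <- function(aln, popmap) {
  ids <- sampleIDs(aln)
  miss <- setdiff(ids, names(popmap@population))
  if (length(miss))
    stopf("samples missing from the population table: %s", paste(miss, collapse = ", "))
  factor(unname(popmap@population[ids]))
}

#' Split an alignment into per-population alignments
#' @inheritParams populationFactor
#' @return Named list of [MtAlignment-class] objects, one per population.
#' @export
splitByPopulation <- function(aln, popmap) {
  f <- populationFactor(aln, popmap)
  lapply(split(seq_len(nSamples(aln)), f), function(i) aln[i])
}

#' @describeIn PopulationMap-class population codes in order of appearance
#' @param x A `PopulationMap`.
#' @export
setMethod("populations", "PopulationMap",
          function(x) unique(unname(x@population[x@samples])))

#' @describeIn PopulationMap-class names of the grouping schemes
#' @export
setMethod("groupingSchemes", "PopulationMap", function(x) names(x@groupings))

#' Group label per population under a scheme
#' @param popmap A [PopulationMap-class].
#' @param scheme Name of a grouping scheme.
#' @return Named character vector population -> group.
#' @export
groupOf <- function(popmap, scheme) {
  if (!scheme %in% names(popmap@groupings))
    stopf("unknown grouping scheme '%s' (available: %s)", scheme,
          paste(names(popmap@groupings), collapse = ", "))
  popmap@groupings[[scheme]]
}

setMethod("show", "PopulationMap", function(object) {
  cat(sprintf("PopulationMap: %d samples, %d populations\n",
              length(object@samples), length(populations(object))))
  if (length(object@groupings))
    cat("  grouping schemes:", paste(names(object@groupings), collapse = ", "), "\n")
  if (nrow(object@coords)) cat("  coordinates: present\n")
})
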