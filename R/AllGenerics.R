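#' @include AllClasses.R
NULL

#' Sample identifiers of an alignment
#' @param x An object with samples.
#' @return Character vector of sample IDs.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Number of sequences in an alignment
#' @param x An [MtAlignment-class].
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Alignment length in sites
#' @param x An [MtAlignment-class].
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' Integer-coded alignment matrix
#'
#' Returns the alignment as an `n x L` integer matrix with A,C,G,T coded
#' 1..4 and non-informative characters (`N`, `-`) as `NA`.
#' @param x An [MtAlignment-class].
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' Populations of a PopulationMap
#' @param x A [PopulationMap-class].
#' @return Character vector of population codes (in order of first appearance).
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' Grouping scheme names
#' @param x A [PopulationMap-class].
#' @export
setGeneric("groupingSchemes", function(x) standardGeneric("groupingSchemes"))

#' Convert a Genealogy to an ape phylo
#' @param x A [Genealogy-class].
#' @return An [ape::phylo] with branch lengths in years.
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))

#' Model labels of a scenario set or reference table
#' @param x A [ScenarioSet-class] or [ReferenceTable-class].
#' @export
setGeneric("modelLabels", function(x) standardGeneric("modelLabels"))

#' Summary-statistic block of a reference table
#' @param x A [ReferenceTable-class].
#' @export
setGeneric("statTable", function(x) standardGeneric("statTable"))

#' Parameter block of a reference table
#' @param x A [ReferenceTable-class].
#' @export
setGeneric("paramTable", function(x) standardGeneric("paramTable"))
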