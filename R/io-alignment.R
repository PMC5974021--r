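#' @include AllClasses.R AllGenerics.R
NULL

# IUPAC ambiguity codes (and '?') that are demoted to N on read; only
# {A,C,G,T} are informative for the pairwise-deletion statistics
.AMBIG <- "RYSWKMBDHV?"

#' Construct an MtAlignment
#'
#' Canonicalizes input sequences: uppercases, maps `U` to `T`, and
#' converts IUPAC ambiguity codes other than `N` to `N` (the number of
#' converted characters is reported via a message).
#'
#' @param seqs Character vector of aligned sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param sampleIds Sample identifiers; taken from `names(seqs)` when
#'   omitted.
#' @return A validated [MtAlignment-class].
#' @examples
#' aln <- mtAlignment(c(s1 = "ACGT", s2 = "ACGA"))
#' nSamples(aln)
#' @export
mtAlignment <- function(seqs, sampleIds = NULL) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs) || length(seqs) == 0L)
    stopf("input error: no sequences supplied")
  ids <- sampleIds %||% names(seqs)
  if (is.null(ids)) stopf("input error: sample IDs are required")
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  nAmbig <- sum(nchar(seqs) - nchar(gsub(sprintf("[%s]", .AMBIG), "", seqs, fixed = FALSE)))
  if (nAmbig > 0) {
    seqs <- chartr(.AMBIG, strrep("N", nchar(.AMBIG)), seqs)
    message(sprintf("converted %d IUPAC ambiguity character(s) to N", nAmbig))
  }
  bad <- nchar(gsub("[ACGTN-]", "", seqs))
  if (any(bad > 0))
    stopf("record %d ('%s') contains characters outside the DNA alphabet",
          which(bad > 0)[1L], ids[which(bad > 0)[1L]])
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    i <- which(w != w[1L])[1L]
    stopf("alignment error: record %d ('%s') has length %d, expected %d",
          i, ids[i], w[i], w[1L])
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  methods::new("MtAlignment", seqs = x)
}

#' Read an aligned multi-FASTA file
#'
#' @param path Path to a FASTA file of equal-length sequences.
#' @return An [MtAlignment-class]; input record order is preserved.
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path)) stopf("input error: file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stopf("input error: no FASTA records in %s", path)
  # keep only the first whitespace-delimited token of each header
  nm <- sub("\\s.*$", "", names(x))
  mtAlignment(as.character(x), sampleIds = nm)
}

#' Write an alignment to FASTA
#' @param x An [MtAlignment-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastaAlignment <- function(x, path) {
  stopifnot(methods::is(x, "MtAlignment"))
  Biostrings::writeXStringSet(x@seqs, filepath = path)
  invisible(path)
}

#' @describeIn MtAlignment-class sample identifiers
#' @param x An `MtAlignment`.
#' @export
setMethod("sampleIDs", "MtAlignment", function(x) names(x@seqs))

#' @describeIn MtAlignment-class number of sequences
#' @export
setMethod("nSamples", "MtAlignment", function(x) length(x@seqs))

#' @describeIn MtAlignment-class alignment length (sites)
#' @export
setMethod("seqLength", "MtAlignment", function(x) Biostrings::width(x@seqs)[1L])

#' @describeIn MtAlignment-class integer-coded matrix (A,C,G,T -> 1..4, else NA)
#' @export
setMethod("alignmentMatrix", "MtAlignment", function(x) {
  m <- as.matrix(x@seqs)
  out <- matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m),
                dimnames = list(names(x@seqs), NULL))
  out
})

#' Subset an alignment by sample ID or index
#' @param x An [MtAlignment-class].
#' @param i Character IDs or integer/logical indices.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "MtAlignment", function(x, i, j, ..., drop = TRUE) {
  methods::new("MtAlignment", seqs = x@seqs[i])
})

#' Concatenate alignments (same length, disjoint sample IDs)
#' @param alnList List of [MtAlignment-class] objects.
#' @return A pooled [MtAlignment-class].
#' @export
poolAlignments <- function(alnList) {
  stopifnot(length(alnList) >= 1L)
  L <- vapply(alnList, seqLength, 1L)
  if (length(unique(L)) != 1L) stopf("alignment error: cannot pool alignments of different lengths")
  seqs <- do.call(c, unname(lapply(alnList, function(a) a@seqs)))
  methods::new("MtAlignment", seqs = seqs)
}

setMethod("show", "MtAlignment", function(object) {
  cat(sprintf("MtAlignment: %d sequences x %d sites\n",
              nSamples(object), seqLength(object)))
  ids <- sampleIDs(object)
  cat("  samples:", paste(utils::head(ids, 5), collapse = ", "),
      if (length(ids) > 5) sprintf("... (%d more)", length(ids) - 5) else "", "\n")
})
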