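#' @include AllClasses.R AllGenerics.R io-alignment.R
NULL

# Pairwise difference and comparable-site matrices under pairwise
# deletion: a site contributes to a pair only when both characters are in
# {A,C,G,T}.  Works on the integer-coded matrix (NA = non-informative).
pairwiseFromMatrix <- function(M) {
  inf <- !is.na(M)
  storage.mode(inf) <- "double"
  comp <- tcrossprod(inf)
  matches <- matrix(0, nrow(M), nrow(M))
  for (b in 1:4) {
    Mb <- M == b
    Mb[is.na(Mb)] <- FALSE
    storage.mode(Mb) <- "double"
    matches <- matches + tcrossprod(Mb)
  }
  D <- comp - matches
  diag(D) <- 0
  dimnames(D) <- dimnames(comp) <- list(rownames(M), rownames(M))
  list(diff = D, comparable = comp)
}

#' Pairwise difference matrix of an alignment
#'
#' Number of sites at which each pair of sequences both carry an
#' unambiguous base (A/C/G/T) and differ; `N` and `-` are excluded
#' pairwise (pairwise deletion).
#'
#' @param aln An [MtAlignment-class].
#' @return List with `diff` (integer-valued difference matrix) and
#'   `comparable` (number of mutually informative sites per pair).
#' @export
pairwiseDifferenceMatrix <- function(aln) {
  stopifnot(methods::is(aln, "MtAlignment"))
  pairwiseFromMatrix(alignmentMatrix(aln))
}

#' Pairwise difference between two sequences
#'
#' @param seqA,seqB Character strings of equal length.
#' @return Integer count of sites where both are in `{A,C,G,T}` and differ.
#' @examples
#' pairwiseDifference("ACNT", "AC-A")  # only site 4 comparable -> 1
#' @export
pairwiseDifference <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB))
    stopf("length mismatch: %d vs %d sites", nchar(seqA), nchar(seqB))
  a <- match(strsplit(toupper(seqA), "")[[1]], c("A", "C", "G", "T"))
  b <- match(strsplit(toupper(seqB), "")[[1]], c("A", "C", "G", "T"))
  ok <- !is.na(a) & !is.na(b)
  sum(a[ok] != b[ok])
}

#' Haplotype classes under missing-data compatibility
#'
#' Two sequences share a haplotype iff they are identical at every site
#' where both are informative (so `N`/`-` never create a difference).
#' Compatibility is not transitive; each sequence is merged into the
#' earliest-seen compatible class (compared against the class founder).
#'
#' @param aln An [MtAlignment-class].
#' @return List with `assignment` (integer class per sample, named) and
#'   `counts` (class sizes; they sum to `nSamples(aln)`).
#' @export
countHaplotypes <- function(aln) {
  stopifnot(methods::is(aln, "MtAlignment"))
  D <- pairwiseDifferenceMatrix(aln)$diff
  n <- nrow(D)
  cls <- integer(n)
  founders <- integer(0)
  for (i in seq_len(n)) {
    hit <- founders[which(D[i, founders] == 0)[1L]]
    if (is.na(hit) || length(founders) == 0L) {
      founders <- c(founders, i)
      cls[i] <- length(founders)
    } else cls[i] <- match(hit, founders)
  }
  names(cls) <- rownames(D)
  list(assignment = cls, counts = as.integer(table(cls)))
}

# segregating sites: columns with >= 2 distinct informative bases
segregatingSites <- function(M) {
  nAllele <- matrix(0L, 4L, ncol(M))
  for (b in 1:4) {
    Mb <- M == b
    Mb[is.na(Mb)] <- FALSE
    nAllele[b, ] <- as.integer(colSums(Mb) > 0L)
  }
  sum(colSums(nAllele) >= 2L)
}
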