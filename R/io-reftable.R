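#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a ReferenceTable
#' @param model Character or factor of model labels (one per row).
#' @param params data.frame of drawn parameters.
#' @param stats data.frame of summary statistics.
#' @param lda Optional fitted LDA projection (see [appendLdaAxes()]).
#' @export
referenceTable <- function(model, params, stats, lda = list()) {
  methods::new("ReferenceTable", model = factor(model),
               params = as.data.frame(params), stats = as.data.frame(stats),
               lda = lda)
}

#' @describeIn ReferenceTable-class model labels (factor levels)
#' @param x A `ReferenceTable`.
#' @export
setMethod("modelLabels", "ReferenceTable", function(x) levels(x@model))

#' @describeIn ReferenceTable-class summary-statistic block
#' @export
setMethod("statTable", "ReferenceTable", function(x) x@stats)

#' @describeIn ReferenceTable-class parameter block
#' @export
setMethod("paramTable", "ReferenceTable", function(x) x@params)

#' Number of rows of a reference table
#' @param x A [ReferenceTable-class].
#' @export
setMethod("length", "ReferenceTable", function(x) length(x@model))

#' Write a reference table to CSV
#'
#' Columns are `model`, `param_*`, `stat_*`.  NaN summary values are
#' written as `NaN` and survive a round trip.
#'
#' @param table A [ReferenceTable-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeReferenceTable <- function(table, path) {
  stopifnot(methods::is(table, "ReferenceTable"))
  if (length(table) == 0L) stopf("refusing to write an empty reference table")
  p <- table@params; s <- table@stats
  names(p) <- paste0("param_", names(p))
  names(s) <- paste0("stat_", names(s))
  df <- cbind(data.frame(model = as.character(table@model)), p, s)
  # full-precision text so the float round trip is bitwise; NaN spelled out
  for (j in names(df)) if (is.numeric(df[[j]])) {
    v <- sprintf("%.17g", df[[j]])
    v[is.na(df[[j]]) & !is.nan(df[[j]])] <- "NA"
    v[is.nan(df[[j]])] <- "NaN"
    df[[j]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference table from CSV
#'
#' @param path CSV written by [writeReferenceTable()].
#' @return A [ReferenceTable-class].  NaN statistics are preserved; when
#'   any are present a validation note is attached as attribute
#'   `"validation"`.
#' @export
readReferenceTable <- function(path) {
  if (!file.exists(path)) stopf("input error: file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"model" %in% names(df) || !any(grepl("^stat_", names(df))))
    stopf("schema error: expected columns model, param_*, stat_* in %s", path)
  pCols <- grep("^param_", names(df), value = TRUE)
  sCols <- grep("^stat_", names(df), value = TRUE)
  params <- df[, pCols, drop = FALSE]; names(params) <- sub("^param_", "", pCols)
  stats <- df[, sCols, drop = FALSE]; names(stats) <- sub("^stat_", "", sCols)
  out <- referenceTable(df$model, params, stats)
  nNaN <- sum(vapply(stats, function(col) sum(is.nan(col)), 0L))
  if (nNaN > 0)
    attr(out, "validation") <- sprintf("%d NaN summary value(s) present", nNaN)
  out
}

setMethod("show", "ReferenceTable", function(object) {
  tab <- table(object@model)
  cat(sprintf("ReferenceTable: %d rows, %d models, %d parameters, %d summaries\n",
              length(object), nlevels(object@model),
              ncol(object@params), ncol(object@stats)))
  cat("  rows per model:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (length(object@lda)) cat("  LDA axes: appended\n")
})
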