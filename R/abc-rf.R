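#' @include io-reftable.R abc-summaries.R
NULL

# drop all-NA / zero-variance columns for LDA; keep names
.usableCols <- function(X) {
  keep <- vapply(X, function(col) {
    col <- col[is.finite(col)]
    length(col) > 1 && stats::sd(col) > 1e-12
  }, TRUE)
  names(X)[keep]
}

#' Append linear-discriminant axes to a reference table
#'
#' Fits an LDA of model label on the summary statistics (k-1 axes for k
#' models) on the reference table only, and appends the projection
#' coordinates as extra summary columns `LD1..LD(k-1)` (they complement,
#' not replace, the raw summaries).  The fitted affine projection is
#' stored in the table's `lda` slot so the observed vector can be
#' projected with [projectLda()].  NaN summaries are median-imputed for
#' the fit.  A singular within-class scatter falls back to a
#' ridge-regularized eigendecomposition with a warning.
#'
#' @param table A [ReferenceTable-class] with >= 2 models.
#' @return The augmented [ReferenceTable-class].
#' @export
appendLdaAxes <- function(table) {
  stopifnot(methods::is(table, "ReferenceTable"))
  if (nlevels(table@model) < 2L) stopf("LDA needs >= 2 models")
  X <- table@stats
  cols <- .usableCols(X)
  if (length(cols) < 2L) stopf("LDA needs >= 2 usable summaries")
  X <- X[, cols, drop = FALSE]
  med <- vapply(X, function(col) stats::median(col[is.finite(col)]), 0)
  for (j in seq_along(X)) X[[j]][!is.finite(X[[j]])] <- med[j]
  fit <- tryCatch(
    suppressWarnings(MASS::lda(as.matrix(X), grouping = table@model)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    center <- colMeans(as.matrix(X))
    scaling <- fit$scaling
  } else {
    warnf("singular within-class scatter: using ridge-regularized LDA")
    Xm <- as.matrix(X)
    center <- colMeans(Xm)
    Xc <- sweep(Xm, 2, center)
    cls <- table@model
    W <- matrix(0, ncol(Xm), ncol(Xm))
    for (lev in levels(cls)) {
      Z <- Xc[cls == lev, , drop = FALSE]
      Z <- sweep(Z, 2, colMeans(Z))
      W <- W + crossprod(Z)
    }
    W <- W / (nrow(Xm) - nlevels(cls)) + diag(1e-6 * mean(diag(W)) + 1e-12, ncol(Xm))
    B <- crossprod(Xc) / (nrow(Xm) - 1) - W
    ev <- eigen(solve(W, B))
    k <- min(nlevels(cls) - 1L, ncol(Xm))
    scaling <- Re(ev$vectors[, seq_len(k), drop = FALSE])
    rownames(scaling) <- colnames(Xm)
    colnames(scaling) <- paste0("LD", seq_len(k))
  }
  proj <- list(cols = cols, center = center, scaling = scaling,
               medians = med)
  coords <- projectLda(proj, table@stats)
  stats <- cbind(table@stats, as.data.frame(coords))
  referenceTable(table@model, table@params, stats, lda = proj)
}

#' Project summary vectors onto fitted LDA axes
#'
#' @param proj The `lda` slot of a table returned by [appendLdaAxes()].
#' @param stats A data.frame of summaries or a single named numeric
#'   vector.
#' @return Matrix of LDA coordinates (`LD1..`).
#' @export
projectLda <- function(proj, stats) {
  if (is.numeric(stats) && !is.matrix(stats))
    stats <- as.data.frame(as.list(stats))
  X <- as.matrix(stats[, proj$cols, drop = FALSE])
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- proj$medians[j]
  out <- sweep(X, 2, proj$center) %*% proj$scaling
  colnames(out) <- colnames(proj$scaling)
  out
}

# impute NaN/NA summaries by pooled training medians, adding missingness
# indicator columns for summaries that are ever missing.  Pooled (not
# per-class) medians matter: class-specific imputed values would let the
# forest read the label off a NaN row and corrupt the out-of-bag prior
# error rate.
.imputeStats <- function(stats, model = NULL, medians = NULL) {
  X <- as.data.frame(stats)
  missingAny <- vapply(X, function(col) any(!is.finite(col)), TRUE)
  if (is.null(medians)) {
    medians <- list(
      overall = vapply(X, function(col) {
        v <- stats::median(col[is.finite(col)])
        if (is.finite(v)) v else 0
      }, 0),
      missingCols = names(X)[missingAny])
  }
  for (j in names(X)) {
    bad <- !is.finite(X[[j]])
    if (any(bad)) X[[j]][bad] <- medians$overall[j]
  }
  for (j in medians$missingCols)
    X[[paste0("miss_", j)]] <- as.numeric(!is.finite(as.data.frame(stats)[[j]]))
  list(X = X, medians = medians)
}

#' Fit the ABC-RF model-choice classifier
#'
#' Trains a random-forest classifier of model label on the summary
#' statistics (including appended LDA axes when present), and
#' precomputes the out-of-bag prior-error-rate curve over forest sizes,
#' the out-of-bag confusion matrix, and the regression forest of the
#' out-of-bag correct-classification indicator used to estimate the
#' posterior probability of the selected model.  NaN summaries are
#' imputed by pooled training medians with missingness-indicator
#' features (pooled so that imputation cannot leak the model label).
#'
#' @param table A balanced [ReferenceTable-class] with >= 2 models.
#' @param nTrees Number of trees (default 500).
#' @param seed Optional integer seed (forests run single-threaded for
#'   reproducibility).
#' @param errorGrid Forest sizes at which the prior error rate is
#'   evaluated (default every 50 trees up to `nTrees`).
#' @return An object of class `modelChoiceFit` (list) with elements
#'   `forest`, `posteriorForest`, `priorErrorRate`, `confusion`,
#'   `classes`, `medians`, `lda`, `trainCols`.
#' @export
fitModelChoice <- function(table, nTrees = 500L, seed = NULL,
                           errorGrid = NULL) {
  stopifnot(methods::is(table, "ReferenceTable"))
  if (nTrees < 1L) stopf("nTrees must be >= 1")
  if (nlevels(table@model) < 2L) stopf("model choice needs >= 2 models")
  tab <- table(table@model)
  if (length(unique(tab)) != 1L)
    stopf("reference table must be balanced (rows per model: %s)",
          paste(tab, collapse = ", "))
  imp <- .imputeStats(table@stats, model = table@model)
  dat <- imp$X
  dat$.model <- table@model
  rseed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else as.integer(seed)
  rf <- ranger::ranger(
    dependent.variable.name = ".model", data = dat,
    num.trees = as.integer(nTrees), keep.inbag = TRUE,
    seed = rseed, num.threads = 1L, respect.unordered.factors = TRUE)
  truth <- table@model
  # per-tree predictions on the training rows, OOB-masked
  ptp <- stats::predict(rf, dat, predict.all = TRUE, num.threads = 1L)$predictions
  classValues <- rf$forest$class.values
  classLevels <- rf$forest$levels
  inbag <- matrix(unlist(rf$inbag.counts), nrow = nrow(dat))
  oob <- inbag == 0L
  nTrees <- as.integer(nTrees)
  grid <- errorGrid %||%
    (if (nTrees >= 50L) unique(c(seq(50L, nTrees, by = 50L), nTrees)) else nTrees)
  grid <- grid[grid >= 1 & grid <= nTrees]
  k <- length(classLevels)
  # ranger's per-tree prediction codes are class.values, which index
  # forest$levels but follow data order, not level order
  labelOfValue <- classLevels[classValues]
  errCurve <- vapply(grid, function(tt) {
    votes <- matrix(0L, nrow(dat), k)
    for (ci in seq_len(k)) {
      votes[, ci] <- rowSums((ptp[, seq_len(tt), drop = FALSE] == classValues[ci]) &
                               oob[, seq_len(tt), drop = FALSE])
    }
    hasOob <- rowSums(votes) > 0
    pred <- labelOfValue[max.col(votes, ties.method = "first")]
    mean(pred[hasOob] != as.character(truth)[hasOob])
  }, 0)
  # full-forest OOB predictions / confusion
  oobPred <- rf$predictions
  confusion <- table(true = truth, predicted = oobPred)
  # Pudlo-style posterior estimator: regression forest on the indicator
  # that the OOB prediction equals the true label
  regDat <- imp$X
  regDat$.correct <- as.numeric(as.character(oobPred) == as.character(truth))
  ok <- !is.na(regDat$.correct)
  postRf <- ranger::ranger(
    dependent.variable.name = ".correct", data = regDat[ok, , drop = FALSE],
    num.trees = as.integer(nTrees), seed = rseed + 1L, num.threads = 1L)
  structure(list(
    forest = rf, posteriorForest = postRf,
    priorErrorRate = data.frame(trees = grid, error = errCurve),
    confusion = unclass(confusion), classes = classLevels,
    medians = imp$medians, lda = table@lda,
    trainCols = setdiff(names(dat), ".model")), class = "modelChoiceFit")
}

# build the feature row for an observed summary vector, matching the
# training columns (LDA projection, pooled-median imputation, indicators)
.observedFeatures <- function(fit, observed) {
  obs <- observed
  if (length(fit$lda)) {
    missRaw <- setdiff(fit$lda$cols, names(obs))
    if (length(missRaw))
      stopf("observed summary vector does not match the reference-table schema (missing: %s)",
            paste(utils::head(missRaw, 5), collapse = ", "))
    coords <- projectLda(fit$lda, obs)
    obs <- c(obs, stats::setNames(as.numeric(coords), colnames(coords)))
  }
  base <- setdiff(fit$trainCols, grep("^miss_", fit$trainCols, value = TRUE))
  miss <- setdiff(base, names(obs))
  if (length(miss))
    stopf("observed summary vector does not match the reference-table schema (missing: %s)",
          paste(utils::head(miss, 5), collapse = ", "))
  row <- as.data.frame(as.list(obs[base]))
  for (j in base) {
    if (!is.finite(row[[j]])) row[[j]] <- unname(fit$medians$overall[j])
  }
  for (j in grep("^miss_", fit$trainCols, value = TRUE)) {
    src <- sub("^miss_", "", j)
    row[[j]] <- as.numeric(!is.finite(unname(obs[src])))
  }
  row
}

#' Random-forest ABC model choice for an observed dataset
#'
#' Votes are the fraction of trees choosing each model for the observed
#' summary vector; the selected model is the vote argmax; its posterior
#' probability is the prediction of the out-of-bag
#' correct-classification regression forest at the observed point.
#'
#' @param fit A `modelChoiceFit` from [fitModelChoice()].
#' @param observed Named numeric summary vector in the reference-table
#'   schema (raw summaries; LDA axes are appended automatically when the
#'   table carried them).
#' @return A [ModelChoiceResult-class].
#' @export
predictModel <- function(fit, observed) {
  stopifnot(inherits(fit, "modelChoiceFit"))
  row <- .observedFeatures(fit, observed)
  pr <- stats::predict(fit$forest, row, predict.all = TRUE, num.threads = 1L)
  v <- as.integer(pr$predictions)
  cv <- fit$forest$forest$class.values
  counts <- vapply(cv, function(x) sum(v == x), 0)
  votes <- stats::setNames(counts / sum(counts), fit$classes[cv])
  votes <- votes[fit$classes]
  selected <- fit$classes[which.max(votes)]
  post <- stats::predict(fit$posteriorForest, row, num.threads = 1L)$predictions
  methods::new("ModelChoiceResult",
               votes = votes, selected = selected,
               posteriorProbability = min(max(post, 0), 1),
               priorErrorRate = fit$priorErrorRate,
               confusion = fit$confusion)
}

#' Posterior parameter estimates under one model
#'
#' Restricts the reference table to one model and fits a quantile
#' regression forest per free parameter; the posterior mean, median and
#' central 95% interval at the observed point come from the
#' terminal-node weight distribution.  Parameters constant over the
#' retained rows are skipped with a note.
#'
#' @param table A [ReferenceTable-class].
#' @param modelLabel The model to condition on (>= 200 rows required).
#' @param observed Named numeric summary vector (raw schema).
#' @param nTrees Trees per regression forest (default 500).
#' @param seed Optional integer seed.
#' @param parameters Optional character vector restricting which
#'   parameters are estimated (default: all free parameters).
#' @return A [ParameterEstimate-class].
#' @export
estimateParameters <- function(table, modelLabel, observed, nTrees = 500L,
                               seed = NULL, parameters = NULL) {
  stopifnot(methods::is(table, "ReferenceTable"))
  sel <- table@model == modelLabel
  if (sum(sel) < 200L)
    stopf("parameter estimation needs >= 200 rows for model '%s' (got %d)",
          modelLabel, sum(sel))
  stats <- table@stats[sel, , drop = FALSE]
  params <- table@params[sel, , drop = FALSE]
  imp <- .imputeStats(stats)
  obs <- observed
  if (length(table@lda)) {
    coords <- projectLda(table@lda, obs)
    obs <- c(obs, stats::setNames(as.numeric(coords), colnames(coords)))
  }
  feat <- imp$X
  obsRow <- as.data.frame(as.list(obs[setdiff(names(feat), grep("^miss_", names(feat), value = TRUE))]))
  for (j in names(obsRow)) if (!is.finite(obsRow[[j]]))
    obsRow[[j]] <- unname(imp$medians$overall[j])
  for (j in grep("^miss_", names(feat), value = TRUE))
    obsRow[[j]] <- as.numeric(!is.finite(unname(obs[sub("^miss_", "", j)])))
  rseed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else as.integer(seed)
  rows <- list(); skipped <- character()
  parNames <- parameters %||% names(params)
  unknown <- setdiff(parNames, names(params))
  if (length(unknown))
    stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  for (pn in parNames) {
    y <- params[[pn]]
    if (all(is.na(y))) next
    if (stats::sd(y, na.rm = TRUE) < 1e-300) { skipped <- c(skipped, pn); next }
    dat <- feat
    dat$.y <- y
    qrf <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                          num.trees = as.integer(nTrees), quantreg = TRUE,
                          seed = rseed, num.threads = 1L)
    qs <- stats::predict(qrf, obsRow, type = "quantiles",
                         quantiles = c(0.025, 0.5, 0.975),
                         num.threads = 1L)$predictions
    mn <- stats::predict(qrf, obsRow, num.threads = 1L)$predictions
    rows[[pn]] <- data.frame(parameter = pn, mean = as.numeric(mn),
                             median = qs[2], q025 = qs[1], q975 = qs[3])
    rseed <- rseed + 1L
  }
  if (length(skipped))
    message(sprintf("skipped constant parameter(s): %s", paste(skipped, collapse = ", ")))
  methods::new("ParameterEstimate", estimates = do.call(rbind, rows),
               model = modelLabel)
}

setMethod("show", "ModelChoiceResult", function(object) {
  cat("ABC-RF model choice\n")
  cat("  votes:", paste(sprintf("%s=%.3f", names(object@votes), object@votes),
                        collapse = ", "), "\n")
  cat(sprintf("  selected: %s (posterior probability %.3f)\n",
              object@selected, object@posteriorProbability))
  er <- object@priorErrorRate
  cat(sprintf("  prior error rate: %.3f at %d trees\n",
              er$error[nrow(er)], er$trees[nrow(er)]))
})

setMethod("show", "ParameterEstimate", function(object) {
  cat(sprintf("Posterior parameter estimates (model '%s')\n", object@model))
  print(object@estimates, row.names = FALSE)
})
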