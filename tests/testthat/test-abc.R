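test_that("summary vectors have the documented schema and compose from popgen stats", {
  set.seed(71)
  seqs <- randomToySeqs(16, 40, missing = 0)
  demes <- list(W = toyAln(seqs[1:4], paste0("w", 1:4)),
                X = toyAln(seqs[5:8], paste0("x", 1:4)),
                Y = toyAln(seqs[9:12], paste0("y", 1:4)),
                Z = toyAln(seqs[13:16], paste0("z", 1:4)))
  s <- computeSummaryVector(demes)
  expect_length(s, 6 * 4 + 3 * choose(4, 2))   # 42 for 4 demes
  # statistic-by-statistic recomputation
  dv <- diversitySummary(demes$W)
  expect_equal(unname(s["h_W"]), dv@h)
  expect_equal(unname(s["mpd_W"]), dv@MPD)
  expect_equal(unname(s["S_W"]), dv@S)
  expect_equal(unname(s["tajd_X"]), tajimasD(demes$X))
  expect_equal(unname(s["phist_W_X"]),
               suppressWarnings(phiStPair(demes$W, demes$X))$phiST)
  D <- oracleDiffMatrix(seqs)
  expect_equal(unname(s["dxy_W_X"]), mean(D[1:4, 5:8]))
})

test_that("identical demes give zero Phi-st and tiny demes give flagged NaN", {
  seqs <- c("ACGTACGTAA", "ACCTACGTAA", "ACGTACTTAA")
  demes <- list(A = toyAln(seqs, paste0("a", 1:3)),
                B = toyAln(seqs, paste0("b", 1:3)))
  s <- computeSummaryVector(demes)
  expect_lte(s[["phist_A_B"]], 0)      # no among-deme structure
  demes2 <- list(A = toyAln(seqs, paste0("a", 1:3)),
                 B = toyAln(seqs[1], "b1"))
  s2 <- computeSummaryVector(demes2)
  expect_true(is.nan(s2[["h_B"]]))
  expect_true(is.nan(s2[["phist_A_B"]]))
  expect_true("B" %in% attr(s2, "flagged"))
})

test_that("reference tables are balanced, seeded and separable by history", {
  fx <- getSeparableFit()
  ref <- fx$ref
  expect_equal(as.integer(table(ref@model)), c(220L, 220L))
  # deep-split rows stochastically dominate panmictic rows in Phi-st
  phi <- ref@stats$phist_A_B
  expect_gt(stats::median(phi[ref@model == "deepsplit"]),
            stats::median(phi[ref@model == "panmixia"]) + 0.3)
  # determinism at small scale
  set <- separableSet()
  r1 <- buildReferenceTable(set, 4, sepMutModel(500), seed = 99)
  r2 <- buildReferenceTable(set, 4, sepMutModel(500), seed = 99)
  expect_identical(statTable(r1), statTable(r2))
  expect_identical(paramTable(r1), paramTable(r2))
})

test_that("LDA appends k-1 reusable axes and separates separated clouds", {
  fx <- getSeparableFit()
  ref <- fx$ref
  expect_true("LD1" %in% names(statTable(ref)))       # k = 2 -> one axis
  expect_false("LD2" %in% names(statTable(ref)))
  # projecting the training rows reproduces the stored coordinates
  coords <- projectLda(ref@lda, ref@stats[, setdiff(names(ref@stats), "LD1")])
  expect_equal(as.numeric(coords[, "LD1"]), ref@stats$LD1, tolerance = 1e-9)

  # two Gaussian clouds 10 sigma apart: LDA axis classifies < 1% wrong
  set.seed(72)
  n <- 400
  X <- data.frame(a = c(rnorm(n), rnorm(n, 10)),
                  b = c(rnorm(n), rnorm(n, 10)),
                  c = rnorm(2 * n))
  tab <- referenceTable(rep(c("g1", "g2"), each = n),
                        data.frame(dummy = rep(1, 2 * n)), X)
  tab <- appendLdaAxes(tab)
  ld <- tab@stats$LD1
  thr <- (mean(ld[1:n]) + mean(ld[(n + 1):(2 * n)])) / 2
  lab <- rep(c(FALSE, TRUE), each = n)
  side <- ld > thr
  errRate <- min(mean(side != lab), mean(side == lab))
  expect_lt(errRate, 0.01)
})

test_that("the classifier recovers well-separated histories and is reproducible", {
  fx <- getSeparableFit()
  fit <- fx$fit
  # separable scenarios: low OOB prior error
  expect_lt(fit$priorErrorRate$error[nrow(fit$priorErrorRate)], 0.10)
  # confusion-matrix marginals equal per-model training counts
  expect_equal(unname(rowSums(fit$confusion)), c(220, 220))
  # predicting a fresh deep-split dataset: votes concentrate correctly
  obs <- generateScenarioFixture(fx$set, "deepsplit", sepMutModel(), seed = 7003)
  res <- predictModel(fit, obs$summary)
  expect_equal(sum(res@votes), 1, tolerance = 1e-9)
  expect_gt(res@votes[["deepsplit"]], 0.9)
  expect_equal(res@selected, "deepsplit")
  expect_gt(res@posteriorProbability, 0.8)
  # bit-reproducible with the same seed and table
  fit2 <- fitModelChoice(fx$ref, nTrees = 200, seed = 7002)
  res2 <- predictModel(fit2, obs$summary)
  expect_identical(res@votes, res2@votes)
  expect_identical(res@posteriorProbability, res2@posteriorProbability)
})

test_that("the prior-error curve is evaluated along the forest and flattens", {
  fx <- getSeparableFit()
  er <- fx$fit$priorErrorRate
  expect_equal(er$trees, seq(50, 200, by = 50))
  expect_true(all(er$error >= 0 & er$error <= 1))
  # beyond enough trees the curve is flat for separable scenarios
  expect_lt(abs(er$error[nrow(er)] - er$error[nrow(er) - 1]), 0.02)
})

test_that("NaN summaries are imputed with indicator features, not dropped", {
  fx <- getSeparableFit()
  ref <- fx$ref
  stats <- ref@stats
  stats$tajd_A[c(3, 50, 130)] <- NaN
  tab <- referenceTable(ref@model, ref@params, stats, lda = ref@lda)
  fit <- fitModelChoice(tab, nTrees = 50, seed = 1)
  expect_true("miss_tajd_A" %in% fit$trainCols)
  obs <- statTable(ref)[1, ]
  v <- unlist(obs); v["tajd_A"] <- NaN
  res <- predictModel(fit, v[setdiff(names(v), "LD1")])
  expect_equal(sum(res@votes), 1, tolerance = 1e-9)
})

test_that("unbalanced tables and schema mismatches are refused", {
  fx <- getSeparableFit()
  ref <- fx$ref
  bad <- referenceTable(c(as.character(ref@model), "panmixia"),
                        rbind(ref@params, ref@params[1, ]),
                        rbind(ref@stats, ref@stats[1, ]))
  expect_error(fitModelChoice(bad, nTrees = 50), "balanced")
  expect_error(predictModel(fx$fit, c(nonsense = 1)), "schema")
  expect_error(fitModelChoice(ref, nTrees = 0), "nTrees")
})

test_that("parameter estimation brackets the truth and orders quantiles", {
  fx <- getSeparableFit()
  obs <- generateScenarioFixture(fx$set, "deepsplit", sepMutModel(), seed = 7010)
  expect_error(estimateParameters(fx$ref, "deepsplit", obs$summary,
                                  parameters = "bogus"), "unknown parameter")
  expect_message(
    est <- estimateParameters(fx$ref, "deepsplit", obs$summary, nTrees = 100,
                              seed = 4),
    "constant parameter")               # the fixed-N prior is skipped
  df <- est@estimates
  expect_equal(df$parameter, "T")
  expect_true(df$q025 <= df$median && df$median <= df$q975)
  expect_true(df$median >= df$q025 && df$median <= df$q975)
  # estimates stay within the prior support
  expect_gte(df$q025, 150000 * 0.99)
  expect_lte(df$q975, 400000 * 1.01)
})
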