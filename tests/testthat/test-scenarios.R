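test_that("the CT-origin set encodes three models differing as intended", {
  set <- ctOriginModels()
  expect_setequal(modelLabels(set), c("demic", "cultural", "continuous"))
  p <- drawParameters(set, "continuous", seed = 1)
  demic <- buildScenarioModel(set, "demic", p)
  cont <- buildScenarioModel(set, "continuous", p)
  cult <- buildScenarioModel(set, "cultural", p)
  # demic and continuous share the topology and differ only by migration
  expect_identical(demic@splits, cont@splits)
  expect_identical(demic@epochs, cont@epochs)
  expect_equal(nrow(demic@migrations), 0L)
  expect_equal(nrow(cont@migrations), 2L)
  expect_equal(unique(cont@migrations$rate), unname(p["m"]))
  # cultural differs only in the CT founding ancestor
  expect_equal(cult@splits$ancestral[cult@splits$derived == "CT"], "AA")
  expect_equal(demic@splits$ancestral[demic@splits$derived == "CT"], "TK")
  # zero migration collapses continuous to the demic structure
  p0 <- p; p0["m"] <- 0
  cont0 <- buildScenarioModel(set, "continuous", p0)
  expect_equal(nrow(cont0@migrations), 0L)
  expect_identical(cont0@splits, demic@splits)
})

test_that("parameter draws respect their priors and seeds", {
  set <- ctOriginModels()
  expect_error(drawParameters(set, "nope"), "unknown model label")
  set.seed(61)
  draws <- replicate(2000, drawParameters(set, "continuous"))
  expect_gte(min(draws["T_CT", ]), 500)
  expect_lte(max(draws["T_CT", ]), 3000)
  expect_gte(min(draws["N_CT", ]), 1e2)
  expect_lte(max(draws["N_CT", ]), 1e5)
  # log-uniform prior: log-draws are uniform
  ks <- suppressWarnings(stats::ks.test(log(draws["m", ]), "punif",
                                        log(1e-6), log(1e-2)))
  expect_gt(ks$p.value, 0.01)
  expect_identical(drawParameters(set, "demic", seed = 5),
                   drawParameters(set, "demic", seed = 5))
})

test_that("every draw from every scenario yields a valid demography", {
  ct <- ctOriginModels(sampleSizes = c(TK = 5L, AA = 5L, CT = 5L))
  lf <- languageFamilyModels(sampleSizes = c(AA = 5L, AN = 5L, ST = 5L, TK = 5L))
  set.seed(62)
  for (set in list(ct, lf)) {
    for (lab in modelLabels(set)) {
      for (i in 1:1000) {
        p <- drawParameters(set, lab)
        m <- buildScenarioModel(set, lab, p)   # validObject inside
        expect_s4_class(m, "DemographicModel")
      }
    }
  }
})

test_that("language-family topologies match their published hypotheses", {
  set <- languageFamilyModels()
  expect_equal(modelLabels(set), paste0("model", 1:5))
  p <- drawParameters(set, "model1", seed = 3)
  m1 <- buildScenarioModel(set, "model1", p)
  m2 <- buildScenarioModel(set, "model2", p)
  # models 1 and 2 share the TK-AN sister relationship (shallowest split)
  first1 <- m1@splits[which.min(m1@splits$time), ]
  first2 <- m2@splits[which.min(m2@splits$time), ]
  expect_equal(first1$derived, "AN")
  expect_equal(first2$derived, "AN")
  # but differ in the deeper branching order
  ord1 <- m1@splits$derived[order(m1@splits$time)]
  ord2 <- m2@splits$derived[order(m2@splits$time)]
  expect_equal(ord1, c("AN", "ST", "AA"))
  expect_equal(ord2, c("AN", "AA", "ST"))
  # split times strictly ordered ancestor-after-descendant
  for (lab in modelLabels(set)) {
    mm <- buildScenarioModel(set, lab, drawParameters(set, lab, seed = 9))
    expect_true(all(diff(sort(unique(mm@splits$time))) > 0))
  }
  # model 5: trifurcation, the two shallow merges are simultaneous
  p5 <- drawParameters(set, "model5", seed = 4)
  m5 <- buildScenarioModel(set, "model5", p5)
  expect_equal(sum(m5@splits$time == min(m5@splits$time)), 2L)
  expect_equal(nrow(m5@splits), 3L)
  # and it still simulates a single connected genealogy
  gen <- simulateGenealogy(m5, seed = 5)
  expect_equal(gen@nTips, sum(set@sampleSizes))
})

test_that("scenario configurations round-trip through YAML", {
  set <- ctOriginModels(priorConfig = list(T_CT = list(min = 800, max = 2500)),
                        sampleSizes = c(TK = 30L, AA = 40L, CT = 50L),
                        generationTime = 29)
  path <- tempfile(fileext = ".yaml")
  writeScenarioConfig(set, path)
  back <- readScenarioConfig(path)
  expect_equal(back@name, set@name)
  expect_equal(back@sampleSizes, set@sampleSizes)
  expect_equal(back@generationTime, 29)
  for (lab in modelLabels(set))
    expect_equal(back@models[[lab]]$priors, set@models[[lab]]$priors)
  # and builds behave identically
  p <- drawParameters(back, "demic", seed = 12)
  expect_identical(buildScenarioModel(back, "demic", p)@splits,
                   buildScenarioModel(set, "demic", p)@splits)
})

test_that("malformed prior overrides are rejected", {
  expect_error(ctOriginModels(priorConfig = list(T_CT = list(min = 10, max = 1))),
               "malformed prior")
  expect_error(ctOriginModels(priorConfig = list(N_CT = list(dist = "banana"))),
               "malformed prior")
})

test_that("the shipped scenario YAML files load into working scenario sets", {
  for (f in c("ct_origins.yaml", "language_families.yaml")) {
    set <- readScenarioConfig(system.file("scenarios", f, package = "mitoABC"))
    lab <- modelLabels(set)[1]
    m <- buildScenarioModel(set, lab, drawParameters(set, lab, seed = 2))
    expect_s4_class(m, "DemographicModel")
  }
})
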