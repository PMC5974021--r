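# a single constant-size deme: the workhorse null model for calibration
oneDeme <- function(n, N = 1000, g = 25)
  demographicModel("X", c(X = as.integer(n)), c(X = N), generationTime = g)

test_that("pairwise TMRCA is exponential with mean N_f generations", {
  m <- oneDeme(2)
  set.seed(101)
  tm <- replicate(5000, tmrca(simulateGenealogy(m))) / 25   # generations
  ks <- suppressWarnings(stats::ks.test(tm, "pexp", rate = 1 / 1000))
  expect_gt(ks$p.value, 0.01)
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1000), 3 * se)
})

test_that("total branch length for n = 10 matches the coalescent closed form", {
  m <- oneDeme(10)
  set.seed(102)
  tbl <- replicate(3000, totalBranchLength(simulateGenealogy(m))) / 25
  expected <- 2 * 1000 * sum(1 / (1:9))
  se <- stats::sd(tbl) / sqrt(length(tbl))
  expect_lt(abs(mean(tbl) - expected), 3 * se)
})

test_that("isolated demes never coalesce across the split boundary", {
  m <- demographicModel(
    c("A", "B"), c(A = 5L, B = 5L), c(A = 500, B = 500),
    splits = data.frame(time = 20000, derived = "B", ancestral = "A"))
  set.seed(103)
  for (rep in 1:100) {
    gen <- simulateGenealogy(m)
    n <- gen@nTips
    # nodes joining lineages sampled in both demes must postdate the split
    tipsOf <- function(node) {
      if (node <= n) return(node)
      unlist(lapply(gen@edge[gen@edge[, 1] == node, 2], tipsOf))
    }
    for (node in (n + 1):(2 * n - 1)) {
      demesBelow <- unique(gen@tipDeme[tipsOf(node)])
      if (length(demesBelow) > 1)
        expect_gte(gen@nodeTime[node], 20000)
    }
  }
})

test_that("genealogies are ultrametric, ape-compatible and deme-labeled", {
  m <- demographicModel(
    c("A", "B"), c(A = 4L, B = 3L), c(A = 800, B = 1200),
    splits = data.frame(time = 5000, derived = "B", ancestral = "A"))
  gen <- simulateGenealogy(m, seed = 7)
  phy <- asPhylo(gen)
  expect_s3_class(phy, "phylo")
  expect_true(ape::is.ultrametric(phy, tol = 1e-6))
  expect_equal(ape::Ntip(phy), 7)
  expect_setequal(unique(unname(gen@tipDeme)), c("A", "B"))
  # parent always older than child
  expect_true(all(gen@nodeTime[gen@edge[, 1]] >= gen@nodeTime[gen@edge[, 2]]))
})

test_that("mutation dropping matches the theta expectation for a pair", {
  N <- 1000
  m <- oneDeme(2, N = N)
  mut <- mtMutationModel(rateCoding = 2e-7, rateNoncoding = 2e-7,
                         sitesCoding = 400L, sitesNoncoding = 100L)
  muPerGen <- 2e-7 * 500 * 25           # genome-wide, per generation
  theta <- 2 * N * muPerGen
  set.seed(104)
  diffs <- replicate(5000, {
    alns <- simulateDataset(m, mut)
    pairwiseDifferenceMatrix(alns$X)$diff[1, 2]
  })
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - theta), 3 * se)
})

test_that("zero mutation rates give identical sequences", {
  m <- oneDeme(5)
  mut <- mtMutationModel(rateCoding = 0, rateNoncoding = 0,
                         sitesCoding = 80L, sitesNoncoding = 20L)
  aln <- dropMutations(simulateGenealogy(m, seed = 1), mut, seed = 2)
  expect_equal(length(countHaplotypes(aln)$counts), 1L)
  expect_equal(diversitySummary(aln)@S, 0L)
})

test_that("simulated datasets are deterministic given the seed", {
  set <- demographicModel(
    c("A", "B"), c(A = 4L, B = 4L), c(A = 700, B = 700),
    splits = data.frame(time = 3000, derived = "B", ancestral = "A"))
  mut <- scaleMutationModel(mtMutationModel(), 500)
  d1 <- simulateDataset(set, mut, seed = 31)
  d2 <- simulateDataset(set, mut, seed = 31)
  expect_identical(as.character(d1$A@seqs), as.character(d2$A@seqs))
  expect_identical(as.character(d1$B@seqs), as.character(d2$B@seqs))
  d3 <- simulateDataset(set, mut, seed = 32)
  expect_false(identical(as.character(d1$A@seqs), as.character(d3$A@seqs)))
})

test_that("growth accelerates coalescence looking backward", {
  # strong forward growth: backward the population shrinks fast, so
  # TMRCA is much younger than the constant-size expectation
  grow <- demographicModel(
    "X", c(X = 2L),
    data.frame(deme = "X", start = 0, N = 1e5, growth = 5e-3))
  const <- demographicModel("X", c(X = 2L), c(X = 1e5))
  set.seed(105)
  tGrow <- mean(replicate(400, tmrca(simulateGenealogy(grow))))
  tConst <- mean(replicate(400, tmrca(simulateGenealogy(const))))
  expect_lt(tGrow, tConst / 5)
})

test_that("invalid demographies are rejected with informative errors", {
  expect_error(demographicModel("X", c(X = 2L), c(X = -5)), "N_f")
  expect_error(
    demographicModel(c("A", "B"), c(A = 2L, B = 2L), c(A = 10, B = 10)),
    "root deme")
  # ancestral deme already merged before receiving lineages
  expect_error(demographicModel(
    c("A", "B", "C"), c(A = 2L, B = 2L, C = 2L), c(A = 10, B = 10, C = 10),
    splits = data.frame(time = c(100, 200), derived = c("B", "C"),
                        ancestral = c("A", "B"))),
    "merged")
  # stranded lineages: two demes, no migration, no split
  island0 <- demographicModel(
    c("A", "B"), c(A = 2L, B = 2L), c(A = 10, B = 10),
    migrations = data.frame(from = "A", to = "B", rate = 1e-3,
                            start = 0, end = Inf))
  expect_s4_class(island0, "DemographicModel")
})

test_that("segregating sites are invariant to site order", {
  m <- oneDeme(6)
  mut <- scaleMutationModel(mtMutationModel(), 300)
  aln <- dropMutations(simulateGenealogy(m, seed = 11), mut, seed = 12)
  M <- alignmentMatrix(aln)
  set.seed(13)
  perm <- sample(ncol(M))
  chars <- c("A", "C", "G", "T")
  shuffled <- apply(M[, perm], 1, function(r) {
    r2 <- chars[r]; r2[is.na(r2)] <- "N"; paste(r2, collapse = "")
  })
  aln2 <- mtAlignment(shuffled, sampleIds = sampleIDs(aln))
  expect_equal(diversitySummary(aln2)@S, diversitySummary(aln)@S)
  expect_equal(diversitySummary(aln2)@MPD, diversitySummary(aln)@MPD)
})
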