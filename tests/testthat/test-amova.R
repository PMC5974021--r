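test_that("pairwise Phi-st hits its analytic endpoints", {
  # both populations are copies of the same haplotype list: the among-
  # population SSD is exactly zero, so the unclamped variance component
  # is <= 0 (never positive structure)
  seqs <- c("ACGTACGT", "ACCTACGT", "ACGTACTT")
  a <- toyAln(seqs, c("a1", "a2", "a3"))
  b <- toyAln(seqs, c("b1", "b2", "b3"))
  pm0 <- populationMap(c(paste0("a", 1:3), paste0("b", 1:3)),
                       rep(c("A", "B"), each = 3))
  res0 <- suppressWarnings(amova(poolAlignments(list(a, b)), pm0,
                                 nPermutations = 0))
  expect_equal(res0@components$SSD[1], 0, tolerance = 1e-12)
  expect_lte(suppressWarnings(phiStPair(a, b))$phiST, 0)

  # two fixed haplotypes at distance 10 -> all variance among populations
  x <- paste(rep("A", 20), collapse = "")
  y <- paste(c(rep("C", 10), rep("A", 10)), collapse = "")
  pa <- toyAln(rep(x, 3), paste0("x", 1:3))
  pb <- toyAln(rep(y, 3), paste0("y", 1:3))
  expect_equal(phiStPair(pa, pb)$phiST, 1, tolerance = 1e-12)

  # identical haplotypes everywhere -> zero total variance, flagged 0
  expect_warning(
    res <- phiStPair(toyAln(rep(x, 3), paste0("p", 1:3)),
                     toyAln(rep(x, 3), paste0("q", 1:3))),
    "degenerate")
  expect_equal(res$phiST, 0)
  expect_error(phiStPair(toyAln(x, "only"), pb), "n >= 2")
})

test_that("a mixed two-population toy set matches the brute-force oracle", {
  set.seed(31)
  seqs <- randomToySeqs(8, 30)
  a <- toyAln(seqs[1:4], paste0("a", 1:4))
  b <- toyAln(seqs[5:8], paste0("b", 1:4))
  got <- suppressWarnings(phiStPair(a, b, nPermutations = 200, seed = 5))
  D2 <- oracleDiffMatrix(seqs)
  exp <- oracleAmova1(D2, rep(c("A", "B"), each = 4))
  expect_equal(got$phiST, exp$phiST, tolerance = 1e-12)
  expect_gt(got$p, 0); expect_lte(got$p, 1)
  # seeded permutation stream is reproducible
  expect_identical(
    got$p, suppressWarnings(phiStPair(a, b, nPermutations = 200, seed = 5))$p)
})

test_that("AMOVA components match the independent SSD oracle on random toys", {
  set.seed(90210)
  for (rep in 1:20) {
    nPop <- sample(2:4, 1)
    sizes <- sample(2:4, nPop, replace = TRUE)
    seqs <- randomToySeqs(sum(sizes), 25, missing = 0.05)
    pops <- rep(sprintf("P%d", seq_len(nPop)), sizes)
    aln <- toyAln(seqs)
    pm <- populationMap(sampleIDs(aln), pops)
    got <- suppressWarnings(amova(aln, pm, nPermutations = 0))
    exp <- oracleAmova1(oracleDiffMatrix(seqs), pops)
    expect_equal(got@components$sigma2, c(exp$sigA, exp$sigW), tolerance = 1e-9)
    expect_equal(unname(got@phi["phiST"]), exp$phiST, tolerance = 1e-9)
    expect_equal(sum(got@components$pct), 100, tolerance = 1e-9)
  }
})

test_that("two-level AMOVA matches the oracle and its permutation schemes run", {
  set.seed(512)
  sizes <- c(3, 4, 2, 3)
  seqs <- randomToySeqs(sum(sizes), 30)
  pops <- rep(sprintf("P%d", 1:4), sizes)
  grp <- c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G2")
  aln <- toyAln(seqs)
  pm <- populationMap(sampleIDs(aln), pops, groupings = list(g = grp))
  got <- suppressWarnings(amova(aln, pm, scheme = "g", nPermutations = 99, seed = 3))
  exp <- oracleAmova2(oracleDiffMatrix(seqs), pops, grp)
  expect_equal(got@components$sigma2, c(exp$sigA, exp$sigB, exp$sigW),
               tolerance = 1e-9)
  expect_equal(unname(got@phi), c(exp$phiST, exp$phiSC, exp$phiCT),
               tolerance = 1e-9)
  expect_equal(sum(got@components$pct), 100, tolerance = 1e-9)
  expect_true(all(got@p > 0 & got@p <= 1))
  again <- suppressWarnings(amova(aln, pm, scheme = "g", nPermutations = 99, seed = 3))
  expect_identical(got@p, again@p)
})

test_that("one-level AMOVA on two populations reproduces phiStPair exactly", {
  set.seed(88)
  seqs <- randomToySeqs(9, 25)
  a <- toyAln(seqs[1:5], paste0("a", 1:5))
  b <- toyAln(seqs[6:9], paste0("b", 1:4))
  pm <- populationMap(c(paste0("a", 1:5), paste0("b", 1:4)),
                      rep(c("A", "B"), c(5, 4)))
  full <- amova(poolAlignments(list(a, b)), pm, nPermutations = 0)
  expect_equal(unname(full@phi["phiST"]), phiStPair(a, b)$phiST,
               tolerance = 1e-14)
})

test_that("equidistant fixed haplotypes put 100% of variance among populations", {
  h <- c(paste(rep("A", 30), collapse = ""),
         paste(c(rep("C", 10), rep("A", 20)), collapse = ""),
         paste(c(rep("A", 20), rep("C", 10)), collapse = ""))
  # d = 10 between every pair of haplotypes
  seqs <- rep(h, each = 4)
  pm <- populationMap(sprintf("s%02d", 1:12), rep(c("P1", "P2", "P3"), each = 4))
  res <- amova(toyAln(seqs), pm, nPermutations = 0)
  expect_equal(res@components$sigma2[res@components$source == "Within populations"], 0)
  expect_equal(res@components$pct[res@components$source == "Among populations"], 100)
})

test_that("merging two identical populations adds no among-population SSD", {
  set.seed(14)
  seqs <- randomToySeqs(5, 30)
  pooled <- toyAln(c(seqs, seqs), c(paste0("u", 1:5), paste0("v", 1:5)))
  pm <- populationMap(sampleIDs(pooled), rep(c("P1", "P2"), each = 5))
  res <- suppressWarnings(amova(pooled, pm, nPermutations = 0))
  expect_equal(res@components$SSD[1], 0, tolerance = 1e-9)
  expect_lte(res@components$sigma2[1], 0)   # unclamped, never positive
})

test_that("degenerate designs are flagged rather than failing silently", {
  set.seed(15)
  seqs <- randomToySeqs(8, 30)
  pm1 <- populationMap(sprintf("s%02d", 1:8), rep(c("P1", "P2"), each = 4),
                       groupings = list(g = c(P1 = "G1", P2 = "G2")))
  # one population per group: within-group stratum degenerate
  w1 <- capture_warnings(res <- amova(toyAln(seqs), pm1, scheme = "g",
                                      nPermutations = 0))
  expect_true(any(grepl("degenerate within-group", w1)))
  expect_equal(res@components$df[2], 0)
  expect_equal(unname(res@phi["phiSC"]), 0)
  # a group with a single population among several
  pm2 <- populationMap(sprintf("s%02d", 1:8),
                       rep(c("P1", "P2", "P3"), c(3, 3, 2)),
                       groupings = list(g = c(P1 = "G1", P2 = "G1", P3 = "G2")))
  w2 <- capture_warnings(amova(toyAln(seqs), pm2, scheme = "g",
                               nPermutations = 0))
  expect_true(any(grepl("single population", w2)))
})
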