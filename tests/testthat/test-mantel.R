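randSymMat <- function(n, labels = NULL) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 1, 10)
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

test_that("a scaled matrix gives r = 1 at the smallest attainable p", {
  set.seed(21)
  A <- randSymMat(4)
  res <- mantelTest(A, 2 * A)   # n = 4 -> automatic exact enumeration
  expect_equal(res@r, 1)
  expect_true(res@exact)
  expect_equal(res@p, 1 / 24)   # only the identity relabeling attains r = 1
})

test_that("exact enumeration at n = 4 agrees with the oracle", {
  set.seed(22)
  for (rep in 1:5) {
    A <- randSymMat(4); B <- randSymMat(4)
    res <- mantelTest(A, B, exact = TRUE)
    exp <- oracleMantelExact(A, B)
    expect_equal(res@r, exp$r, tolerance = 1e-12)
    expect_equal(res@p, exp$p, tolerance = 1e-12)
    expect_equal(res@nPermutations, 24L)
  }
})

test_that("r agrees with vegan's Mantel statistic and p is in the same regime", {
  skip_if_not_installed("vegan")
  set.seed(23)
  A <- randSymMat(10); B <- A + randSymMat(10) * 0.5
  res <- mantelTest(A, B, nPermutations = 999, seed = 7)
  vg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
  expect_equal(res@r, unname(vg$statistic), tolerance = 1e-12)
  expect_lt(abs(res@p - vg$signif), 0.05)
})

test_that("r is invariant to joint relabeling and errors are informative", {
  set.seed(24)
  labs <- sprintf("P%d", 1:6)
  A <- randSymMat(6, labs); B <- randSymMat(6, labs)
  r0 <- mantelTest(A, B, nPermutations = 99, seed = 1)@r
  perm <- sample(labs)
  r1 <- mantelTest(A[perm, perm], B[perm, perm], nPermutations = 99, seed = 1)@r
  expect_equal(r1, r0, tolerance = 1e-12)
  # labeled matrices are aligned by label automatically
  r2 <- mantelTest(A, B[perm, perm], nPermutations = 99, seed = 1)@r
  expect_equal(r2, r0, tolerance = 1e-12)

  C <- matrix(1, 5, 5); diag(C) <- 0
  expect_error(mantelTest(C, randSymMat(5)), "constant matrix.*first")
  expect_error(mantelTest(randSymMat(5), C), "constant matrix.*second")
  expect_error(mantelTest(randSymMat(3), randSymMat(3)), "n >= 4")
})

test_that("permutation p-values are seeded and lie in (0, 1]", {
  set.seed(25)
  A <- randSymMat(8); B <- randSymMat(8)
  p1 <- mantelTest(A, B, nPermutations = 199, seed = 11)@p
  p2 <- mantelTest(A, B, nPermutations = 199, seed = 11)@p
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
})

test_that("great-circle distances follow the haversine closed form", {
  pm <- populationMap(
    c("s1", "s2", "s3"), c(s1 = "P1", s2 = "P2", s3 = "P3"),
    coords = data.frame(population = c("P1", "P2", "P3"),
                        lat = c(0, 0, 0), lon = c(0, 180, 0)))
  m <- greatCircleMatrix(pm)
  expect_equal(m["P1", "P3"], 0)
  expect_equal(m["P1", "P2"], pi * 6371, tolerance = 1e-6)  # half circumference
  expect_equal(m, t(m))
  pmBad <- populationMap(c("s1", "s2"), c(s1 = "P1", s2 = "P2"),
                         coords = data.frame(population = "P1", lat = 10, lon = 100))
  expect_error(greatCircleMatrix(pmBad), "P2")
})

test_that("haplotype sharing counts shared and private classes", {
  x <- paste(rep("A", 12), collapse = "")
  y <- paste(c("C", rep("A", 11)), collapse = "")
  z <- paste(c("C", "C", rep("A", 10)), collapse = "")
  # P1: {x, y}; P2: {y, z}; P3: {z}
  aln <- toyAln(c(x, y, y, z, z, z), sprintf("s%d", 1:6))
  pm <- populationMap(sampleIDs(aln), c("P1", "P1", "P2", "P2", "P3", "P3"))
  m <- haplotypeSharingMatrix(aln, pm)
  expect_equal(m["P1", "P2"], 1L)   # y shared
  expect_equal(m["P2", "P3"], 1L)   # z shared
  expect_equal(m["P1", "P3"], 0L)
  expect_equal(m["P1", "P1"], 1L)   # x private
  expect_equal(m["P3", "P3"], 0L)   # z also found in P2
  expect_equal(m, t(m))

  # disjoint haplotype sets -> zero off-diagonal
  a <- toyAln(c(x, x, z, z), sprintf("t%d", 1:4))
  pmA <- populationMap(sampleIDs(a), rep(c("Q1", "Q2"), each = 2))
  mA <- haplotypeSharingMatrix(a, pmA)
  expect_equal(mA["Q1", "Q2"], 0L)
  expect_equal(diag(mA), c(Q1 = 1L, Q2 = 1L))
})
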