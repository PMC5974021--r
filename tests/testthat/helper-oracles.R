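# Independent brute-force oracles, written naively (explicit loops,
# textbook formulas) so they share no code with the package internals.

# per-site pairwise difference with pairwise deletion
oracleDiff <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  d <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% c("A", "C", "G", "T") && b[i] %in% c("A", "C", "G", "T") &&
        a[i] != b[i]) d <- d + 1L
  }
  d
}

oracleDiffMatrix <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- oracleDiff(seqs[i], seqs[j])
  D
}

# one-level AMOVA from the squared-distance matrix, loop form
oracleAmova1 <- function(D2, pop) {
  pop <- as.character(pop)
  N <- length(pop); pops <- unique(pop); P <- length(pops)
  ssdTot <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) ssdTot <- ssdTot + D2[i, j]
  ssdTot <- ssdTot / (2 * N)
  ssdWP <- 0
  np <- numeric(P)
  for (k in seq_len(P)) {
    idx <- which(pop == pops[k]); np[k] <- length(idx)
    s <- 0
    for (i in idx) for (j in idx) s <- s + D2[i, j]
    ssdWP <- ssdWP + s / (2 * np[k])
  }
  ssdAP <- ssdTot - ssdWP
  sigW <- ssdWP / (N - P)
  n0 <- (N - sum(np^2) / N) / (P - 1)
  sigA <- (ssdAP / (P - 1) - sigW) / n0
  list(sigA = sigA, sigW = sigW,
       phiST = if (sigA + sigW == 0) 0 else sigA / (sigA + sigW))
}

# two-level AMOVA, loop form with the Excoffier unequal-n coefficients
oracleAmova2 <- function(D2, pop, groupOfPop) {
  pop <- as.character(pop)
  N <- length(pop); pops <- unique(pop); P <- length(pops)
  grp <- unname(groupOfPop[pop])
  groups <- unique(unname(groupOfPop[pops])); G <- length(groups)
  sumD2 <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + D2[i, j]
    s
  }
  ssdTot <- sumD2(seq_len(N)) / (2 * N)
  np <- sapply(pops, function(p) sum(pop == p))
  ssdWP <- sum(sapply(pops, function(p) sumD2(which(pop == p)) / (2 * sum(pop == p))))
  Ng <- sapply(groups, function(g) sum(grp == g))
  ssdTotG <- sapply(groups, function(g) sumD2(which(grp == g))) / (2 * Ng)
  ssdWPG <- sapply(groups, function(g)
    sum(sapply(pops[groupOfPop[pops] == g], function(p)
      sumD2(which(pop == p)) / (2 * sum(pop == p)))))
  ssdAPWG <- sum(ssdTotG - ssdWPG)
  ssdAG <- ssdTot - ssdWP - ssdAPWG
  sigW <- ssdWP / (N - P)
  Sg <- sapply(groups, function(g) sum(np[groupOfPop[pops] == g]^2))
  a <- (N - sum(Sg / Ng)) / (P - G)
  b <- (sum(Sg / Ng) - sum(np^2) / N) / (G - 1)
  cc <- (N - sum(Ng^2) / N) / (G - 1)
  sigB <- (ssdAPWG / (P - G) - sigW) / a
  sigA <- (ssdAG / (G - 1) - sigW - b * sigB) / cc
  tot <- sigA + sigB + sigW
  list(sigA = sigA, sigB = sigB, sigW = sigW,
       phiST = (sigA + sigB) / tot, phiSC = sigB / (sigB + sigW),
       phiCT = sigA / tot)
}

# exhaustive Mantel p-value: all n! joint relabelings of the second matrix
oracleMantelExact <- function(A, B) {
  n <- nrow(A)
  perms <- NULL
  gen <- function(v, rest) {
    if (!length(rest)) { perms[[length(perms) + 1L]] <<- v; return(invisible()) }
    for (x in rest) gen(c(v, x), setdiff(rest, x))
  }
  perms <- list(); gen(integer(0), seq_len(n))
  rObs <- cor(A[upper.tri(A)], B[upper.tri(B)])
  rs <- sapply(perms, function(p) {
    Bp <- B[p, p]
    cor(A[upper.tri(A)], Bp[upper.tri(Bp)])
  })
  list(r = rObs, p = mean(rs >= rObs - 1e-12))
}

# random toy alignment over {A,C,G,T} with optional N/- contamination
randomToySeqs <- function(n, L, missing = 0.05) {
  chars <- c("A", "C", "G", "T")
  sapply(seq_len(n), function(i) {
    s <- sample(chars, L, replace = TRUE)
    if (missing > 0) {
      k <- rbinom(1, L, missing)
      if (k > 0) s[sample.int(L, k)] <- sample(c("N", "-"), k, replace = TRUE)
    }
    paste(s, collapse = "")
  })
}

toyAln <- function(seqs, ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(seqs))
  names(seqs) <- ids
  mtAlignment(seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
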