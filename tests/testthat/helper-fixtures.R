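# lazily built, shared across test files (ABC fixtures are the costly ones)
.cache <- new.env(parent = emptyenv())

# two cleanly separable 2-deme scenarios: recent-split panmixia-like vs a
# deep split at many coalescent times, both at fixed moderate theta
separableSet <- function(n = 10L) {
  mk <- function(tmin, tmax) {
    pr <- rbind(
      data.frame(name = "N", dist = "fixed", min = 1000, max = 1000),
      data.frame(name = "T", dist = "uniform", min = tmin, max = tmax))
    build <- function(p, ss, g) {
      demographicModel(
        c("A", "B"), ss[c("A", "B")], c(A = unname(p["N"]), B = unname(p["N"])),
        splits = data.frame(time = unname(p["T"]), derived = "B", ancestral = "A"),
        generationTime = g)
    }
    list(priors = pr, build = build)
  }
  scenarioSet("separable",
              list(panmixia = mk(10, 100), deepsplit = mk(150000, 400000)),
              c(A = n, B = n))
}

sepMutModel <- function(L = 1000L) scaleMutationModel(mtMutationModel(), L)

getSeparableFit <- function() {
  if (!is.null(.cache$sepFit)) return(.cache$sepFit)
  set <- separableSet()
  ref <- buildReferenceTable(set, 220, sepMutModel(), seed = 7001)
  ref <- appendLdaAxes(ref)
  fit <- fitModelChoice(ref, nTrees = 200, seed = 7002)
  .cache$sepFit <- list(set = set, ref = ref, fit = fit)
  .cache$sepFit
}
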