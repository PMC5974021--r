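# mitoABC

Demographic inference from complete mitochondrial genome alignments:
descriptive population-genetic statistics, a single-locus structured
coalescent simulator, demographic-scenario templates for the peopling of
Mainland Southeast Asia, and approximate Bayesian computation (ABC) model
choice with random forests.

## The scientific problem

Complete mtDNA genomes (~16.5 kb, maternally inherited, non-recombining)
are widely used to ask how language spreads relate to population
movements. The motivating question for this package is the origin of
Tai-Kadai (TK) speaking groups such as the central Thai: did they arise by
**demic diffusion** (migration of people from a southern-Chinese TK
source), **cultural diffusion** (local Austroasiatic residents shifting
language), or **continuous migration** (a migrating source with ongoing
gene flow into resident groups)? Parallel questions concern the deeper
genetic relationships of populations speaking Austroasiatic (AA),
Austronesian (AN), Sino-Tibetan (ST) and TK languages.

The package implements the full inferential chain:

- **Descriptive statistics** (per population, under pairwise deletion of
  `N`/`-`): haplotype count, segregating sites *S*, gene diversity
  *h* = *n*(1 − Σ*p*²)/(*n* − 1) with Nei (1987) SD, mean pairwise
  differences (MPD) with Tajima (1983) SD, nucleotide diversity
  π = MPD/*L*<sub>eff</sub>, and Tajima's *D*.
- **Φ<sub>ST</sub> and hierarchical AMOVA** in the Excoffier (1992)
  convention (the count of pairwise differences is the squared
  inter-haplotype distance), with unequal-sample-size coefficients,
  unclamped variance components, and the three standard permutation
  schemes for Φ<sub>ST</sub>, Φ<sub>SC</sub> and Φ<sub>CT</sub>.
- **Mantel tests** (one-tailed permutation, exact enumeration at small
  *n*) against great-circle distance matrices, and **haplotype-sharing
  matrices** (shared and private haplotype classes per population pair).
- A **structured coalescent simulator** for matrilineal demographies:
  population splits, piecewise exponential growth (closed-form
  time-rescaled waiting times), interval-bounded backward migration, and
  a two-partition finite-sites Jukes-Cantor mutation model with
  coding/noncoding rates 1.708 × 10⁻⁸ and 9.883 × 10⁻⁸
  substitutions/site/year.
- **ABC-RF model choice** (Pudlo et al. 2016 style): balanced reference
  tables of (model, parameters, summaries), optional LDA-augmented
  summaries, a 500-tree random-forest classifier with out-of-bag prior
  error rate and confusion matrix, tree-vote fractions for the observed
  data, the posterior probability of the selected model from a second
  regression forest, and posterior parameter quantiles from quantile
  regression forests.
- A **synthetic-data module** (island model and hierarchical
  "study-like" fixtures with two grouping schemes and coordinates) so
  every stage is testable against known ground truth.

## Worked example

A small simulated example dataset ships with the package (three
populations labeled with TK/AA/ST language families, 6 sequences each,
1,200 sites):

```r
library(mitoABC)
fa  <- system.file("extdata", "synthetic_example_alignment.fasta", package = "mitoABC")
tsv <- system.file("extdata", "synthetic_example_metadata.tsv",    package = "mitoABC")
aln    <- readFastaAlignment(fa)
popmap <- readPopulationTable(tsv)

diversityTable(aln, popmap)
#>   population n n_haplotypes S     h  h_sd   MPD MPD_sd       pi    pi_sd
#> 1       G1P1 6            4 4 0.867 0.129 1.933  1.466 0.001611 0.001221
#> 2       G2P1 6            2 1 0.333 0.215 0.333  0.439 0.000278 0.000366
#> 3       G3P1 6            2 2 0.333 0.215 0.667  0.678 0.000556 0.000565

amova(aln, popmap, nPermutations = 1000, seed = 7)
#> AMOVA
#>              source df      SSD    sigma2   pct
#>   Among populations  2 4.444444 0.2888889 37.14
#>  Within populations 15 7.333333 0.4888889 62.86
#>   phiST = 0.3714  (P = 0.000999)
```

37% of the molecular variance lies among the three populations
(Φ<sub>ST</sub> = 0.371), significant at P < 0.01 — unsurprising, since
the fixture's populations diverged 20,000 years ago with no migration.

ABC model choice at desk scale — observed data simulated under demic
diffusion (known truth: founding split 1,750 years ago), 200 simulations
per scenario, 500 trees:

```r
set <- ctOriginModels(sampleSizes = c(TK = 15L, AA = 15L, CT = 15L))
mut <- scaleMutationModel(mtMutationModel(), 1000)
truth <- c(N_TK = 1000, N_AA = 1000, N_CT = 1000, r_TK = 0, r_AA = 0,
           r_CT = 0, T_CT = 1750, T_ROOT = 15000)
obs <- generateScenarioFixture(set, "demic", mut, params = truth, seed = 99)
ref <- appendLdaAxes(buildReferenceTable(set, 200, mut, seed = 1))
fit <- fitModelChoice(ref, nTrees = 500, seed = 2)
predictModel(fit, obs$summary)
#> ABC-RF model choice
#>   votes: continuous=0.504, cultural=0.012, demic=0.484
#>   selected: continuous (posterior probability 0.484)
#>   prior error rate: 0.473 at 500 trees

estimateParameters(ref, "demic", obs$summary, nTrees = 200, seed = 3,
                   parameters = c("T_CT", "T_ROOT"))
#> Posterior parameter estimates (model 'demic')
#>  parameter      mean    median      q025      q975
#>       T_CT  1255.648  1096.865  510.7958  2774.009
#>     T_ROOT 13017.832 10490.194 5348.6235 28261.479
```

The cultural-diffusion scenario is firmly rejected (1% of tree votes),
while demic and continuous migration split the remaining votes almost
evenly — they differ only by a migration term, so at this scale the
forest genuinely cannot tell them apart (which the high prior error rate
also reports). The posterior median of the founding split time under the
demic model (1,097 years; 95% interval 511–2,774) brackets the true
1,750 years.

An end-to-end run (data → statistics → reference table → model choice →
parameter estimation) is a single call: `runPipeline(config)` with a
YAML/list configuration; see `?runPipeline`.

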