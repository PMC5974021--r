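---
title: "Models and methods behind mitoABC"
author: "mitoABC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitoABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitoABC infers demographic history from complete mitochondrial genome
alignments. This vignette is the package's own account of the models it
implements, the conventions and defaults it commits to, and what its
tests do and do not demonstrate.

# The data model

An `MtAlignment` holds equal-length haploid sequences over
`{A,C,G,T,N,-}`. Other IUPAC ambiguity codes are demoted to `N` on read
(with a reported count) because every statistic in the package treats
only `{A,C,G,T}` as informative. All pairwise comparisons use **pairwise
deletion**: a site contributes to a pair only when both sequences carry
an unambiguous base. This is the robust choice for heterogeneous-coverage
mtDNA data; the alternative (complete deletion) discards whole columns
and can change diversity values in the second decimal, which is why
per-sample effective length `L_eff` (the mean number of comparable sites
over pairs) is reported and used as the denominator of nucleotide
diversity, so that `pi = MPD / L_eff` holds exactly.

Haplotype identity uses *compatibility* under missing data: two
sequences share a haplotype iff they agree at every mutually informative
site, so `N`/`-` never create a difference. Compatibility is not
transitive; each sequence joins the earliest-seen compatible class,
compared against the class founder. This can merge classes that exact
string matching would keep apart — deliberately, since partially missing
sequences should not inflate haplotype counts.

# Diversity statistics

Per population (n ≥ 2): haplotype count, segregating sites S, gene
diversity `h = n(1 - sum p_i^2)/(n-1)` with the Nei (1987) sampling
variance, mean pairwise differences (MPD) over all C(n,2) pairs, and
`pi = MPD/L_eff`. The SDs of MPD and pi use the standard total
(stochastic + sampling) variances, `b1*k + b2*k^2` with
`b1 = (n+1)/(3(n-1))` and `b2 = 2(n^2+n+3)/(9n(n-1))` (Tajima 1983; Nei
1987 eq. 10.7 for the per-site version). Published tables produced by
other software can differ from these SDs in the second decimal depending
on deletion settings and variance convention; the point estimates are
convention-free given pairwise deletion.

# AMOVA and Phi statistics

The AMOVA is the distance-based Excoffier (1992) decomposition. Under
the "pairwise difference" distance, the count of differing sites **is**
the squared Euclidean inter-haplotype distance (each site contributes
(x_i - x_j)^2 ∈ {0,1}), so the sums of squares are built directly from
the difference-count matrix — the counts are not squared again. This
matters: squaring the counts depresses the island-model Phi-ST from the
1/(1+2Nm) neighbourhood (~0.46 observed at the package's default island
fixture) down to ~0.38, visibly off the classical expectation.

Variance components use the textbook unequal-sample-size coefficients
and are reported **unclamped**: negative components are legitimate
estimator outcomes (a flag is raised). One consequence worth knowing:
two populations with identical composition have exactly zero
among-population sum of squares but a *negative* variance component
(hence negative Phi-ST), not zero — the same behaviour as standard
software. Degenerate designs are handled explicitly: zero total variance
reports Phi = 0 with a flag; one population per group collapses the
within-group stratum and reduces to a one-level analysis on groups.

Permutation tests use three schemes — individuals among populations
overall (Phi-ST), individuals among populations within groups (Phi-SC),
and whole populations among groups (Phi-CT) — with 10,000 permutations
by default and p-values that count the observed arrangement in both
numerator and denominator, so p ∈ (0,1] always.

The Mantel test correlates the off-diagonal entries of two distance
matrices, one-tailed for positive association (the isolation-by-distance
alternative). At n ≤ 8 with enough requested permutations it enumerates
all n! relabelings exactly. Geographic distances are haversine
great-circle distances on a 6,371 km Earth radius.

# The structured coalescent simulator

The simulator is a backward-in-time structured coalescent for a single
non-recombining matrilineal locus. Time is kept in years and converted
with a generation time g (default 25 years). Within a deme with k
lineages and effective female size N_f(t), pairs coalesce at rate
C(k,2)/N_f(t) per generation. Growth is exponential within an epoch,
parameterized by a forward per-year rate r, so backward in time
`N(t) = N_start * exp(-r (t - t_start))`; waiting times under the
time-varying rate have a closed-form inverse of the cumulative hazard,
so no discretization is involved. Migration is **conservative backward
migration**: a lineage in deme i moves to j at the per-generation rate
m_ij (the standard structured-coalescent convention — documented to
avoid forward/backward confusion). At a split time, all lineages of the
derived deme merge into the ancestral deme. A model must either reduce
to a single root deme or keep its surviving demes connected by
open-ended migration (the island model), otherwise validation rejects it
as potentially non-terminating.

Mutations are dropped on branches as a Poisson process with
partition-specific rates: by default 15,447 coding sites at 1.708e-8 and
1,122 noncoding sites at 9.883e-8 substitutions/site/year (the
two-partition rates standard for complete mtDNA genomes), rescalable to
shorter alignments with the proportions kept. The substitution scheme is
finite-sites Jukes-Cantor from an all-A ancestral sequence; since every
statistic in the package is exchangeable over site order, the partition
is realized as a contiguous noncoding block followed by the coding
block. JC is the minimal defensible default for simulation-based
inference whose summaries never use site identities; it is configurable
in the sense that rates and partition sizes are free, but no other
substitution matrix is currently implemented. Finite sites imply repeat
hits: the number of *segregating sites* falls slightly below the
infinite-sites expectation when theta per site is appreciable, which is
why calibration checks spread the same genome-wide theta over enough
sites to make collisions negligible.

# Scenario templates and priors

Two scenario sets mirror the competing hypotheses for Mainland Southeast
Asia.

**Central-Thai origins** (`ctOriginModels()`), demes TK (southern-Chinese
Tai-Kadai source), AA (local Austroasiatic), CT (central Thai): demic
(CT splits from TK), cultural (CT splits from AA), continuous (CT splits
from TK with symmetric CT–AA migration since the split; at m = 0 it
collapses to demic). AA merges into TK at the deep root split in all
three.

**Language-family relationships** (`languageFamilyModels()`), demes AA,
AN, ST, TK: five rooted population trees. Models 1 and 2 share a (TK,AN)
cherry — `(((TK,AN),ST),AA)` and `(((TK,AN),AA),ST)` respectively;
Model 3 is `((AA,(ST,TK)),AN)`; Model 4 `(((AA,TK),ST),AN)`; Model 5 a
simultaneous trifurcation of AA, TK, ST with AN outgroup. Model 3's
exact internal branching is a configurable assumption (the published
linguistic tree it follows is not fully specified in genetic terms);
whether the tree models carry post-split migration was an open design
point, resolved as *no migration* to keep the trees identifiable from a
single locus.

Default priors (overridable per parameter, and versioned in the shipped
YAML files under `inst/scenarios/`): effective female sizes log-uniform
on [1e2, 1e5]; the recent CT founding split uniform on [0.5, 3] kya
(anchoring the southward TK expansion); the deep TK–AA root split
uniform on [5, 30] kya; the deepest language-family splits start uniform
on [3, 8] kya with positive uniform increments of [0.5, 8] kya per
deeper node (which enforces ancestor-before-descendant ordering by
construction); growth rates uniform on [0, 1e-3]/year for all three
CT-origin demes; continuous-migration rate log-uniform on [1e-6, 1e-2]
per generation. These are documented stand-ins chosen on the published
anchors for the region's history, not fitted values. Default sample
sizes (TK = 150, AA = 150, CT = 210; 100 per language family) stand in
for the pooled study groups; analyses at reduced sizes pass
`sampleSizes` explicitly.

# ABC with random forests

`buildReferenceTable()` simulates a balanced table of (model label,
parameter draw, summary vector). The summary schema is fixed and
computed by the identical code path for observed and simulated data: per
deme the haplotype fraction, h, S, MPD, pi and Tajima's D; per deme pair
the Phi-ST point estimate, mean between-deme differences, and shared
haplotype-class counts. A deme with n < 2 yields NaN for its undefined
entries, with a flag.

`appendLdaAxes()` adds the k-1 linear-discriminant projections as extra
summary columns (the ABC-RF convention — they complement, never replace,
the raw summaries) and stores the affine projection for reuse on the
observed vector. A singular within-class scatter falls back to a
ridge-regularized eigendecomposition with a warning.

`fitModelChoice()` trains a 500-tree (default) random forest
(features-per-split sqrt(p), bootstrap sampling, single-threaded for bit
reproducibility under a seed). The **prior error rate** is the
out-of-bag misclassification rate, reported along a grid of forest sizes
(every 50 trees) so the user can verify the forest has converged; the
out-of-bag **confusion matrix** shows which scenarios are mutually
confusable. For an observed dataset, `predictModel()` reports the
fraction of trees voting for each model and estimates the **posterior
probability of the selected model** with a second regression forest
trained on the indicator that a row's out-of-bag prediction equals its
true label, evaluated at the observed point — a per-dataset quantity
distinct from the vote shares.

One design decision deserves emphasis. NaN summaries are imputed by
**pooled** training medians (with missingness-indicator features), not
per-model medians. Per-model imputation looks natural but leaks the
label: every NaN row receives a class-specific value, and a forest then
separates two *identical* scenarios below chance (we measured out-of-bag
error 0.445 instead of ~0.5 at 1,000 rows per model — a five-sigma
artifact). Pooled imputation restores the correct chance-level behaviour
for indistinguishable models while the indicators retain any genuine
signal in missingness itself.

`estimateParameters()` fits one quantile regression forest per free
parameter on the rows of a single model and reports the posterior mean,
median and central 95% interval at the observed point from the
terminal-node weight distribution. Parameters with constant draws (e.g.
point-mass priors) are skipped with a note.

# The synthetic-data module

`generateIslandDataset()` builds a finite-island model (default 8 demes,
20 haploid samples each, N_f = 1000, Nm = 0.5, 2,000 sites) whose
among-deme fixation index has the classical 1/(1+2Nm) = 0.5 expectation
in the many-deme limit; at 8 demes the finite-deme correction and the
single-locus ratio bias put the realized mean near 0.46.
`generateStudyLikeFixture()` builds the hierarchical shape of a
multi-population mtDNA survey: groups of populations with recent
within-group splits (default 2 kya) and much older between-group splits
(default 20 kya), a `family` grouping that matches the generating
hierarchy, an orthogonal `region` grouping that cuts across it, and
family-clustered coordinates in Thailand-like ranges. The default
per-population size N_f = 1,500 is calibrated so that *full-length*
(16,569-site) fixtures average per-population MPD in the 30–39 band
typical of complete mtDNA surveys in this region; the default 2,000-site
length exists so the test suite runs in minutes.

What the fixtures deliberately do **not** emulate: real haplogroup
composition, phylogeographic detail, sequencing error, heteroplasmy, or
recombination (absent in mtDNA). Passing tests on fixtures therefore
demonstrates the correctness of the estimators and the machinery, not
that any particular real dataset satisfies the models' assumptions.

# Numerical choices and reproducibility

- Permutation p-values include the observed arrangement:
  `p = (1 + #{perm >= obs}) / (1 + B)`, with a 1e-12 tolerance on the
  `>=` comparison against floating-point ties.
- All stochastic entry points accept a `seed` and restore the RNG state
  afterwards; forests run with `num.threads = 1` and an explicit seed,
  making reference tables, votes and posterior numbers bit-reproducible.
- The pipeline (`runPipeline()`) derives all stage seeds from one master
  seed by fixed offsets, stamps the report with a hash of the analytic
  configuration (the output directory is excluded from the hash), and
  can resume from an existing reference-table CSV — the one stage worth
  caching; the cheaper stages are recomputed.
- Reference-table CSVs are written with 17 significant digits and
  explicit `NaN`, so write-read round trips are bitwise.
- Ties in forest voting are broken toward the first class index; ties in
  haplotype classing merge into the earliest-seen class.

# Problem sizes used by the test suite

The suite validates at sizes chosen to finish on one CPU in minutes:
AMOVA equivalence against a brute-force oracle on 50 random toy datasets
(≤12 sequences); pairwise-TMRCA calibration at 10,000 replicates and
Watterson calibration at 6,000 replicates (theta spread over 5,000 sites
so repeat hits are negligible); island-model Phi-ST over 100 replicate
datasets at the generator defaults; indistinguishability at 1,000 rows
per model and 500 trees; separability and origin-scenario recovery at
400 rows per model (15 samples per deme, 1,000 sites); split-time
coverage over 100 synthetic repetitions against one 1,000-row table; and
Mantel type-I error over 500 replicates at 199 permutations.

# Known limitations

- A single non-recombining locus carries one genealogy: every statistic
  has large genealogical variance, and ratio statistics such as Phi-ST
  are biased slightly below their coalescent expectations in any single
  dataset. The tests average over replicate datasets for exactly this
  reason.
- The out-of-bag prior error rate of a random forest sits slightly above
  the true error for hard problems (the classic bootstrap pessimism);
  for indistinguishable models expect ~0.52, not exactly 0.5.
- Demic vs continuous migration are genuinely confounded when the
  migration rate is small — that is a property of the models, faithfully
  reproduced, not a deficiency of the classifier.
- The finite-sites mutation scheme makes segregating-site counts fall
  below infinite-sites formulas at high per-site theta.
- Only Jukes-Cantor substitution is implemented; rate heterogeneity
  among sites within a partition is not modelled.
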