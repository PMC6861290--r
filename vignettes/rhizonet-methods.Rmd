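---
title: "Methods and design of the rhizonet analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the rhizonet analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

# Scope

`rhizonet` covers the stages of a paired bacterial/fungal amplicon
analysis that begin *after* denoising: quality filtering of sequence
variants (SVs), taxonomy handling, diversity and distance computation,
permutation inference, and per-treatment-group Spearman co-occurrence
networks over a merged cross-kingdom genus table. Denoising itself,
chimera removal and reference-database taxonomy assignment are out of
scope; the package consumes the count and taxonomy tables those
pipelines produce. A seeded generator of synthetic experiments stands in
for real sequencing data throughout development and testing, and is a
first-class, tested module in its own right.

The motivating design is a glasshouse mixed-cropping experiment: two
crop varieties ("A" and "W") grown either as mono-crops or together,
giving four root treatment groups, plus a few start-of-experiment soil
samples. All defaults below mirror that design.

# The synthetic experiment generator

## Generative model

For genus $g$ the baseline log-abundance is
$\mu_{0g} \sim N(m, s^2)$, with per-variety offsets
$\delta_{Ag}, \delta_{Wg} \sim N(0, \sigma_v^2)$. Mono-crop group
centroids are $\mu_{0} + \delta_V$. Under mixed cropping, variety $V$'s
centroid is blended towards the other variety:

$$\mathrm{centroid}_{\mathrm{mixed},V} =
  (1-\lambda_{kV})\,(\mu_0 + \delta_V) + \lambda_{kV}\,(\mu_0 + \delta_{V'})$$

where $\lambda_{kV} \in [0,1]$ is a per-kingdom ($k$), per-variety
mixing coefficient. $\lambda = 0$ reproduces the mono-crop centroid
exactly (asserted in tests); $\lambda = 1$ moves the group fully onto
the other variety's centroid.

Each sample's latent vector is its group centroid plus Gaussian noise
whose correlation matrix is the identity except for *planted blocks*:
sets of features (possibly spanning kingdoms) given a common latent
correlation $r$ in the treatment groups where the block is active.
Bacterial and fungal latents are drawn jointly from one multivariate
normal and split afterwards, so cross-kingdom blocks are honoured and
bacterial–fungal distance concordance is plantable. If a block
configuration makes the matrix indefinite it is repaired to the nearest
positive-definite correlation matrix (recorded in the run log); a repair
that moves any entry by more than 0.25 aborts with the offending block
named.

Counts are drawn per kingdom as
$\mathrm{multinomial}(\mathrm{softmax}(\mathrm{latent}), D)$ with depth
$D$ uniform on a per-kingdom range. The log-normal latent / softmax /
multinomial chain is a deliberately simple compositional surrogate: it
produces overdispersed, correlated, closed counts and is fully seedable
(identical scenario + seed gives bit-identical tables). A
negative-binomial depth model was considered and rejected as an extra
parameter with no downstream consumer; the uniform range already spans
the order-of-magnitude depth variation real runs show.

## Defaults and what they emulate

| parameter | default | rationale |
|---|---|---|
| group sizes | 16/11/11/16 (+3 soil) | 8 mono pots × 2 plants, 11 mixed pots × 1 plant per variety; 3 potting-soil samples |
| genera | 100 bacteria, 25 fungi | root communities are bacteria-dominated; few fungal genera |
| $m, s$ | 0, 1 | order-of-magnitude abundance spread typical of genus tables |
| $\sigma_v$, noise sd | 1, 1 | variety effects comparable to within-group variation |
| $\lambda$ | bacteria (A: 0.6, W: 0.05); fungi (A: 0.05, W: 0.6) | the kingdom-asymmetric convergence pattern the design is built to detect: bacterial communities of mixed-cropped A shift towards W while W's stay put, and vice versa for fungi |
| depth ranges | bacteria 14020–95216; fungi 2653–13954 | per-sample read-count ranges typical of paired 16S/ITS MiSeq runs of this size |
| SV expansion | ~3 SVs/genus, lengths $N(253, 3^2)$ | modal 16S V4 contig length 253 bp |

The generator emulates: treatment-dependent composition shifts, planted
correlation structure, depth variation, SV-level length outliers,
negative-control contaminants and rare SVs. It does **not** emulate:
read-level error, chimeras, taxonomic mis-assignment, overdispersion
beyond the latent Gaussian, or soil-to-root source structure (soil
samples are drawn around the baseline centroid only). Passing recovery
tests therefore demonstrates that the analysis machinery detects the
structure this model plants, not that it is robust to every artefact of
real sequencing data.

One deliberate simplification surfaced during calibration work and is
worth stating: Spearman correlations computed on **raw** counts with
variable depth are grossly anti-conservative, because depth acts as a
common positive driver of every feature (null p < 0.05 rates well above
the nominal level; the test suite demonstrates the inflation on raw
counts). Rarefying to a common depth before correlation — the order the
pipeline enforces — restores the rate to near 0.05, as the acceptance
script's calibration check measures directly.
The residual slight excess is the compositional closure
of the multinomial draw, which plain Spearman analysis accepts by
construction; compositionality-aware estimators (SparCC and relatives)
are out of scope because the pipeline reproduces the plain-Spearman
method.

# Preprocessing rules

* **Length window** is inclusive on both ends and optional per kingdom:
  16S data are filtered to the expected amplicon window (default
  240–260 bp, i.e. removing lengths > 260 bp among merged V4 contigs);
  ITS data are left unfiltered because the region's length is
  legitimately variable.
* **"Fewer than 100 reads" removed** means row totals ≥ 100 are kept; a
  total of exactly 100 survives.
* **Negative-control SV removal precedes the read-count rule.** The
  order is configurable in principle and always recorded in the filter
  report, since with both rules active the order can change which rule a
  feature is attributed to (never the surviving set).
* **Taxonomy fill-down** replaces each missing rank with
  `<Rank>_<name>` of the deepest assigned rank (`Family_Prevotellaceae`,
  `Class_Bacilli`), keeping unassigned features alive through rank
  agglomeration while flagging the provenance of the name. The
  operation is idempotent and fails loudly on features with no
  assignment at any rank.
* **Rarefaction** subsamples without replacement (sequential
  conditional hypergeometric draws, exact and O(features) per sample),
  drops samples below the target depth with a warning recorded in the
  report, and by default retains all-zero feature rows so feature axes
  stay comparable across iterations; `dropEmpty = TRUE` removes them.
  A test verifies the singleton-inclusion probability against the
  closed-form hypergeometric expectation.

# Distances and richness

Bray-Curtis operates on counts as given (the caller rarefies first when
depth bias matters); Jensen-Shannon divergence always converts to
relative abundances. JSD uses the natural logarithm with
$0 \log 0 \equiv 0$ and is reported as a plain divergence (not its
square root), so its upper bound is $\ln 2$, attained exactly on
disjoint supports — both asserted in tests. Jaccard defaults to the
binary (presence/absence) form, giving an incidence-vs-abundance
contrast with JSD; the quantitative variant $2BC/(1+BC)$ is available as
`jaccard_quant` and the pipeline logs which was used, since published
analyses often leave the choice implicit.

Iterative rarefied richness follows the standard recipe: rarefy every
sample to the shallowest sample's depth, count non-zero features, repeat
(default 100 trials, child seed per trial) and average. The mean matches
the closed-form hypergeometric expectation
$\sum_f [1 - \binom{N-n_f}{d}/\binom{N}{d}]$ within Monte-Carlo error.

# Permutation inference from first principles

**PERMANOVA** (one-way): $SS_T = \frac1n \sum_{i<j} d_{ij}^2$,
$SS_W = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2$, pseudo-F
$= [SS_A/(a-1)]/[SS_W/(n-a)]$ with $SS_A = SS_T - SS_W$, and
$R^2 = SS_A/SS_T$. The null permutes group labels; the sampled p-value
uses the add-one correction $(\#\{F^\pi \ge F\}+1)/(n_{perm}+1)$, so p
is never zero and the observed statistic is always part of its own
reference distribution. With univariate Euclidean input the pseudo-F
reproduces the classical ANOVA F to machine precision (an oracle test).
Only the one-way design is implemented: the motivating analysis has a
single four-level treatment factor, so strata and multi-factor
partitioning would be dead code.

When exhaustive enumeration is requested and feasible, all distinct
label assignments are generated and p is the exact fraction with
$F^\pi \ge F$. One subtlety: with two equal groups every assignment's
complement produces the identical F, so even a strictly maximal observed
statistic has exhaustive p of $2/\binom{n}{n_1}$, not
$1/\binom{n}{n_1}$ — the test suite pins this down by brute force.

**Mantel**: Pearson correlation (Spearman available) of the two
upper-triangle vectors, with the null built by simultaneously permuting
rows and columns of the second matrix; one-sided for positive
association, add-one corrected, exact when $n! \le n_{perm}$.

**NMDS**: Kruskal stress-1,
$\sqrt{\sum(d - \hat d)^2 / \sum d^2}$, minimized by alternating
isotonic regression of configuration distances on dissimilarity rank
order (pool-adjacent-violators via `stats::isoreg`) with a Guttman
transform update. Ties in the dissimilarities are handled by the primary
(weak) approach. Defaults: $k = 2$, 20 random restarts plus one
classical-MDS start, tolerance $10^{-6}$ on the stress change, 500
iterations. Coordinates are centred; stress is invariant to rotation
and reflection, so coordinates are comparable only up to isometry.
Non-convergence in every restart returns the best configuration with
`converged = FALSE` and a warning rather than an error.

Permutation counts default to 999 everywhere — the field's convention;
nothing in the method requires more unless small p-values must be
resolved finely.

# Co-occurrence tiers and networks

Per treatment group, over that group's root samples only (soil never
enters networks), the package computes Spearman $\rho$ for every
unordered pair of the merged genus table. The threshold notation
"$-0.50 > \rho > 0.50$" found in publication tables is read as
$|\rho| > 0.50$, the only reading under which the tiers nest. Tiers are
counted **within** the significant set (p < α, default 0.05), so
`n_strong_positive ≤ n_strong ≤ n_moderate ≤ n_significant` holds by
construction and is asserted as a property on arbitrary inputs.
Percentages are rounded to the nearest integer of the significant
count and rendered blank when nothing is significant.

p-values use the t approximation with $n-2$ degrees of freedom
(standard at these group sizes); exact enumeration of all $n!$ orderings
is available behind a flag for $n \le 9$, where the factorial is still
tractable, and matches `cor.test`'s exact p in tests. No
multiple-testing correction is applied by default, reproducing the raw
p < 0.05 filter of the motivating analysis; Benjamini-Hochberg can be
applied by the caller on the p matrix if desired. Zero-variance
features, whose rank correlation is undefined, are excluded from pair
enumeration (not assigned $\rho = 0$) and the exclusion is logged.

Networks keep pairs with p < α and $|\rho|$ above the strong threshold
(default 0.75), signed by correlation direction, with nodes labelled by
kingdom so bacteria–bacteria, fungus–fungus and cross-kingdom edges can
be counted. Layout and rendering are left to external tools via the
GraphML export.

# Pipeline orchestration

`runPipeline()` executes: simulate/load → SV expansion → filtering →
taxonomy fill-down → family profiles → NMDS + PERMANOVA (Bray-Curtis,
root samples) → iterative richness → JSD/Jaccard distances + Mantel →
rarefy (root samples) → genus agglomeration → cross-kingdom merge →
per-group co-occurrence, tiers and networks. Each stochastic stage
derives a child seed from the master seed by hashing the stage name, so
stages are independently re-runnable and the whole bundle is
byte-identical under a fixed configuration (asserted by serializing two
runs). A stage failure aborts with the stage named, leaving earlier
results intact. The Mantel stage requires at least one configured
concordance metric; with none it is skipped and logged as skipped.

# Problem sizes used for validation

The test-suite and acceptance-script simulations are sized so the full
validation runs comfortably on a single CPU while keeping every check
statistically meaningful: null calibration uses 1000 PERMANOVA datasets
(n = 24, 99 permutations) and four null co-occurrence simulations
pooling ~9700 pairs; planted-structure recovery uses 50 replicate
experiments at the design's own group sizes (16/11/11/16) with 40
genera and scaled-down depths (2000–4000 bacterial, 500–900 fungal
reads); geometry checks use 200 samples per group so centroid estimates
are tight. These sizes are the package's own validation choices; the
generator's scientific defaults (previous table) are unchanged by them.

# Known limitations

* Plain Spearman co-occurrence inherits compositional artefacts; the
  package reproduces that method faithfully rather than correcting it.
* The t-approximate Spearman p is slightly discrete-data-optimistic at
  very small n with heavy ties; exact enumeration is the fallback there.
* NMDS is a local optimizer; restarts mitigate but cannot guarantee the
  global stress minimum.
* The generator's soil samples share the baseline centroid and carry no
  planted structure; they exist to exercise the root/soil bookkeeping,
  not to model soil communities.
* BIOM import/export is not provided; TSV is the interchange format.
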