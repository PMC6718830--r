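---
title: "Methods: pathotype-stratified transcriptomics with tripathotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathotype-stratified transcriptomics with tripathotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripathotype)
```

# The analysis chain

`tripathotype` implements the computational backbone of a
pathotype-stratified synovial transcriptomics study: biopsies are first
classified histologically into lympho-myeloid (L), diffuse-myeloid (M)
and pauci-immune fibroid (F) pathotypes; cell-lineage gene modules are
derived from a reference expression atlas; bulk RNA-seq counts are
summarised per module by an SVD score and tested for three-group
differential expression; per-gene group effects are visualised in a
polar "three-way volcano" coordinate system; and module scores are
correlated against clinical, ultrasonographic and radiographic traits in
both the synovium and blood compartments. This vignette records the
statistical model behind each stage, the parameters that matter, the
numerical conventions, and what the synthetic validation does and does
not establish.

# Histology classification

Biopsies carry semiquantitative (0–4) immunohistochemistry scores for
CD3, CD20, CD68 in the lining (CD68L) and sublining (CD68SL), CD138, and
a CD20+ aggregate grade (0–3). The rules are evaluated in precedence
order L > M > F:

* **lymphoid**: grade 2–3 CD20+ aggregates with CD20 ≥ 2, *or* CD138 > 2;
* **myeloid**: CD68SL ≥ 2 and CD138 ≤ 2 and (CD20 ≤ 1 or CD3 ≥ 1),
  when the lymphoid rule did not fire;
* **fibroid**: CD68SL < 2 and CD3, CD20, CD138 all < 1;
* otherwise **ungraded**.

Two points in the printed criteria are genuinely ambiguous and were
resolved as package conventions. First, the "and/or" in the myeloid rule
is parsed as CD68SL ≥ 2 AND CD138 ≤ 2 AND (CD20 ≤ 1 OR CD3 ≥ 1): this is
the only reading that keeps M disjoint from L while still admitting
T-cell-containing myeloid biopsies. Second, high plasma-cell staining
(CD138 > 2) is treated as sufficient for the lymphoid call even without
graded aggregates; the alternative (requiring aggregates) would push such
samples into the myeloid branch, and the plasma-cell-rich phenotype
belongs biologically with the lymphoid pole. "Ungraded" is a legal
output for score combinations in rule gaps (for example CD68SL < 2 with
CD3 ≥ 1), not an error: real cohorts also contain unclassifiable
samples. The classifier is validated against an independent truth-table
oracle on the exhaustive enumeration of all 5^5 × 4 = 12,500 score
combinations.

The inflammation ordinal (fibroid = 0, myeloid = 1, lymphoid = 2) orders
pathotypes by infiltrate. The pathotype shift between baseline and a
6-month biopsy is baseline minus follow-up ordinal (positive = became
less inflammatory) and is correlated by Pearson against the change in
DAS28 (baseline minus follow-up, positive = improvement); samples
ungraded at either timepoint are dropped pairwise, and a zero-variance
shift vector yields a flagged degenerate result rather than an error.

# Marker-module derivation from a reference atlas

Promoter-level expression atlases measure several features (CAGE peaks)
per gene; only the feature with the highest mean expression across
tissues is kept (exact ties: lexicographically smallest feature id).
Each gene is then Z-scored across tissues, its tissues are ranked by
expression (rank 1 = highest; ties broken higher-value-first, then by
tissue column order), and a *specificity score* counts the tissues with
Z > 3. A gene joins the module of tissue *t* when

1. its rank in *t* is ≤ 3,
2. its Z score in *t* exceeds 5, and
3. its specificity score is < 10.

The inequalities are applied strictly as printed. The specificity count
includes the target tissue itself — it always contributes when Z > 5, so
the choice only shifts the effective cutoff by one. The Z denominator is
the sample SD (n−1); for panels of hundreds of tissues the difference
from the population SD is negligible, and the choice is exposed as a
parameter. Zero-variance (housekeeping-flat) genes are ineligible for
modules rather than an error. All three criteria are monotone in their
thresholds, which the test suite checks alongside equivalence with a
brute-force per-gene filter.

One structural fact matters when choosing atlas sizes: for a gene
elevated in a single tissue among *n*, the attainable cross-tissue Z is
bounded by roughly √n, because the outlier itself inflates the SD. Z > 5
recovery therefore *requires* a large tissue panel — with 20 tissues the
bound is ≈ 4.25 and no marker can pass. The synthetic atlas defaults to
200 tissues for this reason, matching the scale of real promoter-level
primary-tissue panels. Similarly, a "broad" gene elevated in a fraction
f of tissues has a limiting elevated-tissue Z of √((1−f)/f): broad genes
can only show Z > 3 in ≥ 10 tissues when those 10+ tissues are under a
tenth of the panel, which the defaults (12 of 200) respect.

# SVD module scoring

A module's score is the first right-singular vector of its row-centred
gene × sample submatrix — the standard eigengene summary. Two
conventions are deliberately fixed: rows are centred (so the score
reflects covariation, not absolute level), and the sign is flipped when
the score correlates negatively with the module-mean expression profile
(so "more module activity" is positive). The score has unit norm; the
share of variance carried by the first singular value is reported. Genes
in a module but absent from the matrix are dropped with a warning below
50% missing and are an error above. Scoring operates on
`log2(count/size_factor + 1)`-transformed counts: this preserves the
variance-stabilised log scale the eigengene assumes without reproducing
any shrinkage-based regularised-log transform, a documented divergence
that matters only near zero counts. Scores are computed per compartment
(synovium and blood separately), since cross-compartment pooling would
let compartment dominate the first singular vector.

Group comparisons of scores use one-way ANOVA with pooled-variance
pairwise t tests multiplied by the number of comparisons (capped at 1,
the classical Bonferroni post-test). Tertile summaries split samples at
the empirical 1/3 and 2/3 score quantiles, with the p value from the
two-sided slope test of a simple linear regression of the clinical value
on the *continuous* score — the tertiles are descriptive only.

# Three-way differential expression

Counts are normalised by median-of-ratios size factors (per-sample
median of count ratios to gene-wise geometric means over all-nonzero
genes, rescaled to geometric mean 1; library-size fallback with a
warning when no gene is all-nonzero). Each gene is modelled as negative
binomial with log link, log size-factor offsets, and a per-gene
dispersion α (variance µ + αµ²) estimated by method of moments from
within-group means and variances of normalised counts, floored at 1e-8
and shared between the full (covariates + pathotype) and reduced
(covariates only) models. No empirical-Bayes shrinkage is applied — at
cohort-scale group sizes the moment estimator is adequate, and the
absence of shrinkage keeps the estimator transparent.

The group effect is tested by the likelihood-ratio (deviance)
difference. The statistic divided by its numerator degrees of freedom is
referred by default to an F(df1, df2) distribution, where df2 is the
residual degrees of freedom behind the dispersion estimate (n −
n_groups). The asymptotic chi-square reference is available as an
option, but with a plug-in moment dispersion at 10 samples per group it
is visibly anticonservative (≈7% of null p values below 0.05, and a
Kolmogorov–Smirnov test against uniformity rejects); the F reference —
the same device quasi-likelihood F-tests use — restores calibration,
which the acceptance suite verifies over 20 null-cohort replicates.
Pairwise tests between group pairs reuse the full-cohort size factors
and dispersions with a two-level design (df1 = 1). Non-convergent genes
are flagged and their p values excluded from the BH family. BH
adjustment is step-up with monotone enforcement; missing p values stay
missing.

Colour classes for the volcano: a gene is gray unless its LRT q value is
below 0.05 (configurable). For significant genes the reference is the
minimum-mean group (exact ties broken in the fixed order fibroid <
myeloid < lymphoid), and "upregulated versus reference" requires both
pairwise q < 0.05 *and* a positive fold change — the q value alone is
direction-blind. One group up gives blue (L), red (M) or green (F); two
groups give purple (L+M), yellow (M+F) or cyan (L+F); a significant LRT
with no pairwise-up group is logged as an anomaly and stays gray. An
optional |log2 fold change| > 1 filter on significance is exposed but
off by default, since the q-threshold-only definition is the primary
one. Hierarchical clustering of significant genes uses Z-scaled rows,
Euclidean distance and Ward linkage, cut at k = 4 by default.

# Polar projection

Per-gene group means (mean Z of the log-normalised matrix by default,
or per-group log2 fold change versus the per-gene reference in `fold`
mode) map to the plane by x = √3/2·(M−F), y = L−(M+F)/2, θ = atan2(y, x)
(degrees in [0, 360); defined 0 at the origin, where atan2 is
implementation-defined), r = √(x²+y²), with −log10 LRT p as height
(p clipped at 1e-300, so the height caps at 300). The map is invariant
to adding a constant to all three means, sends cyclic L→M→F permutations
to −120° rotations, and places axis-pure genes exactly on their group's
axis (L 90°, M 330°, F 210°). Switching the radial scale to fold changes
preserves θ exactly only when fold changes are proportional to centred Z
differences; rather than asserting that claim, the payload records which
radial mode produced it and the θ agreement is checked empirically in
the tests for proportional inputs. Colour hex values are fixed constants
so serialized payloads are bit-reproducible.

# Association statistics

Module-trait relations use Spearman correlation on pairwise-complete
observations (missing clinical values are never imputed), with at least
6 complete pairs per test. The BH family is all modules for one trait
within one compartment — matching per-trait significance marking — and
is recorded in the output metadata; a global family is a one-line
change. Concordance between compartments requires dual significance
*with the same correlation sign*; sign-discordant dual-significant pairs
are "neither", since opposite-direction associations are not the same
finding. Module annotation against marker sets uses the upper-tail
hypergeometric probability P(X ≥ k) with BH across labels. Binary
clinical contrasts (ACPA status, erosion progression, EULAR response
groups) use a Welch t test on SVD scores with a standardised mean
difference as effect size — a module-level group test on summary scores,
not a reimplementation of variance-inflation set tests; it preserves the
tested contrast and is validated against planted shifts.

# The synthetic generator: what it emulates, and what not

The generator exists so every stage can be validated against planted
truth. Its defaults are the package's fixed study conditions:

* **Atlas**: 200 tissues × 2000 genes, 5 markers per tissue elevated by
  8 noise-SD in their home tissue, 50 broad genes elevated by 10 in 12
  tissues, unit noise on a uniform 5–10 baseline. Under the derivation
  criteria this yields ≳99% marker sensitivity and essentially complete
  broad-gene exclusion.
* **Cohort**: 30/20/15 samples (lymphoid/myeloid/fibroid, mirroring the
  roughly 2:1:1 skew of real pathotype frequencies at a test-friendly
  scale), 2000 genes with base means on a shuffled log-normal grid
  (median 50, log-SD 1.2), NB dispersion 0.1, library-size factors
  uniform on (0.7, 1.4), and 50 planted genes in each of the six
  up-regulation classes at log2 effect 2.
* **Histology** is drawn inside the score region of each sample's
  pathotype, plus 5% rule-gap ("ungraded") draws so every classifier
  branch is exercised.
* **Module activity** is i.i.d. standard normal per sample on the log2
  scale, multiplied into the module genes' means.
* **Clinical traits** have plausible marginal scales (e.g. DAS28-ESR ~
  N(5.8, 1.3)); a planted (module, trait, ρ) correlation is built by
  generating a Gaussian latent with the Pearson equivalent
  2·sin(πρ/6) of the target Spearman ρ against the module activity and
  rank-remapping it onto the trait's own marginal — Spearman is exactly
  preserved while the trait keeps a realistic scale.
* **Follow-up** pathotypes take one ordinal step down/none/up with
  probabilities 0.3/0.4/0.3 (truncated at the scale ends), and
  ΔDAS28 = response_strength × shift + N(0, 1).

One user-facing seed fans out deterministically to per-stage substreams,
so regenerating any single component is reproducible without coupling
draw orders.

What the generator does *not* emulate: read-level data, transcript-level
quantification, gene-gene correlation beyond module structure,
batch effects beyond an optional binary depth shift, realistic joint
distributions of clinical traits, or the effect-size spectrum of any
real cohort (which is unknown). Passing the synthetic acceptance suite
therefore demonstrates that the chain recovers what it is pointed at
under its stated model — correct rules, calibrated tests, faithful
geometry — not that any biological conclusion transfers to real data.

# Problem sizes and runtime choices

The validation suite runs at deliberately desk-scale sizes: null
calibration uses 20 replicate cohorts of 2000 genes at 10 samples per
group; colour-class recovery uses the default 65-sample cohort; planted
association recovery uses 50 replicate 65-sample cohorts; the classifier
oracle enumerates all 12,500 score combinations. These sizes make the
whole suite run in a few minutes on one CPU while keeping every
stochastic criterion's Monte-Carlo error well inside its margin.

# Known limitations

* The NB GLM uses a plain moment dispersion without shrinkage; for very
  small cohorts (< 5 per group) the F reference helps but power is below
  what moderated estimators achieve. Externally computed DE tables can
  be fed into the projection instead.
* The log2(x+1) transform is not a regularised-log; module scores of
  very low-count genes are noisier than under shrinkage transforms.
* The polar projection is a visual summary: genes with identical (x, y)
  can differ in absolute expression, which only the radial mode choice
  partially distinguishes.
* `collapse_to_dominant_feature` selects one feature per gene globally,
  not per tissue; genes with tissue-switching dominant promoters keep a
  single representative.
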