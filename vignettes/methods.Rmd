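---
title: "Trans-cohort metabolomics biomarker discovery: models and design"
author: "cohortMet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-cohort metabolomics biomarker discovery: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortMet)
```

# The problem

Untargeted plasma metabolomics in case-control designs suffers from strong
cohort effects: population, diet, lifestyle and pre-analytical differences
shift metabolite levels by more than most disease effects. When a study is
replicated in two independent cohorts — here the motivating setting is
people living with HIV on long-term combination antiretroviral therapy
(cART) versus matched HIV-negative controls (HC), profiled in two
countries — pooling the cohorts is statistically unsound. `cohortMet`
instead runs every stage per cohort and combines evidence only at the level
of selected feature *sets*: a metabolite is nominated as a biomarker when
three methodologically independent selection engines all pick it, in every
cohort, with a consistent direction of change.

This vignette describes the statistical machinery, the tunable parameters
and their defaults, what the synthetic-cohort generator does and does not
emulate, and the design decisions that were genuinely open.

# Data model and preprocessing

`MetaboliteExperiment` extends `SummarizedExperiment`: metabolites are rows
with Metabolon-style annotations (super-pathway from a controlled
nine-term vocabulary, sub-pathway, optional HMDB id, drug flag, where
`is_drug` implies the Xenobiotics super-pathway), samples are columns with
cohort, group (`HC`, `cART`, `naive`) and covariates. On disk the
conventional layout is samples x metabolites; `readAbundance()` transposes
and validates (unique ids, complete annotations, numeric cells, each
offender named).

`preprocess()` applies, in order:

1. **Imputation** of missing values per metabolite by the observed minimum
   (default). Untargeted missingness is predominantly left-censoring at the
   limit of detection, for which the per-metabolite minimum is the common
   platform convention; half-minimum and no imputation are available. The
   per-metabolite imputation count is recorded in `rowData`.
2. **log2 transform** (natural log configurable). Fold changes are reported
   as log2FC, so base 2 keeps the scales aligned.
3. **Per-metabolite z-scoring** (optional, default on). Scaling is always
   within one table — one cohort — and never pooled across cohorts.

The imputed, unlogged matrix is retained as a second assay so fold changes
can be computed on the measurement scale after scaling has destroyed group
means. The `isLogged`/`isScaled` flags make re-application an error rather
than a silent double transform.

# Differential abundance

Per metabolite, the two-sided Mann-Whitney U test compares cART against HC.
The exact null distribution is used when `n1 * n2 <= 400` and the data are
tie-free, otherwise the normal approximation with tie and continuity
correction; the switch is exposed because at 24 + 24 (the motivating
design, `n1 * n2 = 576`) the approximation is used, and both paths agree to
|Δp| ≤ 0.02 by property test. Benjamini-Hochberg step-up adjustment runs
across metabolites. Two operating points are conventional and both are
plain parameters: q < 0.1 for the biomarker set, unadjusted p < 0.05 for
enrichment input; neither is hard-coded.

Effect sizes use **Glass delta**, `D = (mean_cART − mean_HC) / SD_HC`, the
mean difference standardized by the *control* group's sample SD — the right
standardizer when treatment changes the spread as well as the location.
`|D|` is binned at 0.2/0.5/0.8 into negligible/small/medium/large. `D` is
computed on the log scale (it is invariant under the common affine map that
z-scoring applies), while log2FC is computed from group means on the
unlogged, imputed scale.

Confounder adjustment (`adjustedGroupTest()`) is ordinary least squares of
the metabolite on the group indicator plus covariates (e.g. exercise, the
one clinical variable that typically differs), with a t-test on the group
coefficient. `tableOne()` reproduces clinical-characteristics statistics:
Yates-corrected chi-square for 2x2 categorical comparisons (the correction
floored at zero so it can never invert a deviation's sign) and
pooled-variance Student t-tests for continuous variables;
`summaryTTest()` reconstructs the SD from a printed mean and 95% CI as
`(CI half-width) * sqrt(n) / t_{0.975, n-1}` so published tables can be
re-checked without raw data.

# Selection engines

**PLS-DA with VIP.** Partial least squares discriminant analysis is fit by
NIPALS with deflation on the centered, z-scored matrix and a centered ±1
response; for a single response the first weight vector is proportional to
`t(X) y`. Variable importance in projection is

$$\mathrm{VIP}_j = \sqrt{p \,\frac{\sum_a \mathrm{SSY}_a\,(w_{aj}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}},$$

with `SSY_a` the response sum of squares explained by component `a`; mean
squared VIP is 1 by construction, which the tests assert to 1e-10. The
default is 2 components (score plots are two-dimensional and additional
components add little for a binary response at n ≈ 50) and a selection
cutoff of VIP > 1 — the conventional "above average contribution" rule,
chosen here as a documented default because no canonical cutoff exists.
The implementation is cross-checked in the test suite against an
independent PLS-DA implementation (mixOmics).

**Boruta-style random forest.** All-relevant selection: each iteration
appends a permuted shadow copy of every undecided feature (at least five
shadows, so the shadow maximum remains a meaningful bar as candidates
dwindle), fits a 500-tree random forest with balanced class weights, and
scores a "hit" for features whose impurity importance exceeds the best
shadow. A two-sided binomial test of the hit count against
Binomial(iterations, 1/2) at `alpha = 0.01` confirms or rejects; survivors
after 100 iterations are tentative and excluded from the selection set by
default (only "confirmed" features enter the consensus). Forests are fit
with `ranger`; the iterative shadow logic is the package's own.
Cross-validated accuracy, confusion matrices and AUROC
(`rfCvAccuracy()`, stratified 10-fold, pooled out-of-fold predictions)
quantify class separability alongside selection.

**Pathway-term importance.** A metabolite-level learner: a balanced random
forest predicts a per-metabolite binary label (by default "significant at
p < 0.05", since the alternative reading — direction of change — is also
meaningful, a direction-label mode is available to the caller) from one-hot
encoded super- and sub-pathway terms, ranked by permutation feature
importance (mean accuracy drop over 50 shuffles per term). This gives a
non-proprietary answer to "which pathway vocabulary terms carry the
case-control signal".

# Consensus nomination

For each method, the per-cohort selections are intersected across cohorts;
the consensus panel is the intersection of those per-method sets. This is
deliberately set intersection, not meta-analytic p-value pooling: the claim
being made is *replication*, not combined evidence. The operation is
order-invariant and anti-monotone in the method list (more methods can only
shrink the panel). Drug metabolites — annotation `is_drug`, sub-pathway
containing "Drug", or an explicit id list (antiretrovirals trivially
separate cases from controls) — are excluded, and every panel member must
have the same fold-change sign in all cohorts (`directionConcordance()`).

# Co-abundance network

All metabolite pairs are tested for Spearman correlation across a cohort's
samples (mid-rank ties, two-sided p from the t approximation, adequate at
n ≥ 10); BH across all pairs; edges kept when rho > 0 and q < 0.05. The
network is built on all samples of the cohort, HC and cART pooled —
co-abundance structure is a property of the metabolome, not of one group —
and this is configurable. Leiden community detection (modularity objective,
resolution 1, `igraph`) partitions the graph; community ids are renumbered
by decreasing size; the "central" community is the one with the highest
mean *full-graph* degree (ties to the larger community, then the smaller
id). `firstNeighbors()` expands a biomarker panel by its graph
neighborhood, the feature set used for the clustering validation below.

# Consensus clustering

Monti-style resampling: `reps = 1000` times, draw `floor(pItem * n)`
samples (`pItem = 0.8`) without replacement, cluster them by average-linkage
agglomerative clustering on `1 − Spearman` distance between sample
profiles, cut at `k = 2` (the case/control question; the linkage and k are
configurable), and tally pair co-clustering among co-drawn repetitions. The
consensus matrix entry `M[i, j]` is that proportion; pairs never co-drawn
are reported `NA` rather than silently zeroed, and final labels (from
reclustering `1 − M`) require a complete matrix. Separation against the
true HC/cART labels is scored by the adjusted Rand index. At `pItem = 1`
the matrix is provably binary, which the tests assert.

# Enrichment

Term over-representation for a selected set against the detected-metabolite
universe: one-sided hypergeometric upper-tail p per super- or sub-pathway
term, BH across terms. Proprietary pathway-activation scoring is
deliberately out of scope; the hypergeometric tail is the reproducible core
of the question "does amino-acid or lipid metabolism dominate this
selection".

# Synthetic cohorts and what passing tests mean

`generateCohorts()` draws, per cohort, latent log2 values with a
common-factor block covariance
(`z = sqrt(rho) f_block + sqrt(1 − rho) eps`, positive-definite for any
`rhoWithin` in [0, 1)), adds the planted group effect (in within-group SD
units, so planted effects sit directly on the Glass-delta scale of the
logged data) to cART samples of biomarker metabolites, adds a
per-(cohort, metabolite) Normal(0, `cohortShiftSd`) batch shift,
exponentiates, and left-censors the lowest `missingRate` fraction of each
metabolite. Identical biomarker identities and effect signs across cohorts
are enforced by construction. Defaults emulate the motivating study
design: 24 + 24 samples per cohort, two cohorts, 841 metabolites at a
46/22/17 percent lipid/amino-acid/xenobiotics mix, six correlation blocks
sized like observed co-abundance communities
(165/145/143/123/110/91), `rhoWithin = 0.5`, `cohortShiftSd = 1` (a "clear
cohort effect"), `missingRate = 0.1`.

Planted biomarker effects default to |D| between 2.5 and 3, with the four
down-regulated members placed in the fourth (neurosteroid-like) block and
the up-regulated one in the sixth (glutamate-like) block. The magnitude was
fixed a priori by a power argument: replicated panel biomarkers in this
kind of study are significant at FDR < 0.001 in every cohort, and for all
five panel members to survive three selection engines in two cohorts of
24 + 24 at BH-adjusted thresholds, per-test power must be ≈ 0.99, which
for a rank test at an effective α of ~3e-3 requires |D| ≳ 2.5. With these
conditions the end-to-end test demands panel recovery in ≥ 90% of 20
seeded runs and empty panels on null cohorts in ≥ 95%.

The generator emulates block correlation, batch shifts, censoring and
effect direction — it does not emulate drug pharmacokinetics, instrument
noise models, heavy-tailed or skewed abundance distributions, or
annotation errors. Passing tests therefore demonstrate that the pipeline's
logic is correct and well calibrated under its own assumptions, not that
any particular real-data finding is true.

Test and acceptance runs use scaled-down problem sizes chosen to keep the
suite fast while leaving the study conditions intact: 150 metabolites in
six proportionally-sized blocks for end-to-end runs (sample sizes stay at
24 + 24), 1000 metabolites for the type-I calibration, 100 metabolites in
two blocks of 50 for network recovery, and 200-rep consensus clustering in
worked examples.

# Numerical choices and degenerate inputs

- Mann-Whitney: all values tied across both groups gives p = 1 with a
  warning rather than an error; the exact/approximate switch is at
  `n1 * n2 <= 400` with no ties.
- Zero-variance metabolites are scaled to all-zeros with a warning
  (preprocessing) and excluded from correlation testing with a warning
  (network stage); a zero control-group SD makes Glass delta an error.
- The Yates correction is floored at zero; expected cells below 1 attach a
  warning.
- Boruta decisions use `pTwo <= alpha`, so `alpha = 1` decides everything
  at the first iteration (the documented degenerate limit).
- Community renumbering breaks ties by smallest member index; central
  community ties go to the larger, then smaller-id community.
- Rank-deficient designs in the adjusted regression error naming the
  collinear columns; missing (cohort, method) cells in the consensus error
  rather than being treated as empty.
- All stochastic stages (fold assignment, forests, Leiden, subsampling)
  take explicit integer seeds; the pipeline derives per-stage seeds from
  one base seed and records them in the run summary.

# Known limitations

- The three selection engines are correlated (they see the same data), so
  the consensus panel is a replication filter, not three independent
  confirmations.
- Spearman edge p-values use the t approximation; below ~10 samples an
  exact permutation test would be preferable.
- Glass delta after minimum-imputation of censored values is biased toward
  zero (censoring shrinks the control SD's tail); the generator's
  censoring lets users measure that bias for their own settings.
- The pathway-term learner's label definition ("significant" vs "direction
  of change") is a genuine ambiguity; both modes are exposed and the
  default is the significance label.
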