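---
title: "Methods: cuproptosis subtyping and the CUS score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuproptosis subtyping and the CUS score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
models each stage assumes, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the places where the design was genuinely open and a
choice had to be made.

## The analysis in one paragraph

A cohort of bulk tumor transcriptomes is clustered twice: first on a small
copper-death-promoting gene *program* (seven genes by default) to define
molecular subtypes, then on the differentially expressed, prognostic genes
*between* those subtypes (the subtype-related genes, CSRGs) to define gene
clusters. The CSRGs are split by the sign of their association with the
reference gene cluster into two signatures, sigC1 and sigC2; each signature
is reduced to its first principal component, and the per-sample
cuproptosis score is the difference

$$\mathrm{CUS}_i = P^{(i)}_{\mathrm{sigC1}} - P^{(i)}_{\mathrm{sigC2}},$$

dichotomized at a survival-optimal cutoff. Downstream stages ask whether
the score tracks survival, immune infiltration, and predicted drug
sensitivity.

## Preprocessing and batch correction

All clustering, differential expression and PCA operate on log2(TPM+1).
The TPM conversion (`fpkm_to_tpm`) rescales each sample to a fixed total of
10^6, so between-sample comparability rests on the usual
composition-sum assumption. No variance filtering is applied by default;
gene selection is explicit (program genes, then screened CSRGs).

`combat_adjust` is a parametric empirical-Bayes location-and-scale
adjustment: per gene the data are standardized against the
batch-size-weighted grand mean and pooled residual variance; per-batch
location and scale effects are shrunk toward batch-level priors (normal on
location, inverse-gamma on squared scale) with method-of-moments
hyperparameters and fixed-point updates (tolerance 1e-4, at most 100
iterations — the tolerance is on the relative change of the shrunken
effects and is far below the sampling noise of the estimates themselves).
Two properties are worth knowing:

* the adjustment re-anchors each gene at its pre-correction
  batch-weighted pooled mean, so correction never moves the cohort-level
  location of a gene;
* empirical-Bayes shrinkage makes the correction *approximately* but not
  exactly idempotent: a second pass re-shrinks the re-estimated scale
  factors and moves values by a fraction of a percent of the first-pass
  change. Exact idempotence is not a property of this algorithm.

Single-batch input is a warning and a no-op rather than an error, so
one-cohort analyses run through the same pipeline. `batch_severity`
reports the mean per-gene one-way F statistic across batches and the
silhouette of the batch labels in the top-two principal components; values
near zero mean the batches are exchangeable.

## Consensus clustering

`consensus_cluster` follows the resampling recipe: 50 repetitions, each
drawing 80% of samples without replacement, z-scoring genes on the
subsample, and running PAM (BUILD + SWAP k-medoids, Euclidean distance)
for each k. The consensus entry for a sample pair is its co-clustering
count divided by its co-sampling count; pairs never co-sampled get 0 and a
warning if they exceed 1% of pairs (at 50 reps × 80% the co-sampling
probability is 0.64 per rep, so this is vanishingly rare for n ≥ 30). The
final assignment is an average-linkage agglomerative cut of one minus the
consensus matrix — PAM is partitional, so the agglomerative step is what
turns per-resample partitions into a single stable call.

k is selected by minimum PAC (the fraction of consensus entries strictly
inside (0.1, 0.9)), ties to the smallest k; a `"fixed"` policy reproduces
an externally chosen k. Genes are z-scored per subsample so that
high-expression genes do not dominate the Euclidean metric; both the
scaling and the k rule are configuration, because neither is forced by the
method.

Two caveats found while validating against brute force: PAM's BUILD+SWAP
is a single-swap local search and is not guaranteed globally optimal on
unstructured point sets (it is exact on well-separated ones, which is what
the oracle tests use), and the consensus matrix is only
permutation-equivariant when `subsample = 1` (resampling is positional).

## ssGSEA and the immune landscape

`ssgsea_scores` implements the rank-weighted running sum: per sample,
genes are ranked by expression descending (ties broken by gene id so
output is platform-independent), in-set steps are weighted by
rank^α with α = 0.25, out-of-set steps uniformly, and the
enrichment score is the sum of the running difference between the two
cumulative fractions. The statistic is rank-based, hence invariant to any
strictly monotone transform of a sample's profile. Normalization divides
the whole score matrix by its range, preserving all orderings. The
stromal/immune composite is the sum of the two unnormalized set scores.
Marker sets are inputs (GMT); the package bundles none, and the synthetic
generator ships its own marker sets so tests need no downloads.

## Differential expression and screening

`moderated_t_table` is a two-group empirical-Bayes t: pooled per-gene
residual variances, a scaled-inverse-chi-square prior fitted by method of
moments on the log variances (trigamma inversion), posterior variances
$(d_0 s_0^2 + d s^2)/(d_0 + d)$, and `d0 + d` degrees of freedom.
`prior_df = 0` recovers the ordinary pooled t exactly — useful both as a
limit check and when moderation is not wanted. The DEG rule is strict:
|log2FC| > 1 AND p < 0.05 on the *raw* p-value (a flag switches to the BH
column; the choice is surfaced because screening conventions differ).
The log-fold-change direction is second-listed group minus first.

Cox screening (`screen_prognostic`) fits one univariate proportional-
hazards model per gene with Efron tie handling (day-resolution survival
data is heavily tied; Breslow is available as a switch). Monotone partial
likelihood is capped at |β| = 15 and flagged rather than failed so
genome-wide screens complete. Rule `"csrg"` keeps p < 0.05; rule
`"potential_cpg"` keeps protective genes with p < 0.001 and 1 − HR > 0.4.

The over-representation test is the upper hypergeometric tail against the
universe of genes *present in the expression matrix* — the only universe
the analysis can know — with BH adjustment across sets.

## The CUS construction

`split_signature` assigns each screened gene by the sign of its
point-biserial correlation with the reference-cluster indicator. The
reference cluster is chosen as the *worse-prognosis* gene cluster (a Cox
fit on the cluster indicator decides which that is): sigC1 then holds the
genes elevated under cuproptosis suppression, and since `pc1_scores` fixes
each component's sign to correlate non-negatively with mean signature
expression, high CUS corresponds to the suppressed program and poor
prognosis. PC signs are mathematically arbitrary; this pair of rules is
what makes the score's direction reproducible, and reports still *assert*
rather than assume the survival direction.

The Σ in the score formula is read as one retained principal component per
signature (PC1), the dominant interpretation in the score-construction
family this design descends from; `pc1_scores` reports variance explained
so a user can judge when one component is too little.

`boruta_select` is shadow-feature all-relevant selection: each iteration
appends a freshly shuffled copy of every feature still in play, computes
random-forest permutation importances (single-threaded, seeded `ranger`,
100 trees), scores a hit for features beating the maximum shadow
importance, and applies a two-sided binomial test (hit probability 1/2,
level α = 0.01, Bonferroni-adjusted across features) after every
iteration. Rejected features leave the pool; confirmed ones remain so the
importance context stays stable. Two deliberate choices:

* the target is the *gene-cluster* assignment, not survival — the score is
  meant to compress the cluster signature, and the survival contrast is
  evaluated afterwards, on held-out information;
* features still tentative at `max_iter` are *kept* by default
  (`keep_tentative = TRUE`) so small signatures survive an undecided run.

Permutation importance matters here: low-variance impurity importance lets
a fixed, accidentally target-correlated noise feature beat the re-drawn
shadow maximum persistently and be confirmed. Even with permutation
importance, the far tail of chance correlations is statistically
indistinguishable from weak signal *within one dataset*, so a small
residue of noise confirmations (about 1–2%) is expected behavior of the
algorithm, not a defect.

The survival cutoff is the maximally selected log-rank statistic over all
score midpoints leaving both groups at least ⌈0.1·n⌉ samples, ties to the
lower cutoff. Because the statistic is maximized over many candidate
splits, its nominal p-value is strongly anticonservative (the null
exceedance of the χ²₁ 95% quantile is far above 5%); the package therefore
labels it descriptive, and group contrasts should be judged by the
downstream log-rank/Cox fits. A related subtlety: with two cleanly
separated hazard regimes the argmax split can sit one or two boundary
samples off the separating gap — group-size imbalance perturbs the
variance term — so exact gap recovery is not guaranteed even in easy
cases.

## Drug-sensitivity imputation

`train_ridge` fits, per drug, the closed-form ridge solution on
gene-standardized predictors, with the penalty chosen by k-fold
cross-validated mean squared error over a grid (default 10^−2…10^4, ties
to the larger penalty). The standardization (reference means and SDs) is
stored and re-applied at prediction, which makes predictions invariant to
gene-wise affine rescaling of raw inputs and makes a cohort sample equal
to a training sample reproduce its fitted value exactly. `homogenize`
intersects gene universes and runs the batch correction with
reference-vs-cohort as the two batches before any transfer. Grid CV was
chosen over an analytic penalty rule for transparency and testability.

## What the synthetic generator emulates — and what it does not

`simulate_cohort` draws, per gene, a uniform(4, 10) log2 baseline; assigns
each sample one of two latent subtypes; shifts the program genes *down* by
`subtype_effect` (2.0 log2 units) in subtype 2, the positively associated
signature genes up in subtype 1, the negatively associated ones and the
immune markers up in subtype 2; adds per-gene, per-batch additive shifts
drawn N(0, `batch_shift`² = 0.5²) (a scale-effect toggle exists to stress
the variance adjustment); and adds N(0, 1) residual noise. The recorded
latent activity is the centered, sign-flipped noiseless program mean — the
*suppression* axis — so that subtype 2 has high activity, high hazard and
poor prognosis, and a Cox fit on the recorded activity recovers
+`hazard_coef`. Survival is exponential proportional-hazards
(baseline median three years, time unit days) with independent exponential
censoring whose rate is set by bisection on the closed-form expected
censoring fraction (target 0.4).

The defaults (two batches of 200 samples, 1000 genes, 7 program genes, 31
signature genes split 16/15, effect 2.0, noise 1.0, hazard coefficient
0.8) are the study conditions every recovery test runs under; they were
chosen once as a desk-scale analogue of a two-cohort renal-carcinoma
merge, and the test suite states its problem sizes from them.

`simulate_reference_panel` gives each of 120 cell-line-like samples a
latent program-propensity factor that loads on the program and signature
genes with the cohort's sign pattern at half the between-subtype
amplitude, and builds each drug's true log-IC50 as a linear combination of
ten predictor genes (coefficient signs aligned with the axis) plus N(0, 1)
noise. The factor structure is essential, not decorative: with fully
independent genes, a ridge model cannot find ten sparse predictors among a
thousand at n = 120 (held-out correlation ≈ 0), whereas real panels work
precisely because response tracks correlated expression programs — the
elesclomol/cuproptosis axis being the motivating example.

Not emulated: negative-binomial count noise, library-size artifacts,
gene–gene correlation outside the program/signature/immune blocks,
copy-number or methylation structure, and non-proportional hazards.
Passing recovery tests therefore demonstrates that the pipeline's logic is
correct under its own model assumptions — not that those assumptions hold
for any particular real cohort.

## Numerical and degenerate-input conventions

* Expression matrices must be finite; duplicate gene or sample ids are
  errors naming the offender.
* Zero-variance genes: passed through unchanged (batch correction),
  an error (PC scores, signature split — a constant gene cannot carry a
  sign), or an NA row with a `degenerate` flag (correlation tables).
* Ranking ties in ssGSEA break lexicographically by gene id; consensus
  PAC ties and cutpoint ties break toward the smaller value.
* Scores exactly at the CUS cutoff go to the "low" group.
* The empirical-Bayes prior df can be 0 (no moderation) or Inf (complete
  pooling); both limits are handled explicitly.
* Exact rank-sum enumeration is used up to a combined n of 12 without
  ties; beyond that, the normal approximation with tie and continuity
  correction.

## Reproducibility

Every stochastic routine takes a seed; `run_pipeline` fans a single
global seed out to fixed per-stage offsets, so toggling one stage does not
shift another stage's random stream, and two runs from one config are
byte-identical (checksums in the manifest). Test-suite simulations use the
default study conditions with 5–10 seed replicates for recovery metrics
and 2000–5000 replicates for calibration checks; these sizes keep each
property measurable at the asserted tolerances.

## Known limitations

* The pipeline is two-group at heart: more than two subtypes are clustered
  and reported, but the signature split and CUS are defined for the
  two-cluster case.
* The cutpoint p-value is selection-inflated by construction and is
  reported as descriptive; no selection-adjusted inference is attempted.
* Gene identifiers are matched as exact strings; no alias resolution.
* The ridge transfer assumes the batch correction puts reference and
  cohort on one scale; tissue-specific response structure beyond the
  shared expression axes is out of reach of a linear model.
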