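# cuproscore

Cuproptosis subtyping and scoring for bulk tumor transcriptomes.

Cuproptosis is a copper-dependent form of programmed cell death tied to
lipoylated TCA-cycle enzymes and mitochondrial respiration. In clear cell
renal carcinoma — a tumor with a strongly glycolytic (Warburg) metabolism —
suppression of the cuproptosis program carries prognostic and therapeutic
information: tumors with low expression of the copper-death-promoting genes
(*FDX1*, *LIAS*, *LIPT1*, *DLD*, *DLAT*, *PDHA1*, *PDHB*) behave
differently under immunotherapy and targeted agents than tumors that retain
the program. `cuproscore` implements the full analysis that turns this
observation into a per-sample score, for methodologists and translational
analysts who want the pipeline as tested, reusable, seedable code rather
than a one-off script collection.

## What the pipeline computes

Starting from one or more gene-by-sample expression cohorts (FPKM, TPM or
log2 scale) with survival annotation:

1. **Cohort assembly** — FPKM→TPM conversion (`TPM_g = FPKM_g / Σ_g FPKM_g
   × 10⁶`), log2(TPM+1), gene-universe intersection across cohorts,
   exclusion of samples without complete survival data, and parametric
   empirical-Bayes batch correction (location and scale, method-of-moments
   hyperpriors) with PCA/F-statistic severity diagnostics.
2. **Molecular subtyping** — Monti-style consensus clustering over 50
   resamples of 80% of samples, PAM (k-medoids) with Euclidean distance as
   the inner clusterer, average-linkage cut of the consensus
   dissimilarity; k chosen by minimum PAC (proportion of consensus entries
   in (0.1, 0.9)) or fixed by policy.
3. **Immune landscape** — single-sample GSEA (rank weights `r^α`, α = 0.25)
   per immune cell marker set, plus StromalScore / ImmuneScore whose sum is
   the combined microenvironment score.
4. **Signature construction** — moderated-t differential expression between
   subtypes filtered at |log2FC| > 1 and p < 0.05; univariate Cox screening
   (Efron ties) keeps prognostic genes (p < 0.05); a second consensus
   clustering on those genes defines gene clusters.
5. **The cuproptosis score (CUS)** — screened genes are split by the sign
   of their association with the reference gene cluster into sigC1 and
   sigC2; Boruta-style shadow-feature selection (permutation-importance
   random forests, binomial decisions) prunes the sets; each set is
   summarized by its first principal component (orientation fixed against
   mean signature expression), and

   CUS = P<sub>sigC1</sub> − P<sub>sigC2</sub>

   per sample. The cohort is dichotomized at the survival-optimal cutoff
   (maximally selected log-rank statistic, minimum group fraction 0.1) into
   high- and low-CUS groups.
6. **Downstream comparisons** — Kaplan–Meier / log-rank survival contrasts,
   CUS–immune correlations, clinical subgroup tests (Wilcoxon,
   Kruskal–Wallis, chi-square), and ridge-regression drug-sensitivity
   imputation from a reference cell-line-like panel (closed-form ridge,
   k-fold cross-validated penalty) with rank-sum comparisons of predicted
   log-IC50 between score groups.

A fully seeded synthetic-cohort generator (`simulate_cohort`,
`simulate_reference_panel`, `write_fixture_bundle`) emulates the assumed
data structure — two batches, a 7-gene program defining two latent
subtypes, 31 signature genes with known association signs,
subtype-dependent immune infiltration, proportional-hazards survival tied
to the latent program, and a drug panel with gene-linear log-IC50 — so
every stage is testable against known ground truth without downloads.

## Worked example

```r
library(cuproscore)

cfg <- sim_config(seed = 7)               # 2 x 200 samples, 1000 genes
sim <- simulate_cohort(cfg)
corrected <- combat_adjust(sim$expr, sim$clinical$batch)$corrected

cons <- consensus_cluster(corrected, genes = sim$truth$program_genes,
                          kmax = 4, reps = 50, subsample = 0.8, seed = 7)
print(cons)
#> Consensus clustering: 50 reps, subsample 0.8
#>   PAC by k: k=2: 0.022, k=3: 0.226, k=4: 0.349
#>   chosen k (min-PAC): 2
subtype <- consensus_assignment(cons, 2)

degs  <- filter_degs(moderated_t_table(corrected, factor(subtype)))
csrgs <- screen_prognostic(corrected, sim$clinical, "csrg", genes = degs)$kept
length(degs); length(csrgs)               # 56 DEGs, all 56 prognostic

# reference = the worse-prognosis cluster, so high CUS = poor prognosis
cox_cl <- cox_fit_univariate(sim$clinical$time, sim$clinical$event,
                             as.numeric(subtype == 1))
ref   <- if (cox_cl$beta > 0) 1 else 2
split <- split_signature(corrected, csrgs, subtype, reference_cluster = ref)
cus   <- compute_cus(corrected, split)

cp  <- optimal_cutpoint(cus$CUS, sim$clinical$time, sim$clinical$event)
print(cp)
#> Optimal survival cutpoint: 5.441267
#>   standardized log-rank statistic: 11.27 (descriptive; maximally selected)
#>   candidates scanned: 321  minprop: 0.1
grp <- assign_cus_groups(cus$CUS, cp$cutoff)
```

The two PAC values say the samples cluster stably only at k = 2; the 56
DEGs between those clusters all pass the Cox screen, and the resulting CUS
splits survival sharply: log-rank χ² = 127.1 (p = 1.8e-29), high-vs-low
hazard ratio 4.30 [3.27, 5.64]. Because the generator records the latent
program-suppression activity, the score can be validated directly:
`cor(cus$CUS, sim$truth$activity)` = 0.990. The cutpoint's log-rank
statistic is reported as descriptive — it is maximized over candidate
splits and inherits the usual selection inflation.

`run_pipeline(default_pipeline_config(seed = 1))` executes all stages in
order and writes every intermediate table plus a checksummed
`manifest.json`; two runs from the same config are byte-identical.

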