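# gragp

Grey relational gene selection and Gaussian process classification for
RNA-seq read counts.

## The problem

Bulk RNA-seq experiments deliver a genes × samples table of non-negative
integer read counts. Classifying samples into two groups (tumour vs
normal, population A vs B) from such counts faces three obstacles: counts
are overdispersed (variance exceeds the mean), heavily right-skewed with
extreme values, and the useful genes are a tiny fraction of tens of
thousands measured with only dozens of samples. `gragp` implements a
complete pipeline for this setting:

1. **Transformation.** Counts become log2 counts per million with
   observation-level precision weights (the voom approach): each gene is
   regressed on the sample design, a lowess trend is fitted through the
   per-gene (mean log2 count, √standard deviation) scatter, and each
   observation gets weight `trend(fitted log count)^-4`. An optional batch
   covariate enters the design. After this, normal-based statistics apply.
2. **Five filter scores per gene.** With class means μ₁, μ₂, standard
   deviations σ₁, σ₂ and sizes n₁, n₂ on the transformed scale:
   - absolute two-sample t statistic `|μ₁ − μ₂| / √(σ₁²/n₁ + σ₂²/n₂)`;
   - symmetric Kullback–Leibler entropy
     `½[σ₁²/σ₂² + σ₂²/σ₁² − 2 + (1/σ₁² + 1/σ₂²)(μ₁ − μ₂)²]`;
   - Bhattacharyya distance
     `¼ln[¼(σ₁²/σ₂² + σ₂²/σ₁² + 2)] + ¼(μ₁ − μ₂)²/(σ₁² + σ₂²)`;
   - standardized Wilcoxon rank sum `|W − E[W]| / sd[W]` of the smaller
     group, with midranks and tie-corrected variance;
   - empirical AUC folded as `max(AUC, 1 − AUC)`.
3. **Grey relational aggregation.** The genes × 5 score table is treated as
   a multi-criteria decision problem: each criterion column is min–max
   normalized to [0, 1], compared against the ideal all-ones reference
   through the grey relational coefficient
   `δᵢⱼ = (Δmin + αΔmax) / (Δᵢⱼ + αΔmax)` with Δᵢⱼ = |1 − xᵢⱼ| and α = 0.5,
   and averaged with criterion weights into one grade per gene. The top-k
   genes by grade form the feature set.
4. **Classification.** A Bayesian Gaussian process binary classifier
   (squared-exponential ARD kernel, logistic likelihood, Laplace
   approximate inference, hyperparameters optimized on the approximate
   marginal likelihood), plus a sparse Poisson linear discriminant analysis
   (sPLDA) comparator that works on the raw counts with soft-thresholded
   class profiles and total-count / median-ratio / 75th-percentile size
   factors.
5. **Evaluation.** Repeated stratified 5-fold cross-validation with
   selection nested inside training folds, reporting accuracy, F-measure,
   AUC and mutual information (in % of 1 bit), and an exact/tie-corrected
   Mann–Whitney U-test for comparing two result sets.

A negative-binomial simulator with planted differential expression,
library-size variation and optional batch effects provides ground truth
for calibration and recovery studies.

## Worked example

```r
library(gragp)

sim <- simulate_counts(n_genes = 1000, n_per_class = c(40, 40),
                       de_fraction = 0.01, log2_fold_change = 2,
                       dispersion = 0.2, seed = 42)
v      <- voom_transform(sim$counts, sim$labels)
scores <- score_genes(v$values, sim$labels)
sel    <- select_top_k(scores, 10)
sel$result
#> Grey relational ranking of 1000 genes (alpha = 0.5)
#> Top genes:
#>        gene   grade
#> 1  gene0224 0.99397
#> 2  gene0918 0.96541
#> 3  gene0557 0.86919
#> ...
recovery_report(sel$selected, sim$truth)$recall
#> [1] 1

cv <- cross_validate(sim$counts, sim$labels, k = 10, n_repeats = 5, seed = 7)
cv
#> 5 x 5-fold cross-validation (gp classifier, top 10 genes, selection nested in folds)
#>            mean    se
#> accuracy  94.50  2.55
#> f_measure 94.02  2.78
#> auc       98.97  0.57
#> mi        76.96 10.39
```

The ten planted differentially expressed genes are exactly the ten with
the highest grey relational grades (recall 1), and the nested
cross-validated GP classifier reaches 94.5% mean accuracy on held-out
samples. The `mi` row is mutual information between predicted and true
labels as a percentage of the 1-bit maximum.

A thin command-line front end is installed as `exec/gragp`, chaining
`simulate → transform → score → select → classify → evaluate → compare`
over TSV files; run it without arguments for usage.

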