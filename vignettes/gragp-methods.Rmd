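---
title: "Methods: grey relational gene selection and GP classification of RNA-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grey relational gene selection and GP classification of RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
what each stage assumes, which knobs matter, why the defaults are what
they are, and what the synthetic-data studies do and do not demonstrate.

## 1. From counts to a normal-theory working scale

RNA-seq counts are overdispersed, right-skewed and heteroscedastic, which
breaks the assumptions of the classical two-sample statistics we want to
use for gene ranking. `voom_transform()` converts counts to log2 counts
per million,

$$v_{gs} = \log_2\!\frac{c_{gs} + 0.5}{L_s + 1}\times 10^6,$$

with $L_s$ the column sum, then models the residual mean–variance
relationship: each gene is regressed on the sample-level design
(intercept + class, plus batch indicators when a batch factor is
supplied), a lowess curve (span 0.5) is fitted through the per-gene points
(mean log2 count, $\sqrt{\text{residual sd}}$), and every observation
receives the precision weight

$$w_{gs} = \big(\mathrm{trend}(\widehat{\log_2\text{count}}_{gs})\big)^{-4}.$$

Numerical choices:

* offset 0.5 on counts and 1 on library sizes — the standard dialect,
  keeping zeros finite while preserving within-sample orderings;
* flat extrapolation of the trend beyond the fitted range, so remote
  fitted values cannot produce negative predicted standard deviations;
* genes with zero residual variance have their predicted
  $\sqrt{\text{sd}}$ floored at $10^{-6}$ before the inverse fourth power.

**Batch handling.** When a batch factor is present it always enters the
design used to estimate residual variances, so weights are batch-aware.
The *values* are left untouched by default; `remove_batch = TRUE`
additionally subtracts the fitted batch terms. Both modes exist because
downstream scoring can legitimately be run either on raw or on
batch-adjusted log-CPM; the package defaults to batch-aware weights with
unadjusted values, and the scores are computed unweighted on the
transformed values (the five criterion formulas are unweighted; the
weights justify treating the transformed data as approximately normal
rather than entering the formulas).

## 2. Five filter criteria

For each gene, with class summaries $(\mu_1, \sigma_1, n_1)$ and
$(\mu_2, \sigma_2, n_2)$ on the transformed scale (unbiased $n-1$
standard deviations):

| criterion | definition | degenerate-input rule |
|---|---|---|
| t | $\lvert\mu_1-\mu_2\rvert/\sqrt{\sigma_1^2/n_1+\sigma_2^2/n_2}$ | 0 if means equal and both sds zero; capped at $10^8$ if sds zero but means differ |
| entropy | $\tfrac12[\sigma_1^2/\sigma_2^2+\sigma_2^2/\sigma_1^2-2+(1/\sigma_1^2+1/\sigma_2^2)(\mu_1-\mu_2)^2]$ | variances floored at $10^{-8}$ |
| Bhattacharyya | $\tfrac14\ln\tfrac14(\sigma_1^2/\sigma_2^2+\sigma_2^2/\sigma_1^2+2)+\tfrac14(\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2)$ | as entropy |
| Wilcoxon | $\lvert W-\mathrm E[W]\rvert/\mathrm{sd}[W]$, $W$ = midrank sum of the smaller group | 0 when all pooled values tie |
| AUC | $\max(\mathrm{AUC}, 1-\mathrm{AUC})$, empirical with half-credit ties | — |

The floor and cap keep every score finite while preserving the ordering a
practitioner expects (perfectly separated constant genes rank top, not
crash). The Wilcoxon statistic is standardized with the tie-corrected
normal-approximation variance
$\frac{n_1 n_2}{12}\big[(N+1)-\sum_t (t^3-t)/(N(N-1))\big]$; midranks plus
tie correction is a deliberate convention, documented here because the
bare "rank-sum statistic" leaves the variance unspecified. The AUC is
folded so that down-regulated genes score as high as up-regulated ones;
the empirical AUC is computed through the rank identity with the
Mann–Whitney U statistic, so no ROC curve is ever interpolated.

## 3. Grey relational aggregation

The genes × 5 score table is an MCDM problem: genes are alternatives,
criteria are the five scores, all declared larger-is-better. Each column
is min–max normalized (`grey_generate()`), so each spans exactly $[0,1]$
and the ranking becomes invariant to positive affine rescaling of any
criterion — the five scores live on incomparable scales and this is what
makes aggregation meaningful. Closeness of gene $i$ to the ideal
reference row of ones is

$$\delta_{ij} = \frac{\Delta_{\min} + \alpha\,\Delta_{\max}}
                     {\Delta_{ij} + \alpha\,\Delta_{\max}},\qquad
  \Delta_{ij} = \lvert 1 - x_{ij}\rvert,$$

with $\Delta_{\min},\Delta_{\max}$ taken over the **whole** matrix and the
distinguishing coefficient $\alpha = 0.5$ by default ($\alpha$ only
compresses or expands the coefficient range; it rarely changes a top-k
set). The grade is the weighted mean $\sum_j w_j \delta_{ij}$.

Open choices made here: criterion weights default to **equal** ($w_j =
1/5$) — the aggregation introduces weights but no principled unequal
choice exists a priori, so equal weighting is the neutral default and the
argument is exposed; ties in grade break by original gene order (stable
radix sort) so selection is deterministic.

## 4. Gaussian process classifier

`gp_fit()` is a from-scratch binary GP classifier: zero-mean prior with
squared-exponential covariance (ARD by default, one length-scale per
gene), logistic likelihood, and Laplace approximate inference — Newton
iteration to the posterior mode $\hat f$, with the approximate log
marginal likelihood

$$\log Z \approx -\tfrac12 \hat a^\top \hat f + \log p(y\mid \hat f)
  - \textstyle\sum_i \log L_{ii},$$

maximized over log hyperparameters by BFGS (finite-difference gradients,
25 iterations by default — ample for the $n \le 120$, $k \approx 10$
problems this package targets). Predictive probabilities average the
logistic over the Gaussian latent predictive by 20-point Gauss–Hermite
quadrature. Inputs are standardized per gene with training-fold
statistics, which makes unit initial hyperparameters sensible; a relative
jitter of $10^{-8}$ on the kernel diagonal absorbs duplicate or nearly
duplicate samples. Laplace was chosen over EP as the default because it
is cheap, deterministic, and — as the test suite verifies against
brute-force integration of the exact 3-point posterior — accurate to a
few hundredths of a nat at these sample sizes.

Note one honest subtlety encoded in the tests: duplicating a training
point is numerically harmless (jitter) but *not* a no-op — the duplicate
doubles that observation's likelihood contribution, so predictions move
slightly, as they should.

## 5. Sparse Poisson LDA comparator

`splda()` models counts in class $k$ as
$X_{ij} \sim \text{Poisson}(s_i\, g_j\, d_{kj})$ with $g_j$ the gene's
total training count and size factors $s_i$ estimated by total count,
median ratio (reference genes = those positive in every training sample,
to keep geometric means finite), or the 75th percentile (linear
interpolation between order statistics — the convention is pinned down by
an oracle test because "75th percentile" alone underdetermines it). With
$a = X_{C_k j} + \beta$ and $b = \sum_{i\in C_k} s_i g_j + \beta$, the
class profile is $a/b$ soft-thresholded toward 1 by $\rho/b$, becoming
exactly 1 when $b\lvert 1 - a/b\rvert \le \rho$, so $\rho$ controls how
many genes participate. $\beta = 1$ is the conventional unit pseudocount
(configurable; no principled alternative presents itself at these
depths). Classification maximizes
$\sum_j x^*_j \log d_{kj} - s^* \sum_j g_j d_{kj} + \log \pi_k$ with equal
priors by default and ties broken toward the first class.
`splda_tune_rho()` picks $\rho$ by stratified internal CV, breaking
accuracy ties toward the sparser model; its default grid is 0 plus 29
log-spaced values up to the smallest $\rho$ that silences every gene.

## 6. Cross-validation harness and metrics

`cross_validate()` runs repeated stratified 5-fold CV. Stratification is
used although plain random splitting would also be defensible: with
dozens of samples per class, unstratified folds occasionally lose a class
entirely and the scores are undefined. Within each training fold the
pipeline recomputes scoring, grey relational selection and classifier
training from scratch; log2-CPM values are per-sample quantities, so
computing them once up front leaks nothing. `select_in_fold = FALSE`
provides the optimistic variant (select once on all data) for comparison
with studies that did so. Per repeat, predictions are pooled over the
five folds into one confusion matrix; accuracy, F-measure (positive class
= second class), empirical AUC of the predicted probabilities, and mutual
information are reported as percentages. MI is reported in bits × 100 —
for binary labels the maximum is 1 bit, so the scale reads as "% of
perfect association"; an entropy-normalized variant would differ only for
unbalanced designs. A master seed spawns per-repeat substream seeds, so
runs are reproducible and repeats use independent fold assignments.

`mann_whitney_compare()` is exact (full enumeration over pooled midrank
assignments, ties included) for $m + n \le 12$ and otherwise uses the
tie-corrected normal approximation without continuity correction.

## 7. The synthetic generator and what the studies show

`simulate_counts()` draws NB counts with
$\text{var} = \mu + \phi\mu^2$, mean
$\mu_{gs} = L_s\,\mu_g\,2^{\pm\text{lfc}\cdot\text{DE}_g\cdot\text{class}_s}\,2^{\text{batch lfc}\cdot b_s}$:
baseline means log2-uniform on $[1, 8]$ (2–256 counts, mimicking the
low/high-expressor skew of real count tables), library multipliers
log2-uniform on $[-0.5, 0.5]$, half of DE genes up- and half
down-regulated (so the AUC folding is actually exercised), and dispersion
$\phi = 0.2$ — a typical bulk RNA-seq value. Batch effects can be
orthogonal to class or deliberately confounded.

Two study conditions are fixed as the package's reference experiments:

* **Null calibration** — no DE genes, 1000 genes, 20 samples per class,
  30 CV repeats of the nested GRA–GP pipeline. One caveat discovered and
  documented here: CV repeats on a *single* finite null dataset are
  strongly correlated (whatever chance structure the dataset has persists
  across fold reshuffles), and the between-dataset spread of mean CV
  accuracy is several times the within-dataset repeat standard error. A
  calibration claim based on one dataset's repeat-SE would therefore be a
  seed lottery in either direction. The packaged check spreads the 30
  repeats over 10 independent null datasets and compares the grand mean
  against three times the valid between-dataset standard error.
* **Signal recovery** — 1000 genes, 10 DE at $|\log_2 FC| = 2$,
  $\phi = 0.2$, 40 per class; grey relational top-10 recovery across 20
  seeds and nested CV accuracy of the GP on the selected genes.

What these runs do **not** show: real data have correlated genes,
batch-by-class interactions, unbalanced library-size distributions with
heavy tails, and biological outliers, none of which the generator
produces. Passing the synthetic studies demonstrates correctness of the
machinery and sane behaviour under the stated NB conditions — not
performance claims on any particular tissue or platform.

## 8. Problem sizes and determinism

The shipped tests and the acceptance script use 1000-gene simulations
with 40–80 samples, 3–30 CV repeats and 20 recovery seeds; these sizes
were chosen to exercise every code path at full fidelity while keeping a
complete run in minutes on one core. Every stochastic step — simulation,
fold assignment, rho tuning — flows from an explicit integer seed, and
identical seeds give bit-identical outputs.

## 9. Known limitations

* Binary classification only; the grey relational machinery is
  class-count agnostic but the scores and both classifiers are two-class.
* The GP uses Laplace inference; EP or MCMC would be more accurate for
  strongly non-Gaussian posteriors, at a determinism and cost price.
* Evidence-optimized ARD is high-variance at these sample sizes: with ~10
  selected genes that all separate the same two classes, maximizing the
  approximate marginal likelihood over 11 hyperparameters can prune most
  genes and inflate the signal amplitude. That genuinely raises the
  evidence, but on unlucky dataset draws it costs held-out accuracy
  relative to fixed unit hyperparameters (`optimize = FALSE`) or a single
  shared length-scale (`kernel = "iso"`), both of which are exposed for
  exactly this reason.
* Filter scores ignore gene–gene correlation by construction (a filter
  method's standing assumption for small-n, large-p data).
* sPLDA inherits the Poisson assumption; overdispersed data are handled
  upstream by the transformation route, not inside the comparator.
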