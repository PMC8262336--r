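---
title: "Molecular phenotyping of myometrium: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular phenotyping of myometrium: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquiesce)
```

## The problem

Clinical phenotyping of labor is imprecise: a preterm delivery may follow
membrane rupture, cervical dilation, or intraamniotic infection without the
uterine corpus ever switching from its quiescent (Q) to its contractile,
nonquiescent (NQ) transcriptional program. `myoquiesce` classifies bulk
RNA-seq profiles of myometrial biopsies along that molecular axis and
distills the call down to a parsimonious two-gene statistic, the
ATP2B4/ATP2A2 expression ratio. ATP2B4 (the plasma-membrane calcium pump
PMCA4) falls with contractility while ATP2A2 (the sarco/endoplasmic
reticulum pump SERCA2) rises, so their ratio drops in NQ tissue; low ratios
call NQ.

The pipeline has six stages, mirroring how the analysis is meant to be run:

1. **Clinical scoring** — semiquantitative scores for gestational age
   (term 1 / preterm 0), contractions (0–2), cervical dilation (0–10 cm),
   membrane status (0/1) and Triple I (0/1), plus delivery-group assignment
   (TL, TNL, PTB-sPTL, PTB-PPROM, PTB-PI).
2. **Signature derivation** — negative binomial differential expression
   between term-labor (TL) and term-not-in-labor (TNL) reference samples,
   filtered at |linear fold change| ≥ 1.5 and BH FDR < 0.1.
3. **PCA projection phenotyping** — PCA trained on the labeled term samples
   over the signature genes; remaining samples are projected (no refit) and
   called Q or NQ by the nearest PC1 reference centroid.
4. **Enrichment** — GSEA-style weighted Kolmogorov–Smirnov statistics with a
   permutation null, and overlap-coefficient edges between enriched sets.
5. **Ratio classification** — ATP2B4/ATP2A2 from counts or from
   comparative-Ct qPCR, ROC analysis with Youden threshold selection,
   NQ iff ratio ≤ τ.
6. **Correlated panels** — genes whose log expression tracks either anchor
   at Pearson r ≥ 0.95, candidate substitutes for the two-gene statistic.

## Differential expression model

Counts are modelled per gene as negative binomial,
$k_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i)$ with
$\log \mu_{ij} = \log s_j + x_j^\top \beta_i$, where $s_j$ are
median-of-ratios size factors (plain median of $k_{ij}/\text{geomean}_i$
over all-nonzero genes, rescaled to unit geometric mean) and $x_j$ encodes
the group contrast plus an optional batch covariate. The group coefficient
is tested with a Wald test (normal reference); p-values are adjusted by
Benjamini–Hochberg across genes.

This is a deliberately *simplified* NB pipeline implementing the stated
criteria, not a re-implementation of any specific published tool: there is
no independent filtering, no outlier (Cook's-style) replacement, and no
fold-change shrinkage. Dispersions are per-gene method-of-moments estimates
on normalized counts pooled within groups,
$\hat\alpha = \max\{(\widehat{\mathrm{var}} - \bar\mu)/\bar\mu^2,
10^{-8}\}$, blended 50/50 with a trend $\alpha(\mu) = a_0/\mu + a_1$ fitted
across genes by least squares. The blend stabilizes small-sample moment
estimates while letting genuinely overdispersed genes keep their own signal.
We chose the Wald test over a likelihood-ratio test for transparency and
testability of the fitting path (a vectorized Fisher-scoring IRLS over all
genes simultaneously); at the package's design scale the two agree closely.
Genes that are all-zero in one group get their displayed fold change from
0.5-pseudo-counted group means and are flagged `separated`; their p-values
still come from the model fit.

Calibration, measured by the test suite on planted-null cohorts (20,000
genes, 5 + 5 samples): the raw p-value distribution has Kolmogorov–Smirnov
distance < 0.02 from uniform and type-I error at nominal 0.05 within
[0.04, 0.065].

## PCA phenotyping

The expression transform is $\log_2(\text{normalized count} + 1)$; the
input data do not dictate a transform, and log stabilization is the standard
choice for count PCA. PCA is covariance-based by default (genes are on a
common log scale already); a `scale` flag provides correlation PCA.
Components are oriented so the NQ training centroid lies below the Q
centroid on each axis, which unties phenotype calls from eigen-solver sign
conventions. Projection applies the training centers, scales and loadings
with no refit, and errors on missing genes rather than imputing.

Phenotype calling uses the minimal reproducible rule consistent with
separating clusters along PC1: the midpoint between the two labeled training
centroids, ties toward NQ (a borderline contractile call is the safer
error). An optional transitional band marks samples within
`band/2` × (inter-centroid distance) of the midpoint — total band width a
fraction `band` of the centroid separation — reflecting that borderline
ratios/scores are biologically a continuum.

Clinical association uses midrank (tie-corrected) Spearman correlation, with
a t-approximation for n > 10 and a permutation p-value below that
(exhaustive over all n! orderings up to n = 7, seeded Monte Carlo with
20,000 draws for n = 8–10, where full enumeration is no longer proportionate).

## Enrichment

Genes are ranked by signal-to-noise,
$(\mu_A - \mu_B)/(\sigma_A + \sigma_B)$, with each group's standard
deviation floored at $\max(\sigma, 0.2|\mu|, 10^{-8})$ — the desktop GSEA
convention; the floor fraction is configurable. An alternative ranking,
$\mathrm{sign}(\log_2 \mathrm{FC}) \cdot (-\log_{10} q)$ with $q$ floored at
$10^{-300}$, supports ranking by a differential-expression result; the exact
signed form is our documented choice. Enrichment scores are weighted KS
running-sum extrema (hits weighted by $|m|^p / \sum |m|^p$, default
$p = 1$).

The null is permutation-based. Phenotype permutation regenerates the ranking
each iteration and is the default; with fewer than 7 samples per group the
label space is too coarse (5 + 5 samples admit only 126 distinct
partitions, and resampled relabelings replicate the observed partition often
enough to bias p upward by about 0.01), so the package warns and offers
gene-set permutation, which draws random same-size sets and is exactly
calibrated in that regime. The nominal p-value is sign-stratified with an
add-one rule, $p = (1 + \#\{\text{same-sign perms at least as extreme}\}) /
(1 + \#\{\text{same-sign perms}\})$, so it is never exactly zero and is
uniform under the null; NES divides ES by the mean same-sign permuted |ES|,
and FDR is the usual sign-stratified tail-frequency ratio on the NES scale.
Enrichment-map edges connect sets passing p < 0.005 and FDR < 0.1 with
overlap coefficient $|A \cap B| / \min(|A|, |B|) \ge 0.1$; graph clustering
and rendering are out of scope.

## Ratio classifier

From counts, the ratio is simply $k_{\mathrm{ATP2B4},j} /
k_{\mathrm{ATP2A2},j}$: any per-sample scaling cancels, so raw and
normalized modes agree exactly (both are provided; gene-length effects also
cancel because the same two genes are compared across samples). From qPCR,
duplicate wells are averaged on the Ct scale (the geometric mean of linear
abundances, standard comparative-Ct practice) and
$R = 2^{-(\bar{Ct}_{\mathrm{ATP2B4}} - \bar{Ct}_{\mathrm{ATP2A2}})}$.
Reference-gene normalization (mean Ct of B2M and RPL30, i.e., the log2 of
their geometric mean) is applied for per-gene relative abundances but
cancels in the two-gene ratio, so both paths are implemented.

ROC analysis treats lower ratios as NQ. AUC is computed as the tie-adjusted
Mann–Whitney concordance over all (NQ, Q) pairs, which equals the area under
the stepwise curve and is invariant under strictly increasing transforms.
The operating threshold τ maximizes Youden's J = sensitivity +
specificity − 1; the selection criterion behind published operating
thresholds is typically unstated, so Youden is the default with an explicit
`tau` override for reproducing externally fixed cutoffs. The NQ side of the
threshold is inclusive (NQ iff R ≤ τ). A relative transitional band
$(\tau(1-b), \tau(1+b)]$ is available, mirroring the PCA band.

## The synthetic cohort generator

Every stage is testable without downloads via `simulate_cohort()`. The
generator's defaults are the study conditions of the cohort design the
package targets, chosen once:

* **Design**: 5 TL + 5 TNL term reference samples and 21 preterm samples of
  which 4 are latently NQ (31 samples, 9 NQ / 22 Q); 20,000 genes; 21% of
  genes carry a planted contrast with |log2 FC| ≥ log2(1.5), magnitudes
  log2(1.5) + Exponential(mean 0.35) with random sign.
* **Anchors**: ATP2B4 log2 FC −1.5 and ATP2A2 +0.9 (NQ vs Q), baselines
  1500 and 300 counts (both robustly expressed); reference genes B2M (4000)
  and RPL30 (2500) are planted flat. Anchors are exempt from the
  planted-fraction lottery and always carry their effects — the classifier
  surface requires them — including at `de_fraction = 0` (documented
  exception).
* **Counts**: NB with dispersion trend $\alpha(\mu) = 5/\mu + 0.05$,
  log-normal library sizes (sd 0.2), two sequencing batches with per-gene
  log2 batch effects (sd 0.1); term samples always share batch 1, so the
  reference contrast is batch-free while preterm modelling exercises the
  batch covariate.
* **qPCR**: $Ct = 34 - \log_2(\text{planted expression}) + \varepsilon$,
  duplicate wells, well noise sd 0.15 cycles. Ct values derive from the
  planted means rather than the sampled counts, so the zero-noise limit
  recovers planted ratios exactly and count-level noise enters only through
  the RNA-seq side of comparisons.
* **Clinical emission**: a conditional-probability table per latent
  phenotype (NQ: contractions regular 0.95 / irregular 0.05, dilation
  Binomial(10, 0.5), rupture 0.5; Q: absent 0.7 / irregular 0.3,
  Binomial(10, 0.05), rupture 0.15; Triple I for preterm cases 0.40
  suspected/confirmed, 0.05 unknown). With probability `mismatch_rate`
  (default 0.15) a sample's presentation is emitted from the *opposite*
  phenotype's distribution, modelling clinically laboring but molecularly
  quiescent cases. These probabilities are synthetic conventions — the
  real-world emission rates are unknown — sized to reproduce the qualitative
  picture of a minority of clinically mislabeled preterm samples.
* **RNG**: Mersenne-Twister with inversion normals and rejection sampling,
  pinned and recorded in the run manifest; a fixed seed gives byte-identical
  cohorts.

What the generator does *not* emulate: gene–gene correlation beyond the
shared phenotype effect (so anchor-correlated panels at r ≥ 0.95 are
typically empty on synthetic data, whereas real co-regulated transcriptomes
yield hundreds of panel genes), GC/length biases, outlier samples, and
single-cell structure. Passing tests therefore demonstrate statistical
correctness of the machinery — calibration, recovery of planted effects,
classifier behavior — not the biological effect sizes of any real cohort.

## Numerical choices and degenerate inputs

* Duplicate gene rows in count input are collapsed by summation
  (transcript-to-gene aggregation), with a warning.
* Size factors require at least one all-nonzero gene; the error suggests a
  pseudo-reference fallback rather than silently switching to one.
* IRLS: linear predictors are clamped to ±30 (natural log scale) to avoid
  overflow under separation; at most 30 iterations, convergence at 1e-10.
* Zero-variance signature genes are dropped from PCA with a warning; a
  constant clinical score yields a missing correlation with a warning.
* Ranking ties are broken by metric descending then gene symbol ascending,
  making ranked lists strictly deterministic.
* GSEA p-values use add-one counting; FDR is clipped to 1.
* A PC1 score exactly at the centroid midpoint is called NQ; a ratio exactly
  at τ is called NQ (both documented tie rules, erring toward sensitivity
  for the contractile phenotype).

## Problem sizes used by the test suite

Unit tests run on cohorts of 100–2,000 genes; calibration and recovery
checks use the full 20,000-gene design (one cohort each); the anchor-ratio
ROC check uses 50 replicate cohorts at 2,000 genes, since the two anchor
genes' counts do not depend on how many null genes surround them. The
enrichment calibration check uses 1,000 random sets at 999 permutations so
that the Kolmogorov–Smirnov estimate of the p-value distribution has
sampling noise (~0.027) comfortably below the 0.05 acceptance bar; at 200
sets the expected KS of even perfectly uniform p-values is ~0.06.

## Known limitations

* The DE stage's moment/trend dispersion blend is less efficient than
  shrinkage estimators; it is calibrated at the package's design scale but
  will be conservative for very small counts.
* Phenotype permutation below 7 samples per group is coarse; the package
  warns and offers gene-set permutation.
* Threshold selection by Youden's J is sensible for balanced error costs;
  clinical deployment would want cost-weighted operating points.
* No batch harmonization is applied when concatenating ratio data across
  cohorts; the ratio's within-sample cancellation is the only protection.
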