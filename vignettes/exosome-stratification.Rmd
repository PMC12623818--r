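---
title: "Stratifying chronic pancreatitis from exosomal RNA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying chronic pancreatitis from exosomal RNA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(exococa)
```

Chronic pancreatitis (CP) progresses through exocrine failure
(steatorrhea) and endocrine failure (pancreatogenic diabetes). This
package re-implements a liquid-biopsy stratification workflow that reads
four RNA classes from plasma exosomes (mRNA, miRNA, lncRNA, circRNA),
derives three CP subtypes of increasing severity by cluster-of-cluster
(COCA) integration, and distils a small miRNA panel into a diagnostic
classifier. This vignette records the model, the tunable parameters, and
the design decisions a maintainer should know about.

## The synthetic cohort generator

No patient data ship with the package. `simulate_cohort()` generates
cohorts with the statistical structure the downstream analysis assumes,
so every stage is testable end to end:

* **Scale and baseline.** Expression is log-normal on the log2 scale:
  each feature has a baseline drawn uniformly on [5, 11] (log2 units)
  shared by all samples, plus Gaussian noise with `noise_sd` (default
  0.5, a typical residual spread for normalized bulk RNA-seq on this
  scale). Values are clamped at zero, and an optional negative-binomial
  count mode (`mode = "counts"`, dispersion 0.2) produces raw-count-like
  matrices. The original study never states its normalization beyond
  library-size correction, so the log-normal default is a stand-in, not
  an inference from data.
* **Design.** 22 healthy controls and 89 CP samples split evenly across
  three subtypes, mirroring the derivation cohort; all sizes are
  configurable.
* **Severity signal.** A fraction (default 20%) of each platform's
  features is informative: its group mean shifts by `severity_step`
  (default 1 log2 unit) per ordered severity level Normal → COCA1 →
  COCA2 → COCA3 — upward for mRNA markers and both signature gene sets,
  downward for the informative miRNAs (the miR-24-3p direction). The
  20% informative fraction is a realistic differential-expression rate
  for a disease cohort of this kind.
* **Planted couplings.** Each planted miRNA–mRNA pair draws the mRNA as
  a decreasing affine function of its miRNA plus noise, so the negative
  correlation is guaranteed by construction rather than resting on the
  shared group structure alone.
* **Decoy interactions** are drawn from the *non-informative* features
  of both platforms. A decoy is meant to be a null pair; sampling decoys
  from all features would routinely pair an informative falling miRNA
  with an informative rising mRNA, creating pairs that are planted
  signal in all but name and making recovery metrics meaningless.
* **Coordinates** for lncRNA/mRNA features sit on one synthetic
  chromosome with uniform starts and lengths of 0.5–5 kb, 0-based and
  half-open, feeding the cis-target tests.

What the generator does **not** emulate: read-level sequencing noise,
UMI/ambient-RNA artifacts, batch structure, correlated gene modules, or
feature-specific effect-size heterogeneity (every informative feature
shifts by the same step). Passing tests therefore demonstrate that the
machinery recovers the planted structure under clean, favorable
conditions; they say nothing about robustness to batch effects or
annotation error in real cohorts.

## Consensus clustering and the choice of K

`consensus_sweep()` implements Monti consensus clustering from scratch:
for each K, 1000 iterations (100 in the package's own analyses; see
*Problem sizes*) draw 80% of the samples without replacement, cluster
them with PAM on the Pearson-correlation distance d = 1 − r, and the
consensus entry (i, j) is the fraction of co-sampled iterations in which
i and j co-clustered. Final labels cut an average-linkage tree of
1 − consensus at K.

* **PAM** is the classical deterministic BUILD + SWAP local search
  (compiled, `src/pam.cpp`), with ties broken toward the smallest index.
  Being a local search it can, on rare instances, terminate in a
  swap-stable solution above the global medoid optimum — the reference
  `cluster::pam` returns the identical solution on such instances. About
  94% of small random instances reach the global optimum.
* **Diagnostics.** A(K) is the area under the empirical CDF of the
  upper-triangle consensus entries, computed as
  Σ (x(i) − x(i−1)) · i/m over the sorted entries; PAC is the fraction
  of entries strictly inside (0.1, 0.9) — the conventional window, since
  the study never prints its own; the silhouette uses the same distance
  as the clustering, with singletons contributing 0.
* **K selection per platform** (`select_k()`): lowest PAC wins, PAC
  values within 0.01 of the minimum count as tied, the largest mean
  silhouette breaks ties, remaining ties go to the smallest K. This
  makes the "largest silhouette and lowest PAC" criterion deterministic
  when the two disagree.
* **A known geometric limitation.** The planted severity model makes all
  informative features shift monotonically by the same step, so the three
  subtype centroids are collinear in expression space. PAM at K = 3
  recovers the planted subtypes essentially perfectly (ARI 1.0 across
  seeds), but the 2-cluster cut along the severity axis is often
  perfectly stable under resampling (PAC(2) = 0) and has the larger
  silhouette, so the min-PAC rule frequently returns K = 2 (about half
  of platform sweeps). Feature median-centering — the usual
  pre-processing for correlation-based consensus clustering — does not
  help here: it projects the middle subtype onto pure noise and degrades
  recovery outright. Real cohorts, whose subtypes separate in different
  feature subspaces, do not share this degeneracy. The workflow
  therefore follows the study's own choice and fixes the integration
  target at K = 3 by default (`platform_k = 3`, `coca_k = 3` in
  `pipeline_config()`), while the rule-based selection remains available
  (`platform_k = NULL`) and is reported alongside.

## COCA integration

Per-platform calls are coded into a binary indicator matrix (one column
per platform × cluster; every row sums to the number of platforms) and
consensus-clustered with the same machinery. Pearson distance on binary
rows is well defined whenever rows are non-constant; a constant row
(impossible with ≥ 2 platforms disagreeing anywhere) triggers a logged
fallback to Jaccard distance. The cluster number is guided by the
proportional CDF-area increase, in the exact forward-difference form the original workflow defines:

\[ \Delta(K) = \begin{cases} A(K) & K = 2 \\ \dfrac{A(K+1) - A(K)}{A(K)} & K > 2 \end{cases} \]

Note the *forward* difference — unusual relative to the common
backward-difference convention, which is available via
`delta_k(..., convention = "backward")`. "Did not remarkably increase"
is operationalised as the smallest K ≥ 3 with Δ(K) < 0.1; the threshold
is configurable and the fallback (no K qualifies) returns the largest
evaluated K with a warning. Recovered clusters are renamed COCA1…COCA3
in increasing order of median exocrine-signature score, with ties broken
by cluster size — the study never states how its clusters were mapped to
ordinal names, so severity ordering is this package's declared
convention.

## Signature derivation and scoring

Markers are one-vs-rest Wilcoxon rank-sum tests per cell type with
log2FC = log2((μ_in + c)/(μ_out + c)), pseudocount c = 0.01 on the
normalized scale (the study defers to its toolchain's defaults without
printing a pseudocount). The exocrine signature pools the top 40
markers by log2FC of acinar REG+ and activated stellate cells, the
endocrine signature those of alpha and beta cells; ranking is applied
per cell type and the union de-duplicated, with an fdr < 0.05 gate
before ranking (the study ranks "by log2FC" and carries FDR in its
tables; the gate is declared here). A bulk sample's score is the exact
median of its expression over the signature genes present in the
matrix. Quadrant cuts default to the median score of the healthy
controls on each axis — the study never states its cut placement.

## The diagnostic classifier

All multi-class handling is one-vs-rest, with the union of per-class
survivors taken at each stage (the study says "for each subtype and
healthy samples" without defining the combination rule):

1. **Screen**: single-feature logistic regression per class,
   likelihood-ratio p < 0.01 in any class. Perfect separation is flagged
   and treated as p = 0 — such features are maximally informative, so
   dropping them (as a failed fit) would be perverse.
2. **Stability selection**: "bootstrapping 70% of the data" is read as
   stratified subsampling *without* replacement, matching the printed
   70% fraction; classical with-replacement resampling is available via
   `stability_config(replace = TRUE)`. A feature must be significant at
   p < 0.05 in strictly more than 95% of 1000 resamples ("over 95%" read
   as strict).
3. **LASSO**: one-vs-rest `glmnet` with the penalty at minimum
   cross-validated deviance over 5 stratified folds (the study prints no
   selection rule); the panel is the union of non-zero coefficients.
4. **Network**: a feed-forward softmax network trained by resilient
   backpropagation — per-weight steps that grow ×1.2 while the gradient
   sign persists and shrink ×0.5 when it flips (bounds 1e-6…50, initial
   0.1) — plus a global backtracking acceptance rule: an epoch whose
   proposed update increases the loss is rejected and all steps halve,
   so the accepted-loss trajectory is non-increasing. Inputs are
   standardized on the training set only and the parameters stored for
   prediction, so no test-set leakage occurs. The default grid crosses
   hidden layouts {(), (8), (16), (8,4)} with logistic/tanh activations
   under cross-entropy loss (sum-of-squares is available); the study's
   actual grid values are unpublished. The best specification is the one
   with the highest test-set accuracy, ties going to fewer parameters
   and then grid order.

Models serialize to JSON (`save_classifier()`) holding the panel, class
order, standardization parameters and weights, and reload to identical
predictions.

## Key-pair filtering

Pearson correlations are computed per catalogued miRNA–mRNA pair across
all samples with p from the t transform and BH adjustment across **all
pairs tested in the run** (the study is silent on the adjustment scope).
The correlation filter keeps FDR < 0.05 and r < −0.3, both strict. The
trend screen tests the three adjacent group comparisons with Welch's t
(the study's statistics section names t-tests; Wilcoxon is available
behind a flag) and demands all three significant at p < 0.05 with
agreeing directions — "three comparisons at least" among four ordered
groups *is* all the adjacent comparisons there are. The default keeps
only miRNA-down / mRNA-up pairs, the direction of the miR-24-3p →
S100A8 finding; the mirrored combination is admitted with
`mirrored = TRUE`. Trend p-values are not multiplicity-adjusted, as
printed.

## Numerical and degenerate-input conventions

* Zero-variance features in both groups of a differential test are not
  tested; equal constant means report p = 1, different constant means
  p = 0.
* BH adjustment clamps at the raw p so `fdr >= p` holds exactly in
  floating point.
* Strict inequalities everywhere a threshold is printed with one
  (|FC| > 1, FDR < 0.05, r < −0.3, p < 0.01/0.05), so boundary values
  are excluded.
* One root seed derives independent child seeds for every stage and
  iteration stream (`child_seed()`), keeping results below 2^31 and
  making the whole pipeline a pure function of (config, seed); the
  manifest of `run_pipeline()` checksums every output file to make this
  checkable.

## Problem sizes used in the package's own analyses

The full study protocol (1000 consensus iterations, 1000 stability
resamples) is the default of the per-stage constructors. The shipped
analyses, tests and the acceptance script run the same machinery at 100
consensus iterations and 200 stability resamples with 20 replicate
cohorts (50 for the null false-positive control) — sizes at which the
Monte-Carlo summaries are already stable to well within the margins
being asserted.

## Known limitations

* The collinear-severity geometry above: automatic K selection by
  min-PAC prefers K = 2 on roughly half of the synthetic platform
  sweeps even though K = 3 labels are essentially exact.
* PAM is a local search and does not guarantee the global medoid
  optimum (~6% of tiny random instances).
* The generator's clean structure means recovery results are upper
  bounds on real-data behavior; the actual 12-miRNA panel, the 31
  correlated pairs and the published accuracy figures depend on the
  deposited cohort and external interaction databases and are not
  reproducible from synthetic data.
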