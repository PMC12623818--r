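# exococa

Multi-omics subtype stratification of chronic pancreatitis (CP) from
plasma-exosome RNA profiles, re-implemented as a tested, reproducible R
workflow. The package is aimed at computational biologists who want to run,
audit or adapt the stratification machinery — per-platform consensus
clustering, cluster-of-cluster (COCA) integration, signature scoring, a
miRNA diagnostic classifier, and a miRNA–mRNA key-pair filter — without
access to the original patient sequencing data: a synthetic cohort
generator with planted ground truth stands in for the deposited cohort.

## The analysis

Given four expression matrices over the same samples (mRNA, miRNA, lncRNA,
circRNA; 22 healthy controls + 89 CP patients by default):

1. **Differential expression** per platform (Welch t on log2 values, BH
   adjustment) at the thresholds |log2FC| > 1 and FDR < 0.05, plus lncRNA
   target prediction (*cis*: gene within 10 kb; *trans*: Pearson r > 0.5).
2. **Per-platform consensus clustering** of the CP samples (Monti
   resampling consensus: 1000 iterations of 80% sample resampling, PAM
   k-medoids on the Pearson-correlation distance d = 1 − r, K = 2…10),
   with the CDF area A(K), the proportion of ambiguous clustering
   PAC = #{ 0.1 < consensus(i,j) < 0.9 } / #pairs, and the mean silhouette
   per K.
3. **COCA integration**: the four subtypings are coded into a binary
   indicator matrix (one column per platform × cluster), which is itself
   consensus-clustered. The cluster number is guided by the proportional
   CDF-area increase

   Δ(K) = A(2) for K = 2, and Δ(K) = (A(K+1) − A(K)) / A(K) for K > 2,

   choosing the first K ≥ 3 whose Δ falls below a threshold (default 0.1);
   the workflow's default fixes K = 3, the study's setting. Subtypes are
   renamed COCA1 → COCA3 in increasing order of median exocrine-signature
   score.
4. **Signature scoring**: exocrine (acinar/stellate) and endocrine
   (alpha/beta) gene sets are derived as top-40 one-vs-rest Wilcoxon
   markers from cell-level data; a bulk sample's score on a signature is
   its **median expression** over the set, and samples are placed in a
   four-quadrant diagram cut at the healthy-control medians.
5. **Diagnostic classifier** over {Normal, COCA1, COCA2, COCA3} from
   miRNA profiles: univariate one-vs-rest logistic screen (p < 0.01) →
   bootstrap stability selection (70% subsamples × 1000, keep features
   significant at p < 0.05 in > 95% of resamples) → LASSO (union of
   non-zero one-vs-rest coefficients at the CV-minimum penalty) → a
   grid-searched feed-forward softmax network trained by resilient
   backpropagation, evaluated with confusion matrices on an 80:20 split.
6. **Key miRNA–mRNA pairs**: every catalogued interaction is tested for
   negative correlation (keep FDR < 0.05 and r < −0.3), then both members
   must show opposing monotone trends across Normal → COCA1 → COCA2 →
   COCA3 (all three adjacent Welch comparisons p < 0.05, miRNA falling and
   mRNA rising) — the miR-24-3p / S100A8 pattern.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
synthetic cohort and write their tables to `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f" --seed 1; done
```

Script 04 (COCA integration) prints, for seed 1:

```
  K         A       delta
  2 0.4782710 0.478270988
  3 0.6744127 0.023926048
  4 0.6905487 0.017264698
  ...
Delta(K) rule selects K = 3 (the study fixed the cluster number at 3)
ARI vs planted truth: 1
       coca
planted COCA1 COCA2 COCA3
  COCA1    30     0     0
  COCA2     0    29     0
  COCA3     0     0    30
```

Δ(3) ≈ 0.024 < 0.1 means adding a fourth cluster no longer increases the
consensus CDF area appreciably, so K = 3 is chosen, and the recovered
subtypes match the planted ones exactly (adjusted Rand index 1). Script 07
then recovers all 5 planted miRNA–mRNA couplings from 500 catalogued
pairs with no false positive, e.g.

```
    mirna      mrna          r      p_value          fdr  mirna_trend mrna_trend
 miR_0005 mRNA_0045 -0.9383645 4.172069e-52 2.086034e-49         down         up
```

— a miRNA falling monotonically across severity groups while its target
mRNA rises, with a strongly negative Pearson correlation across samples.

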