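# ddiexpr

Direct data integration (DDI) for multi-study expression biomarker
discovery.

Case/control transcriptomic studies of rare diseases are small — a few
cases, often no controls — and their marker lists are unstable across
studies. `ddiexpr` is for computational biologists who want to pool several
such microarray studies into one analysis and quantify what the pooling
buys: it merges studies by per-array Z-score standardization, calls
differentially expressed genes (DEGs) with a moderated t-statistic, measures
marker-list robustness by subsample overlap, validates marker panels on
independent studies with a linear SVM, and annotates the final list with
gene-set enrichment and interaction-network hub ranking. A synthetic
multi-study generator with known ground truth makes the whole pipeline
testable end to end without any external data.

## The method in brief

**Integration.** Every array is standardized across genes,

    z_i = (x_i − x̄) / δ,

where x̄ and δ are the mean and SD of all gene intensities on that array;
studies are then concatenated on the exact intersection of their gene ids.
Each merged column has mean 0 and SD 1, removing study-level location/scale
batch effects.

**Differential expression.** Per gene, a two-group model with
empirical-Bayes variance moderation: posterior variance
`s²_post = (d0·s0² + df·s²)/(d0 + df)` with (d0, s0²) estimated by method of
moments on log s², moderated t on `d0 + df` degrees of freedom, BH
adjustment, and the dual marker threshold |logFC| > log2(1.5) and adjusted
p < 0.05.

**Robustness.** Ten stratified 2/3 subsamples, DEGs re-called per
subsample, all C(10,2) = 45 pairwise overlap values
(|A∩B| / min(|A|,|B|) by default), their median, and the co-discovery
profile (genes found in ≥ N of the lists).

**Validation.** Linear SVM (C = 1) trained on the discovery dataset
restricted to the marker genes, scored on reserved validation studies:
TP/FN/TN/FP, ACC, SEN, SPE, MCC, threshold-sweep ROC and Mann–Whitney AUC —
all implemented from their definitions.

**Annotation.** Hypergeometric over-representation (exact log-space tails,
BH across the collection), immune-term annotation by set-name pattern, and
hub ranking by degree in the marker-induced subgraph of a
confidence-filtered (> 0.7) interaction network.

## Worked example

```r
library(ddiexpr)

bundle <- run_experiment(list(
  sim = list(n_genes = 1000, n_edges = 20000),
  strategies = list(single = "study7",
                    ddi = c("study2", "study3", "study5", "study6", "study7")),
  validation = c("study1", "study4"),
  final = "ddi",
  seed = 17))

bundle
#> <ddi_experiment>
#>   single: 10 samples, 21 markers, overlap median 0.25, validation AUC 1.00
#>   ddi: 72 samples, 85 markers, overlap median 0.80, validation AUC 1.00

unlist(bundle$strategies$ddi$recovery)
#> sensitivity         fdr
#>   0.8600000   0.4941176

bundle$strategies$ddi$classification
#> <classification_report> TP=8 FN=0 TN=4 FP=0 | ACC 1.00 SEN 1.00 SPE 1.00 MCC 1.00 AUC 1.00

unlist(bundle$comparisons)
#> single_vs_ddi
#>  8.818682e-10

head(bundle$annotation$hubs, 3)
#>     gene degree immune
#> 1 g00848      4  FALSE
#> 2 g00015      3  FALSE
#> 3 g00107      3   TRUE
```

Reading the numbers: the five-study integrated analysis (72 samples) finds
85 markers with a subsample overlap median of 0.80 versus 0.25 for the
single 10-sample study — the robustness gain that motivates integration —
and the difference in the 45 paired overlap values is large (Welch
p ≈ 9e-10). It recovers 86% of the planted true markers; the realized FDR
(0.49 here, at 1000 genes) reflects per-(study, gene) batch shifts that are
partially confounded with group in this asymmetric design (four of the
seven studies have no controls) — see the methods vignette
(`vignettes/ddi-methods.Rmd`) for the analysis of this limitation. The
SVM trained on the integrated markers classifies the 12 reserved validation
samples perfectly, and the hub table ranks markers by their degree in the
confidence-filtered interaction network, flagging immune-annotated ones.

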