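# atcmarkers

Marker discovery and diagnostic validation for anaplastic thyroid
carcinoma (ATC), as a tested R analysis pipeline.

ATC is the most lethal thyroid malignancy, and distinguishing it from
poorly differentiated (PDTC), papillary (PTC) and follicular (FTC)
thyroid carcinoma has long lacked a *positive* marker. This package
implements the two analysis stages behind the proposal of IGF2BP1 and
MAGEA3 as such markers, for anyone who wants to rerun, audit or adapt the
method:

1. **Transcriptome screen.** From a gene x sample RNA-seq count matrix
   with class labels (ATC/PTC/FTC/PDTC/NT): TMM normalization, FPM,
   common NB dispersion, a conditional exact test of ATC vs all other
   samples ("noATC"), BH-FDR; then the *de novo expression screen* —
   mean FPM in noATC < 1, ATC/noATC fold change > 50, FDR <= 0.01 —
   ranked by increasing relative standard deviation (RSD = sd/mean of FPM
   across ATC samples), with cancer-testis annotation of the top 20.
   Preranked GSEA (weighted KS running sum; gene-set permutation NES and
   q-values) characterizes the comparison against hallmark-style gene
   sets.
2. **IHC diagnostics.** From immunohistochemistry cohort tables:
   Histoscores (`H = sum_i i * pct_i` over intensities 0-3, range 0-300),
   positivity calls (any detectable staining by default), pooled 2x2
   tables of marker positivity vs ATC across cohorts, and
   sensitivity/specificity (Wilson CIs), PPV/NPV (standard-logit CIs at
   sample prevalence) and the diagnostic odds ratio
   `DOR = (TP*TN)/(FN*FP)` with log-method CIs and Haldane–Anscombe
   correction for zero cells.

A synthetic-cohort module (`simulate_counts()`, `simulate_ihc_cohort()`,
`make_gene_sets()`) generates inputs with known ground truth — planted
ATC-exclusive markers and decoys — so the whole pipeline is testable
without any external download.

## Worked example

The numbered scripts under `analysis/` run the full workflow on the
synthetic study cohort and the packaged IHC count table, writing tables
under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # cohort + gene sets
Rscript analysis/02_differential_expression.R
Rscript analysis/03_marker_screen.R
Rscript analysis/04_gsea_hallmarks.R
Rscript analysis/05_ihc_diagnostics.R
```

Output of the screen and diagnostics stages (as printed):

```
common dispersion: 0.1025
genes at FDR <= 0.01: 46 of 2040
candidates passing the de novo filter: 28
planted markers in the top 20: 20 / 20
decoys in the top 20: 0
most enriched set: ENRICHED_SET (NES 1.82, q 0)
IGF2BP1  sens 75.0%  spec 99.5%  PPV 96.4% (79.1-99.5)  DOR 612.0 (74.6-5020.8)
MAGEA3   sens 50.0%  spec 100.0%  PPV 100.0% (68.9-99.8)  DOR 411.0 (23.8-7098.3)  [Haldane]
MYC      sens 72.2%  spec 92.2%  PPV 61.9% (49.3-73.1)  DOR 30.7 (12.6-74.8)
```

Reading: the screen recovers every planted marker and rejects every decoy;
on the pooled cohorts (36 ATC vs 205 non-ATC carcinomas) IGF2BP1
identifies ATC with a diagnostic odds ratio of 612, MAGEA3 — perfectly
specific but less sensitive — reaches 411 after zero-cell correction, and
MYC's background expression in other carcinomas drops its PPV to 61.9%,
excluding it as a selective marker.

Equivalent calls from R:

```r
library(atcmarkers)
sim <- simulate_counts(sim_config(seed = 1))
scr <- run_marker_screen(sim$counts, sim$samples, ct_genes = ct_gene_list())
head(scr$markers)

diagnostic_report(thyroid_cohort_counts(),
                  markers = c("IGF2BP1", "MAGEA3", "MYC"))
```

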