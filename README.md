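# methgate

Analysis machinery for asking whether DNA methylation gates a
transcription factor's ability to activate its targets. The motivating
system compares wild-type (WT) cells with Dnmt3a/Dnmt3b double-knockout
(DKO, de novo methylation-deficient) cells, in ES cells and Flk1+ mesoderm
progenitors, before and after switching on a dexamethasone-inducible Gata4
fusion. Genes that respond to Gata4 only in hypomethylated DKO mesoderm —
the *hyper-responsive* genes — are the central readout.

The package implements, as tested reusable functions:

* **Expression statistics** — quantile normalization (mean-of-sorted-columns
  reference, tie-aware), probe-to-gene mean merging, and an empirical-Bayes
  moderated t: gene variances are shrunk toward a scaled-F prior whose
  hyperparameters (d0, s0²) come from digamma/trigamma moment matching of
  log s²; t = log2FC / (s̃·√(1/nₐ+1/n_b)) on d0 + d degrees of freedom.
  Selection uses p < 0.01 and a strictly >2-fold (or >4-fold) change.
* **The responder cascade** — three "up in induced DKO mesoderm" selections
  (vs induced WT, vs uninduced DKO, vs the pre-induction t=0 baseline)
  intersected at 72 h and 24 h; their overlap defines persistent
  responders, and a short-term 0–3 h design gives immediate responders.
* **Temporal clustering** — UPGMA on 1 − Pearson profile distances with a
  deterministic tie rule; the two root clusters are labeled group 1 / group
  2 by their ES-cell response.
* **ChIP peaks** — Gaussian-KDE tag density (bandwidth 30 bp, mass-exact),
  candidate threshold 5× mean density, summit enrichment ≥3× over scaled
  background, differential (DKO-specific) peaks, nearest-gene association
  within 5 kb, and central enrichment of the GATA consensus WGATAR with a
  binomial tail test.
* **Bisulfite scoring** — global clone alignment with C→T-aware scoring
  (compiled), per-CpG methylation calls, conversion/identity QC, pooled
  percent-methylated summaries, lollipop rendering, and Fisher tests
  between profiles.
* **A synthetic-data generator** — plants the full study design (genotype ×
  treatment × context × time with the study's replicate structure, gene
  archetypes, ChIP peaks and bisulfite clone panels) with known ground
  truth, so every stage is validated against construction.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`METHGATE_SEED` selects the seed; default 1):

```sh
Rscript analysis/01_simulate_data.R     # writes results/data/
Rscript analysis/02_expression_de.R
Rscript analysis/03_extract_responders.R
Rscript analysis/04_cluster_profiles.R
Rscript analysis/05_chip_peaks.R
Rscript analysis/06_bisulfite.R
Rscript analysis/07_report.R            # collates results/summary.json
```

Stage 2–6 output at seed 1:

```
           comparison up_2fold down_2fold up_4fold down_4fold
  WT_DexM_vs_DKO_DexM       40          0       40          0
  WT_DexP_vs_DKO_DexP       85          0       41          0
   WT_DexM_vs_WT_DexP       15          0        2          0
 DKO_DexM_vs_DKO_DexP       60          0        8          0
hyper-responsive: 45 @72h, 45 @24h; persistent overlap 45
immediate responders at 3 h: 64; of these 15 are persistent
clustered 45 persistent responders: group1 25 (mean ES lfc 1.89), group2 20 (-0.12)
called 6 peaks; 3 DKO-specific; 6 linked to a gene within 5000 bp
central motif enrichment: 138/175 best matches central (expect 0.20), p = 4.17e-62
WT: 24/24 clones pass QC, 90.0% of CpGs methylated
DKO: 23/24 clones pass QC, 8.7% of CpGs methylated
WT - DKO = 81.3 percentage points (Fisher p = 3.25e-79)
```

Reading the numbers: the 40 genes ≥4-fold up in uninduced DKO are the
planted methylation-sensitive (constitutively derepressed) class; the 45
hyper-responsive genes recovered at both time points are exactly the
planted group 1 + group 2 responders, and the root split separates them by
their ES response (group 1 responds in ES, mean log2FC 1.89; group 2 does
not, −0.12). Of 64 genes already up 2-fold at 3 h, 15 are also persistent
responders. The peak caller recovers all six planted binding sites, the
three planted DKO-specific ones survive the WT comparison, and the GATA
consensus concentrates at peak centers (138/175 vs 20% expected). The
bisulfite panel shows the WT region ~90% methylated versus ~9% in DKO.

The same chain is available in one call:

```r
library(methgate)
res <- run_pipeline(pipeline_config(seed = 1))
str(res$summary)
```

## Layout

```
R/                  implementation (simulators, statistics, cascade,
                    clustering, peaks, bisulfite, pipeline, IO)
src/                compiled Needleman-Wunsch bisulfite alignment (Rcpp)
analysis/           numbered narrative drivers (see worked example)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance suites with
                    brute-force oracles
vignettes/          methods vignette: models, assumptions, parameter
                    rationale, limitations
```
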