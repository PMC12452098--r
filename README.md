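# icisig

Multi-omics response signatures from blood CD8+ T cells for immune
checkpoint inhibition (ICI).

Whether a cancer patient will respond to anti-PD-(L)1 therapy is hard to
predict even when the drug target is expressed. `icisig` implements a
blood-based analysis that discriminates **long-term responders (LTR)** from
**non-responders (NonR)** using three readouts of circulating CD8+ T cells
measured by CITE-seq with paired TCR sequencing:

* **composition** — per-sample T-cell subset/state proportions, compared
  between groups with Wilcoxon rank-sum tests;
* **expression** — pseudobulk differential expression of genes and surface
  markers per T-cell subset, with hypergeometric over-representation
  (`P(X ≥ k)` upper tail, BH-corrected) of marker lists in gene sets;
* **repertoire** — paired-TCR clonotypes, normalized clone sizes
  `|Clonotype_xy| / |Sample_x|`, Gini–Simpson diversity `1 − Σp²`,
  longitudinal expansion/contraction, and a CDR3-edit-distance repertoire
  similarity within and between response groups.

At its core is a **cell-level response classifier**: a multinomial logistic
regression with elastic-net penalty
`NLL + λ(α‖β‖₁ + (1−α)/2 ‖β‖₂²)`, trained on the lenient differential
feature set (log-normalized RNA + denoised ADT) of one T-cell subset, with
**leave-one-sample-out** outer folds, a per-fold grid search over α and
6-fold inner cross-validation for λ, class-balanced training, strict
majority (>50%) sample calls, and a **signature** formed by the per-feature
median coefficient across folds rescaled to [−1, 1] (+1 → NonR, −1 → LTR).
Signatures transfer to any cell × gene matrix through per-cell **module
scores** (signature mean minus expression-matched control genes) compared
between patient groups with Welch t-tests.

Because real cohorts of this kind are small and not redistributable, the
package ships a first-class synthetic cohort generator
(`sim_config()` / `simulate_dataset()`) producing CITE-seq + paired-TCR
data with planted group effects — differential features, composition
shifts, maturity-ordered clone sizes, group-shared TCR motifs — so every
stage is testable against ground truth.

## Worked example

The numbered drivers under `analysis/` run the whole study on a simulated
cohort (8 LTR + 6 NonR donors, 200 cells/sample, 1,000 genes, 13 planted
TEM response markers at log2FC 1.5) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc_normalize.R
Rscript analysis/03_annotate_proportions.R
Rscript analysis/04_pseudobulk_de.R
Rscript analysis/05_tcr_repertoire.R
Rscript analysis/06_train_classifier.R   # full alpha grid, ~5 min
Rscript analysis/07_signature_transfer.R
```

Selected output from one run:

```
QC: 2721 of 2800 cells pass (97.2%)
subset assignment agrees with simulation truth for 98.3% of cells
     label     p_value direction      # TN depleted in responders
6       TN 0.002388057      NonR
planted TEM features recovered at the strict cutoff: 13 of 13
 within-LTR     between within-NonR   # repertoire distances
      62.79       63.51       62.59
leave-one-sample-out CV: 14 folds, 780 cells
  per-cell balanced accuracy: 0.954
  per-sample accuracy: 1.000 (14/14)
signature: 39 features; planted features recovered with LTR direction: 13 of 13
TEM module score LTR vs NonR: t = 27.8, p = 1.82e-132 (means 0.123 vs -0.219)
random size-matched gene sets: p > 0.05 in 19 of 20 draws
```

Reading this: QC keeps ~97% of cells at the stringent default thresholds;
the planted naive-T-cell depletion in responders is detected (raw Wilcoxon
p ≈ 0.002); all 13 planted markers clear the strict differential cutoff
(p < 0.05, |log2FC| ≥ 0.5); within-LTR repertoires are closer than
LTR-vs-NonR ones because of group-shared TCR motifs; the classifier calls
every held-out sample correctly and recovers all planted features with the
correct (LTR) sign; and the learned signature separates the groups on an
independently simulated cohort while size-matched random gene sets do not.

## Layout

* `R/` — package code: simulation, QC/normalization, annotation,
  pseudobulk DE + enrichment, TCR statistics, classifier, transfer.
* `analysis/` — numbered narrative drivers (the pipeline).
* `tests/testthat/` — unit, property and acceptance tests.
* `vignettes/icisig-methods.Rmd` — the model, its assumptions, parameter
  choices and limitations.
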