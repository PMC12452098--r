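---
title: "Methods: CD8+ T-cell multi-omics signatures of checkpoint-inhibitor response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CD8+ T-cell multi-omics signatures of checkpoint-inhibitor response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`icisig` implements a blood-based multi-omics pipeline for discriminating
long-term responders (LTR) from non-responders (NonR) to immune checkpoint
inhibition, using CITE-seq profiles (RNA + surface-protein ADT counts) and
paired TCR chains of circulating CD8+ T cells. The pipeline covers per-cell
quality control and normalization, marker-panel subset annotation with
composition tests, pseudobulk differential expression with
over-representation analysis, TCR repertoire statistics, a
leave-one-sample-out elastic-net response classifier with signature
extraction, and module-score transfer of the learned signature to unseen
cohorts. Because real patient cohorts of this kind are small and not
redistributable, the package ships a first-class synthetic-data generator
whose planted effects give every stage a ground truth.

# The synthetic cohort generator

`sim_config()` / `simulate_dataset()` emulate a two-group cohort of
multi-visit donors. The default design is 8 LTR and 6 NonR donors, one
visit, 200 cells per sample and 1,000 genes — the scale at which all
shipped experiments run.

**RNA.** Per-gene baseline means are lognormal (sdlog 1.2), partitioned so
that mitochondrial ("MT-"-prefixed) genes carry ~3% and ribosomal
("RPS"/"RPL") genes ~30% of a cell's library — typical shares for T cells,
and the reason the pMito/pRibo QC metrics behave realistically. Counts are
negative binomial with a common dispersion (0.5); per-sample sequencing
depth varies lognormally (sdlog 0.3), a deliberately generic choice since
cohort-specific depth variation is rarely reported. Subset identity raises
each subset's five planted marker genes 8-fold; cell states work the same
way with a milder 4-fold elevation. A planted differential effect
multiplies the feature mean by `2^log2fc` in cells of the stated (subset,
group) — the quantity every downstream recovery test is scored against.

**ADT.** Surface-marker counts are a cell signal plus Poisson ambient
background; isotype-control rows carry ambient background only, and
ambient-only "empty droplet" barcodes are emitted for background
estimation. The cell signal is negative binomial rather than Poisson:
protein counts are overdispersed in real CITE-seq (staining and binding
efficiency vary between cells), and a Poisson signal would make single
markers unrealistically clean class separators.

**TCR.** Cells are partitioned into clones with geometric sizes whose
success parameter decreases along the maturity order TN < TSCM < TCM <
TEM < TEMRA (validated at configuration time), so expected clone size
grows with differentiation. With probability `tcr_group_sharing` (default
0.5) a clonotype comes from its group's shared motif pool — verbatim or
with one substitution — producing identical and near-identical TCRs across
samples of the same group; otherwise CDR3s are random amino-acid strings
(length 8–20, C...F convention) with V/J calls from a small fixed catalog.
Full V(D)J recombination, transcriptome co-expression structure and
doublets are out of scope. A small fraction of cells is unpaired (5%) or
carries two beta chains (1%) to exercise the clonotype filters.

**What passing tests do and do not show.** The generator has no donor
random effects, no gene–gene correlation beyond group/subset/state
structure, and independent cells within samples. Recovery results on it
demonstrate the pipeline's correctness and calibration, not expected
performance on real cohorts, where donor heterogeneity and correlated
expression will loosen every bound.

# Quality control and normalization

Five per-cell metrics drive filtering: detected genes (NODG), total UMIs
(NUMI), mitochondrial and ribosomal percentages (pMito, pRibo), and
detected protein (NODP = log10 of total ADT counts). The stringent default
thresholds are NODG 340–2,500, NUMI 500–7,000, pMito 0–6%, pRibo 18–55%,
NODP > 2.75. Two-sided ranges are treated as closed intervals (a cell at
340 passes) while the NODP bound is strict; the sources describing these
ranges do not state inclusiveness, so we chose the convention that mirrors
their typography ("–" ranges vs ">") and expose it as a flag. Undefined
metrics (zero-count cells) fail rather than error.

`auto_qc_thresholds()` derives cutoffs from the data: per metric of each
contrasted pair, a Gaussian KDE (Silverman bandwidth) of the marginal is
computed; for a bimodal density the cutoff is the deepest valley between
the two highest modes, assigned as lower or upper bound depending on which
side of the valley holds more cells (the main population). When pairs
disagree, the more stringent value wins; unimodal marginals fall back to
1%/99% quantiles with a warning. The underlying published procedure is a
visual density-cloud inspection, not an algorithm, so this is our
formalization of it.

RNA uses the standard log-normalization `ln(1 + count/total × 10^4)`.
Pseudobulk fold changes, however, are computed on the *linear*
library-size-normalized scale (the convention of averaging `expm1` of
log-normalized values): averaging log values compresses a planted 2-fold
effect to ~0.3–0.4 on the log2FC scale, whereas linear averaging recovers
it at ~1.0. The per-cell classifier features stay on the log scale.

ADT normalization is a transparent simplification of background-anchored
denoising: each marker is z-scored against its ambient (empty-droplet)
distribution, then each cell's mean isotype-control z-score is subtracted
from all its markers. This keeps the two essential ideas — ambient
correction and removal of per-cell technical staining noise — in closed
form; the full Gaussian-mixture per-cell background model is intentionally
not reimplemented.

# Annotation and composition tests

`score_cell_labels()` scores each label as mean(positive markers) −
mean(negative markers) on normalized values (RNA and ADT on their own
scales; panels are expected to be scale-comparable) and assigns the argmax,
with lexicographic tie-breaking and a tie flag. Per-sample composition is
compared between groups with a two-sided Wilcoxon rank-sum test per label
(exact for ≤10 tie-free samples per group, normal approximation with tie
correction otherwise), reported without multiple-testing correction —
composition trends are read on raw p-values, and samples from different
visits of one donor are treated as independent samples.

# Pseudobulk differential expression and enrichment

Expression is averaged per sample within cell-type strata (or across all
cells), dropping (stratum, sample) combinations under 10 cells; testing on
sample-level means avoids pseudo-replicating cells. V(D)J segment genes
(TRAV/TRBV/IG... prefixes) are excluded — they encode donor repertoire, not
regulation. Group differences use the same two-sided rank-sum test with
`log2FC = log2((mean1+eps)/(mean2+eps))`, eps = 1e-9, so zero-mean features
stay finite and are gated by the p-value. Two cutoffs are defined: strict
(p < 0.05, |log2FC| ≥ 0.5) for reported markers and lenient (p < 0.1,
|log2FC| ≥ 0.2) for the classifier's candidate features, deliberately
permissive so features that only matter in combination survive. ADT
differential abundance reuses the same machinery on denoised values; their
z-scale pseudobulk means can be negative, in which case the fold change is
undefined and the feature is simply not selectable.

Over-representation of a gene list in a gene set uses the exact upper-tail
hypergeometric probability `P(X >= k)` (equivalently a one-sided Fisher
test) with Benjamini–Hochberg correction across sets; gene-set databases
are user-supplied GMT files, and shipped tests use synthetic sets only,
since term counts are database-version-dependent.

# TCR repertoire statistics

Clonotypes are cells with exactly one TRA and one TRB chain, keyed by CDR3
amino-acid sequences plus V/J calls of both chains; cells with extra chains
are dropped and tallied, malformed junctions rejected. The normalized
clonotype size is its paired-TCR count divided by the sample's paired-TCR
total; abundances are discretized into the half-open bins (0,1e-5],
(1e-5,1e-4], (1e-4,1e-3], (1e-3,0.01], (0.01,1]. Diversity is the
Gini–Simpson index `1 − Σp²` — the "higher = more diverse" reading —
cross-checked against vegan in the tests. Longitudinal dynamics classify a
shared clonotype as expanded/contracted by comparing normalized sizes
between visits, with exact equality counted separately.

Repertoire similarity uses a documented simplified distance, not the full
published TCR distance (CDR1/2/2.5 loops and gap-penalized BLOSUM
alignment are out of scope): per chain, the Levenshtein distance between
CDR3s times a substitution weight plus a flat V-gene mismatch penalty (4),
with the beta chain weighted 3× the alpha — the convention that beta
contributes most antigen contact. Group-level similarity averages
all-pairs clonotype distances per sample pair (unique clonotypes,
unweighted by clone size; frequency weighting is an option), excluding
same-donor cross-visit pairs, then averages pairs within
within-group/between categories. Whether the original comparisons weighted
by clonotype frequency is not stated; unweighted is the default because it
measures repertoire composition rather than expansion.

# The response classifier

Candidate features are the lenient differential set; the feature matrix
concatenates log-normalized RNA and denoised ADT columns (sorted by
modality then name) for one cell-type stratum. Covariate–response
associations are screened (chi-squared without continuity correction for
categorical, Welch t for continuous) but reported only; in particular the
treatment regimen is deliberately never a feature, so baseline samples
remain classifiable.

The model is a multinomial logistic regression with elastic-net penalty.
Outer evaluation is leave-one-sample-out: all cells of one sample held out
per fold (multiple visits of a donor are distinct samples). Training cells
are optionally downsampled to balanced classes. Per fold, the mixing
parameter is grid-searched (default 0.0–1.0, step 0.05) with 6-fold inner
cross-validation over cells, stratified by class and seeded; the penalty
strength is the inner-deviance minimizer (the "minimum" rule; the
one-standard-error rule is exposed as an option since the original tooling
supports both and no choice is stated). Per-fold (alpha, lambda) pairs are
kept and reported rather than fixed globally. Every fold asserts that no
held-out cell index appears in its training indices.

A sample is called correctly only when *strictly more than* 50% of its
cells receive the true label — exactly half is incorrect. Per-cell
performance is balanced accuracy (mean per-class recall). The signature is
the per-feature median coefficient across folds (for two classes, the
second-minus-first class contrast), retaining non-zero medians and
rescaling by the maximum absolute median so the extremes hit ±1; positive
values point to the second group (NonR), negative to the first (LTR).

# Signature transfer

`module_score()` scores a gene set per cell as mean signature-gene
expression minus mean expression of control genes drawn from the same
average-expression bins (25 equal-frequency bins, 100 controls per
signature gene, seeded) — the standard module-score construction. Group
comparisons use two-sided Welch t-tests against a designated baseline
group (the unequal-variance form is the safe default where only "t-test"
is specified); per-cell scoring is the default, per-patient aggregation is
left to the caller. The negative control scores a size-matched random gene
set, conventionally excluding the tested signature from the draw so the
control measures scoring calibration rather than residual signal.

# Numerical and scale choices

* All randomness is seeded; identical configs and seeds give bit-identical
  datasets, fold assignments and control-gene draws. RNG state is always
  restored.
* Wilcoxon p-values: exact distribution for ≤10 tie-free samples per
  group; identical data returns p = 1.
* Background sds are floored at 1e-8 (warning) for zero-variance markers.
* Degenerate inputs fail loudly where they indicate upstream errors
  (zero-total cells at normalization, empty CDR3s) and soft-fail where
  they are expected data features (undefined QC metrics, unpaired cells).
* Shipped experiment sizes: differential recovery and null calibration run
  10 seeds each at the 8+6 × 200-cell design; classifier recovery runs 5
  seeds with the alpha grid at step 0.25 and 4 label permutations at alpha
  0.5 (the full step-0.05 grid remains the package default and is used in
  the `analysis/` drivers); the transfer cohort uses 400 cells per sample
  so both groups exceed 500 effector-memory cells; repertoire-similarity
  experiments plant high group sharing (0.8) over 20 seeds.

# Known limitations

* The generator's independence assumptions (no donor random effects, no
  co-expression) make planted-recovery rates optimistic relative to real
  cohorts.
* The simplified ADT denoising and TCR distance are stand-ins that keep
  the respective method ideas at desk scale; results depending on their
  fine structure (e.g. absolute distance values) are not comparable to the
  full algorithms.
* Gene-set enrichment covers over-representation only; ranked GSEA is
  deliberately out of scope.
* With more than two response classes the signature contrast is not
  reduced; per-class coefficient matrices are returned as-is.
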