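#!/usr/bin/env Rscript
# Simulate the study cohort: two response groups (8 LTR donors, 6 NonR
# donors; one visit each), 200 CD8+ T cells per sample with RNA, surface
# (ADT) and paired-TCR readouts. Thirteen response markers are planted on
# effector memory (TEM) cells of the responder group -- ten genes and three
# surface markers at log2 fold change 1.5 -- so every later stage can be
# judged against ground truth. A separate two-visit donor is simulated for
# the clonotype dynamics analysis.

suppressMessages(library(icisig))
dir.create("results", showWarnings = FALSE)
dir.create("scratch/cohort", recursive = TRUE, showWarnings = FALSE)

planted <- rbind(
  data.frame(subset = "TEM", feature = sprintf("GENE%04d", 1:10),
             group = "LTR", log2fc = 1.5),
  data.frame(subset = "TEM", feature = sprintf("ADT%03d", 1:3),
             group = "LTR", log2fc = 1.5)
)
cfg <- sim_config(planted_de = planted, seed = 20260925L)
print(cfg)

ds <- simulate_dataset(cfg)
print(ds)
write_dataset(ds, "scratch/cohort")
write_sim_config(cfg, "scratch/cohort/sim_config.yaml")

# longitudinal pair: half of the v1 clonotypes persist and expand 2-fold
pair_cfg <- sim_config(planted_de = planted, cells_per_sample = 400L,
                       seed = 20260926L)
pair <- simulate_timepoint_pair(pair_cfg, shared_fraction = 0.5,
                                expansion_factor = 2)
write_dataset(pair, "scratch/cohort_pair")

cat("cohort written to scratch/cohort (",
    nrow(ds$gene_counts), "cells ), pair to scratch/cohort_pair\n")
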