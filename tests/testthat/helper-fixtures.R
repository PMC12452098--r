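# Shared fixtures: small cohorts keep module tests fast; acceptance-scale
# experiments live in test-acceptance.R.

small_config <- function(seed = 1L, planted_de = NULL,
                         n_donors_per_group = c(LTR = 3L, NonR = 3L),
                         cells_per_sample = 80L, n_genes = 300L, ...) {
  sim_config(n_donors_per_group = n_donors_per_group,
             cells_per_sample = cells_per_sample, n_genes = n_genes,
             planted_de = planted_de, seed = seed, ...)
}

# planted effect table on TEM cells of the LTR group
tem_planted <- function(n_rna = 10, n_adt = 0, log2fc = 1.5) {
  rbind(
    if (n_rna > 0) data.frame(subset = "TEM",
                              feature = sprintf("GENE%04d", seq_len(n_rna)),
                              group = "LTR", log2fc = log2fc),
    if (n_adt > 0) data.frame(subset = "TEM",
                              feature = sprintf("ADT%03d", seq_len(n_adt)),
                              group = "LTR", log2fc = log2fc)
  )
}

sample_group_map <- function(ds, levels = c("LTR", "NonR")) {
  m <- ds$cell_meta[!duplicated(ds$cell_meta$sample_id), ]
  setNames(factor(m$response_group, levels = levels), m$sample_id)
}

sample_donor_map <- function(ds) {
  m <- ds$cell_meta[!duplicated(ds$cell_meta$sample_id), ]
  setNames(m$donor_id, m$sample_id)
}

# one-row clonotype record for distance tests
clono <- function(cdr3a, va, cdr3b, vb) {
  list(cdr3a = cdr3a, va = va, ja = "TRAJ1", cdr3b = cdr3b, vb = vb,
       jb = "TRBJ1")
}
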