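#!/usr/bin/env Rscript
# TCR repertoire statistics: paired-chain clonotypes, abundance
# discretization, Gini-Simpson diversity per sample, inter-sample
# repertoire distance within and between response groups, and longitudinal
# clonotype dynamics on the two-visit donor.

suppressMessages(library(icisig))
norm <- readRDS("scratch/normalized.rds")

ct <- build_clonotypes(norm$tcr, norm$cell_meta)
cat("dropped cells:", paste(names(attr(ct, "dropped")),
                            attr(ct, "dropped"), collapse = ", "), "\n")

div <- sample_diversity(ct)
groups <- setNames(norm$cell_meta$response_group, norm$cell_meta$sample_id)
groups <- groups[!duplicated(names(groups))]
div$group <- groups[div$sample_id]
write.table(div, "results/tcr_diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("median Simpson diversity: LTR %.4f vs NonR %.4f\n",
            median(div$simpson[div$group == "LTR"]),
            median(div$simpson[div$group == "NonR"])))

tot <- attr(ct, "sample_totals")
bins <- discretize_abundance(normalized_size(ct$count, tot[ct$sample_id]))
abundance <- as.data.frame(table(group = groups[ct$sample_id], bin = bins))
write.table(abundance, "results/tcr_abundance_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

donors <- setNames(norm$cell_meta$donor_id, norm$cell_meta$sample_id)
donors <- donors[!duplicated(names(donors))]
gs <- group_similarity(ct, groups, donors)
print(round(gs$category_means, 2))
cat("within-LTR repertoires are closer than LTR-vs-NonR: group-shared motifs\n")
write.table(gs$pairs, "results/tcr_pair_distances.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# longitudinal dynamics on the two-visit donor
pair <- read_dataset("scratch/cohort_pair")
ctp <- build_clonotypes(pair$tcr, pair$cell_meta)
v <- sort(unique(pair$cell_meta$sample_id))
dyn <- clonotype_dynamics(ctp, v[1], v[2])
cat(sprintf("dynamics %s -> %s: %d shared (%d expanded, %d contracted), %d unique to v1, %d new at v2\n",
            v[1], v[2], nrow(dyn$shared), dyn$n_expanded, dyn$n_contracted,
            nrow(dyn$unique_v1), nrow(dyn$unique_v2)))
big <- dyn$shared[which.max(dyn$shared$size_v2), ]
cat(sprintf("largest shared clone holds %.2f%% of the v2 repertoire\n",
            100 * big$size_v2))
write.table(dyn$shared, "results/tcr_dynamics_shared.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
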