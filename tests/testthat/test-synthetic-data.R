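test_that("config validation rejects inconsistent inputs", {
  expect_error(sim_config(n_donors_per_group = c(3, 3)), "named")
  expect_error(small_config(planted_de = data.frame(
    subset = "TEM", feature = "isotype1", group = "LTR", log2fc = 1
  )), "isotype")
  expect_error(small_config(planted_de = data.frame(
    subset = "TEM", feature = "NOPE", group = "LTR", log2fc = 1
  )), "absent")
  expect_error(small_config(planted_de = data.frame(
    subset = "XXX", feature = "GENE0001", group = "LTR", log2fc = 1
  )), "subset")
  # clone sizes must grow with maturity
  bad <- c(TN = 0.4, TSCM = 0.9, TCM = 0.8, TEM = 0.6, TEMRA = 0.4,
           MAIT = 0.7, `NKT-like` = 0.6)
  expect_error(small_config(clone_size_shape = bad), "maturity")
  # probability vectors must sum to one
  props <- matrix(0.2, 2, 7, dimnames = list(
    c("LTR", "NonR"),
    c("TN", "TSCM", "TCM", "TEM", "TEMRA", "MAIT", "NKT-like")
  ))
  expect_error(small_config(subset_props_by_group = props), "sum to 1")
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- small_config(seed = 9L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(d1$gene_counts), as.matrix(d2$gene_counts))
  expect_identical(d1$adt_counts, d2$adt_counts)
  expect_identical(d1$tcr, d2$tcr)
  expect_identical(d1$cell_meta, d2$cell_meta)
})

test_that("dataset structure satisfies its invariants", {
  ds <- simulate_dataset(small_config(seed = 3L))
  meta <- ds$cell_meta
  # sample_id uniquely maps to (donor, visit)
  map <- unique(meta[, c("sample_id", "donor_id", "visit")])
  expect_equal(nrow(map), length(unique(meta$sample_id)))
  # TCR records reference existing cells
  expect_true(all(ds$tcr$cell_id %in% meta$cell_id))
  expect_true(all(ds$gene_counts@x >= 0))
  expect_true(all(ds$adt_counts >= 0))
  # isotype controls are ambient-only: means close to the ambient rate
  iso_mean <- mean(ds$adt_counts[, ds$isotype_names])
  expect_lt(abs(iso_mean - ds$config$ambient_adt_mean), 1)
})

test_that("realized subset fractions track configured proportions", {
  ds <- simulate_dataset(small_config(seed = 21L, cells_per_sample = 200L))
  cfg <- ds$config
  for (s in unique(ds$cell_meta$sample_id)) {
    m <- ds$cell_meta[ds$cell_meta$sample_id == s, ]
    p <- cfg$subset_props_by_group[m$response_group[1], ]
    obs <- table(factor(m$true_subset, levels = names(p)))
    # multinomial 99% bounds per subset (normal approximation)
    n <- nrow(m)
    half <- 2.58 * sqrt(n * p * (1 - p)) + 1
    expect_true(all(abs(obs - n * p) <= half),
                info = paste("sample", s))
  }
})

test_that("without planted effects the pseudobulk fold changes are null", {
  props <- matrix(1 / 7, 2, 7, dimnames = list(
    c("LTR", "NonR"),
    c("TN", "TSCM", "TCM", "TEM", "TEMRA", "MAIT", "NKT-like")
  ))
  ds <- simulate_dataset(sim_config(
    n_donors_per_group = c(LTR = 8L, NonR = 8L), cells_per_sample = 120L,
    n_genes = 400L, subset_props_by_group = props, seed = 17L
  ))
  lin <- normalize_rna(ds$gene_counts, log = FALSE)
  pb <- pseudobulk(lin, ds$cell_meta, strata = "ALL")
  de <- de_test(pb, sample_group_map(ds))
  expect_lt(median(abs(de$log2fc)), 0.1)
})

test_that("a planted log2 effect is recovered by direct group means", {
  planted <- data.frame(subset = "TEM", feature = "GENE0005",
                        group = "LTR", log2fc = 1.0)
  ds <- simulate_dataset(sim_config(planted_de = planted, seed = 5L))
  lin <- normalize_rna(ds$gene_counts, log = FALSE)
  meta <- ds$cell_meta
  # oracle: per-sample mean of normalized counts over TEM cells, then group
  # mean ratio, computed with a plain loop independent of pseudobulk()
  tem <- meta$true_subset == "TEM"
  samp_means <- tapply(lin[tem, "GENE0005"], meta$sample_id[tem], mean)
  grp <- sample_group_map(ds)
  oracle_lfc <- log2(mean(samp_means[grp[names(samp_means)] == "LTR"]) /
                       mean(samp_means[grp[names(samp_means)] == "NonR"]))
  expect_lt(abs(oracle_lfc - 1.0), 0.3)
  # pipeline route agrees with the oracle
  pb <- pseudobulk(lin, meta, strata = "TEM")
  de <- de_test(pb, grp)
  expect_equal(de$log2fc[de$feature == "GENE0005"], oracle_lfc,
               tolerance = 1e-10)
})

test_that("clone sizes grow with subset maturity", {
  ds <- simulate_dataset(small_config(seed = 8L, cells_per_sample = 250L))
  ok <- !is.na(ds$truth$clonotype)
  key <- paste(ds$cell_meta$sample_id, ds$truth$clonotype)[ok]
  sizes <- tapply(key, ds$cell_meta$true_subset[ok],
                  function(x) mean(table(x)))
  expect_lt(sizes[["TN"]], sizes[["TEM"]])
  expect_lt(sizes[["TCM"]], sizes[["TEMRA"]])
})

test_that("timepoint pairs honor the sharing fraction and expansion", {
  cfg <- small_config(seed = 12L, cells_per_sample = 150L)

  tp0 <- simulate_timepoint_pair(cfg, shared_fraction = 0)
  ct0 <- build_clonotypes(tp0$tcr, tp0$cell_meta)
  dyn0 <- clonotype_dynamics(ct0, attr(tp0, "sample_v1"),
                             attr(tp0, "sample_v2"))
  expect_equal(nrow(dyn0$shared), 0)

  tp5 <- simulate_timepoint_pair(cfg, shared_fraction = 0.5)
  ct5 <- build_clonotypes(tp5$tcr, tp5$cell_meta)
  dyn5 <- clonotype_dynamics(ct5, attr(tp5, "sample_v1"),
                             attr(tp5, "sample_v2"))
  n1 <- nrow(dyn5$shared) + nrow(dyn5$unique_v1)
  # realized shared count within the binomial(n1, 0.5) 99% interval
  expect_gt(nrow(dyn5$shared), qbinom(0.005, n1, 0.5))
  expect_lt(nrow(dyn5$shared), qbinom(0.995, n1, 0.5))

  # full sharing at expansion 1: expansion vs contraction is symmetric
  # sampling noise, so across seeds about half of the moving clonotypes
  # expand (single-cell clones can only move one way per seed, which makes
  # single-seed counts lumpy)
  frac <- vapply(1:5, function(i) {
    cfg_i <- small_config(seed = 900L + i, cells_per_sample = 150L)
    tp1 <- simulate_timepoint_pair(cfg_i, shared_fraction = 1,
                                   expansion_factor = 1)
    ct1 <- build_clonotypes(tp1$tcr, tp1$cell_meta)
    dyn1 <- clonotype_dynamics(ct1, attr(tp1, "sample_v1"),
                               attr(tp1, "sample_v2"))
    dyn1$n_expanded / (dyn1$n_expanded + dyn1$n_contracted)
  }, numeric(1))
  expect_gt(mean(frac), 0.3)
  expect_lt(mean(frac), 0.7)

  expect_error(simulate_timepoint_pair(cfg, 0.5, expansion_factor = 0),
               "positive")
  expect_error(simulate_timepoint_pair(cfg, 1.5), "0, 1")
})

test_that("datasets round-trip through the plain-text writers", {
  ds <- simulate_dataset(small_config(seed = 2L,
                                      n_donors_per_group = c(LTR = 1L,
                                                             NonR = 1L),
                                      cells_per_sample = 40L,
                                      n_genes = 120L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(as.matrix(back$gene_counts), as.matrix(ds$gene_counts))
  expect_equal(back$adt_counts, ds$adt_counts)
  expect_equal(back$tcr, ds$tcr)
  expect_equal(back$cell_meta$sample_id, ds$cell_meta$sample_id)
  expect_equal(back$isotype_names, ds$isotype_names)
})

test_that("simulation configs round-trip through YAML", {
  cfg <- small_config(seed = 4L, planted_de = tem_planted(3))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$subset_props_by_group, cfg$subset_props_by_group)
  expect_equal(back$clone_size_shape, cfg$clone_size_shape)
  expect_equal(back$seed, cfg$seed)
  # a re-simulation from the round-tripped config is identical
  expect_identical(as.matrix(simulate_dataset(back)$gene_counts),
                   as.matrix(simulate_dataset(cfg)$gene_counts))
})
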