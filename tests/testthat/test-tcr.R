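make_tcr <- function(cells, cdr3a = "CASSA", cdr3b = "CASSG") {
  rbind(
    data.frame(cell_id = cells, locus = "TRA", v_call = "TRAV1",
               j_call = "TRAJ1", junction_aa = cdr3a),
    data.frame(cell_id = cells, locus = "TRB", v_call = "TRBV1",
               j_call = "TRBJ1", junction_aa = cdr3b)
  )
}

test_that("clonotype construction keeps exactly-paired cells", {
  meta <- data.frame(cell_id = sprintf("c%d", 1:6), sample_id = "s1")
  tcr <- make_tcr(sprintf("c%d", 1:3))                     # one clone, 3 cells
  tcr <- rbind(tcr, make_tcr("c4", cdr3b = "CASSW"))       # second clone
  tcr <- rbind(tcr, data.frame(cell_id = "c5", locus = "TRA",
                               v_call = "TRAV1", j_call = "TRAJ1",
                               junction_aa = "CAAAF"))     # alpha only
  tcr <- rbind(tcr, make_tcr("c6"),
               data.frame(cell_id = "c6", locus = "TRB", v_call = "TRBV2",
                          j_call = "TRBJ2", junction_aa = "CTTTF")) # 2 betas
  ct <- build_clonotypes(tcr, meta)
  expect_equal(sum(ct$count), 4)  # c1..c3 + c4
  expect_equal(nrow(ct), 2)
  expect_equal(ct$count[ct$cdr3b == "CASSG"], 3)
  dropped <- attr(ct, "dropped")
  expect_equal(unname(dropped["multi_chain"]), 1)
  expect_equal(unname(dropped["unpaired"]), 1)
  expect_equal(unname(attr(ct, "sample_totals")["s1"]), 4)
})

test_that("malformed junctions are rejected and totals equal retained cells", {
  meta <- data.frame(cell_id = c("c1", "c2"), sample_id = "s1")
  tcr <- make_tcr(c("c1", "c2"))
  tcr$junction_aa[tcr$cell_id == "c2" & tcr$locus == "TRB"] <- "CAS*Z"
  ct <- build_clonotypes(tcr, meta)
  expect_equal(unname(attr(ct, "dropped")["malformed_junction"]), 1)
  expect_equal(sum(ct$count), 1) # c2 lost its beta chain -> unpaired

  ds <- simulate_dataset(small_config(seed = 61L))
  ct2 <- build_clonotypes(ds$tcr, ds$cell_meta)
  # per-sample totals equal an independent tally of exactly-paired cells
  for (s in unique(ds$cell_meta$sample_id)) {
    cells <- ds$cell_meta$cell_id[ds$cell_meta$sample_id == s]
    rec <- ds$tcr[ds$tcr$cell_id %in% cells, ]
    n_a <- table(factor(rec$cell_id[rec$locus == "TRA"], levels = cells))
    n_b <- table(factor(rec$cell_id[rec$locus == "TRB"], levels = cells))
    expect_equal(unname(attr(ct2, "sample_totals")[s]),
                 sum(n_a == 1 & n_b == 1))
  }
})

test_that("normalized clonotype sizes behave as exact ratios", {
  expect_equal(normalized_size(5, 100), 0.05)
  expect_equal(round(100 * normalized_size(536, 4210), 2), 12.73)
  expect_error(normalized_size(5, 0), "positive")
  expect_error(normalized_size(0, 10), "0 < count")
  ds <- simulate_dataset(small_config(seed = 62L))
  ct <- build_clonotypes(ds$tcr, ds$cell_meta)
  tot <- attr(ct, "sample_totals")
  for (s in names(tot)) {
    f <- normalized_size(ct$count[ct$sample_id == s], tot[[s]])
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})

test_that("abundance discretization uses the half-open interval borders", {
  bins <- discretize_abundance(c(1e-5, 2e-5, 5e-4, 0.005, 0.5, 1))
  expect_equal(as.character(bins),
               c("(0,1e-05]", "(1e-05,0.0001]", "(0.0001,0.001]",
                 "(0.001,0.01]", "(0.01,1]", "(0.01,1]"))
  expect_error(discretize_abundance(0), "0, 1")
  expect_error(discretize_abundance(1.2), "0, 1")
  # brute-force loop oracle on random fractions
  set.seed(5)
  f <- runif(200, 1e-6, 1)
  got <- discretize_abundance(f)
  borders <- c(0, 1e-5, 1e-4, 1e-3, 0.01, 1)
  oracle <- vapply(f, function(x) {
    which(x > borders[-6] & x <= borders[-1])
  }, integer(1))
  expect_equal(as.integer(got), oracle)
})

test_that("Gini-Simpson diversity matches closed forms and vegan", {
  expect_equal(simpson_diversity(10), 0)
  for (K in c(2, 5, 17)) {
    expect_equal(simpson_diversity(rep(3, K)), 1 - 1 / K)
  }
  expect_equal(simpson_diversity(c(2, 1, 1)), 0.625)
  # permutation invariance
  x <- c(7, 1, 3, 9, 2)
  expect_equal(simpson_diversity(x), simpson_diversity(rev(x)))
  expect_gte(simpson_diversity(x), 0)
  expect_lt(simpson_diversity(x), 1)
  expect_error(simpson_diversity(numeric()), "positive")
  skip_if_not_installed("vegan")
  expect_equal(simpson_diversity(x),
               unname(vegan::diversity(x, index = "simpson")))
})

test_that("clonotype dynamics classify expansion by normalized size", {
  df <- rbind(
    data.frame(clonotype_key = "K1", cdr3a = "CAF", va = "TRAV1",
               ja = "TRAJ1", cdr3b = "CGF", vb = "TRBV1", jb = "TRBJ1",
               sample_id = "v1", count = 10L),
    data.frame(clonotype_key = "K2", cdr3a = "CCF", va = "TRAV1",
               ja = "TRAJ1", cdr3b = "CDF", vb = "TRBV1", jb = "TRBJ1",
               sample_id = "v1", count = 90L),
    data.frame(clonotype_key = "K1", cdr3a = "CAF", va = "TRAV1",
               ja = "TRAJ1", cdr3b = "CGF", vb = "TRBV1", jb = "TRBJ1",
               sample_id = "v2", count = 30L),
    data.frame(clonotype_key = "K3", cdr3a = "CEF", va = "TRAV1",
               ja = "TRAJ1", cdr3b = "CFF", vb = "TRBV1", jb = "TRBJ1",
               sample_id = "v2", count = 120L)
  )
  ct <- structure(df, class = c("icisig_clonotypes", "data.frame"),
                  sample_totals = c(v1 = 100L, v2 = 150L),
                  dropped = c(multi_chain = 0L, unpaired = 0L,
                              malformed_junction = 0L))
  dyn <- clonotype_dynamics(ct, "v1", "v2")
  # K1: 10/100 = 0.1 -> 30/150 = 0.2, expanded
  expect_equal(dyn$shared$status, "expanded")
  expect_equal(dyn$n_expanded, 1)
  expect_equal(dyn$unique_v1$clonotype_key, "K2")
  expect_equal(dyn$unique_v2$clonotype_key, "K3")
  expect_equal(dyn$n_expanded + dyn$n_contracted + dyn$n_equal,
               nrow(dyn$shared))
  expect_error(clonotype_dynamics(ct, "v1", "v1"), "distinct")
})

test_that("the simplified TCR distance has metric-like behavior", {
  cfg <- tcr_distance_config()
  a <- clono("CASSF", "TRAV1", "CASRF", "TRBV1")
  expect_equal(tcr_distance(a, a, cfg), 0)
  # single beta substitution, same V genes: 1 * subst(1) * beta weight(3)
  b <- clono("CASSF", "TRAV1", "CASKF", "TRBV1")
  expect_equal(tcr_distance(a, b, cfg), 3)
  # V-gene mismatch adds the flat penalty per chain
  d <- clono("CASSF", "TRAV2", "CASRF", "TRBV1")
  expect_equal(tcr_distance(a, d, cfg), 1 * 4)
  expect_error(tcr_distance(clono("", "TRAV1", "CASRF", "TRBV1"), a, cfg),
               "empty CDR3")

  set.seed(31)
  rand <- function() clono(
    paste(sample(c("A", "C", "S", "R", "F"), 6, TRUE), collapse = ""),
    sample(c("TRAV1", "TRAV2"), 1),
    paste(sample(c("A", "C", "S", "R", "F"), 6, TRUE), collapse = ""),
    sample(c("TRBV1", "TRBV2"), 1))
  for (i in 1:50) {
    x <- rand(); y <- rand()
    expect_equal(tcr_distance(x, y, cfg), tcr_distance(y, x, cfg))
  }
  # triangle inequality on the Levenshtein component (V penalty zero)
  cfg0 <- tcr_distance_config(v_penalty = 0)
  for (i in 1:500) {
    x <- rand(); y <- rand(); z <- rand()
    expect_lte(tcr_distance(x, z, cfg0),
               tcr_distance(x, y, cfg0) + tcr_distance(y, z, cfg0) + 1e-12)
  }
})

test_that("group similarity excludes same-donor pairs and averages pairs", {
  one_clone <- function(sample, key) {
    data.frame(clonotype_key = key, cdr3a = "CAAF", va = "TRAV1",
               ja = "TRAJ1", cdr3b = strsplit(key, "_")[[1]][1],
               vb = "TRBV1", jb = "TRBJ1", sample_id = sample, count = 5L)
  }
  df <- rbind(one_clone("s1", "CASSF_1"), one_clone("s2", "CASSF_1"),
              one_clone("s3", "CASTF_1"), one_clone("s4", "CASTF_1"))
  ct <- structure(df, class = c("icisig_clonotypes", "data.frame"),
                  sample_totals = setNames(rep(5L, 4),
                                           sprintf("s%d", 1:4)),
                  dropped = c(multi_chain = 0L, unpaired = 0L,
                              malformed_junction = 0L))
  groups <- setNames(c("LTR", "LTR", "NonR", "NonR"), sprintf("s%d", 1:4))
  donors <- setNames(sprintf("d%d", 1:4), sprintf("s%d", 1:4))
  gs <- group_similarity(ct, groups, donors)
  # identical single-clonotype repertoires: zero within-group distance
  expect_equal(unname(gs$category_means["within-LTR"]), 0)
  expect_equal(unname(gs$category_means["within-NonR"]), 0)
  expect_gt(unname(gs$category_means["between"]), 0)
  expect_equal(nrow(gs$pairs), choose(4, 2))

  # same-donor pairs (other visits) are excluded: one extra visit of a
  # donor removes exactly (n_samples - 1) pairs... the donor's own pair
  donors2 <- donors; donors2["s2"] <- "d1"
  gs2 <- group_similarity(ct, groups, donors2)
  expect_equal(nrow(gs2$pairs), choose(4, 2) - 1)
})

test_that("planted group sharing makes within-group repertoires closer", {
  wins <- vapply(1:5, function(seed) {
    ds <- simulate_dataset(small_config(
      seed = 800L + seed, cells_per_sample = 60L,
      n_donors_per_group = c(LTR = 4L, NonR = 3L)
    ))
    ct <- build_clonotypes(ds$tcr, ds$cell_meta)
    gs <- group_similarity(ct, sample_group_map(ds), sample_donor_map(ds))
    gs$category_means[["within-LTR"]] < gs$category_means[["between"]]
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
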