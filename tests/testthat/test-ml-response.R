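test_that("confounder screening applies the right test per covariate type", {
  labels <- rep(c("LTR", "NonR"), each = 6)
  cov <- data.frame(
    gender = rep(c("M", "F"), 6),                 # balanced 2x2: chi2 = 0
    const = rep("x", 12)
  )
  expect_warning(res <- confounder_tests(cov, labels), "constant")
  expect_equal(res$statistic[res$covariate == "gender"], 0)
  expect_equal(res$p_value[res$covariate == "gender"], 1)
  expect_equal(res$p_value[res$covariate == "const"], 1)

  # perfectly associated 2x2 table: chi2 = n = 10 without correction
  labels2 <- rep(c("LTR", "NonR"), each = 5)
  res2 <- confounder_tests(data.frame(reg = rep(c("single", "combi"),
                                                each = 5)), labels2)
  expect_equal(res2$statistic, 10)
  expect_lt(res2$p_value, 0.05)

  set.seed(2)
  res3 <- confounder_tests(data.frame(age = c(rnorm(20), rnorm(20, 5))),
                           rep(c("A", "B"), each = 20))
  expect_equal(res3$type, "continuous")
  expect_lt(res3$p_value, 1e-6)
})

test_that("the feature matrix is ordered, typed and value-faithful", {
  rna <- matrix(1:12, 3, 4,
                dimnames = list(sprintf("c%d", 1:3),
                                c("GZMB", "CD69", "TRBV7", "AAA")))
  adt <- matrix(13:18, 3, 2,
                dimnames = list(sprintf("c%d", 1:3), c("CD8", "CD2")))
  meta <- data.frame(cell_id = sprintf("c%d", 1:3), sample_id = "s1",
                     response_group = "LTR", true_subset = "TEM")
  feats <- data.frame(feature = c("GZMB", "CD69", "TRBV7", "CD8", "CD2"),
                      modality = c("RNA", "RNA", "RNA", "ADT", "ADT"))
  fm <- build_feature_matrix(rna, adt, feats, meta)
  # V(D)J gene dropped; ADT block first, then RNA, each alphabetical
  expect_equal(colnames(fm$X),
               c("ADT:CD2", "ADT:CD8", "RNA:CD69", "RNA:GZMB"))
  expect_equal(unname(fm$X["c2", "RNA:GZMB"]), rna["c2", "GZMB"])
  expect_equal(unname(fm$X["c3", "ADT:CD8"]), adt["c3", "CD8"])
  expect_error(
    build_feature_matrix(rna, adt,
                         data.frame(feature = "TRBV7", modality = "RNA"),
                         meta),
    "empty feature list")
})

test_that("class balancing downsamples to the minority class", {
  labels <- rep(c("a", "b"), c(100, 40))
  idx <- balance_cells(labels, seed = 3L)
  expect_equal(as.vector(table(labels[idx])), c(40L, 40L))
  expect_identical(idx, balance_cells(labels, seed = 3L))
  expect_false(identical(idx, balance_cells(labels, seed = 4L)))
  # already balanced input: every cell kept, unconditionally
  expect_equal(balance_cells(rep(c("a", "b"), each = 30)), 1:60)
  expect_error(balance_cells(rep("a", 5)), "2 classes")
})

test_that("elastic-net fits shrink fully at large lambda and interpolate", {
  set.seed(42)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, sprintf("f%d", 1:5)))
  y <- factor(rep(c("A", "B"), c(100, 200)))
  fit <- fit_multinomial_elasticnet(X, y, alpha = 0.5, lambda = 1e3)
  expect_true(all(fit$coefficients == 0))
  # with zero coefficients the intercepts reproduce the class frequencies
  p <- predict(fit$fit, newx = X[1:2, ], s = 1e3, type = "response")[, , 1]
  expect_equal(unname(p[1, ]), c(1 / 3, 2 / 3), tolerance = 1e-3)

  # separable two-class toy at vanishing ridge penalty: training accuracy 1
  Xs <- cbind(f1 = c(rnorm(50, -3), rnorm(50, 3)), f2 = rnorm(100))
  ys <- factor(rep(c("A", "B"), each = 50))
  fs <- fit_multinomial_elasticnet(Xs, ys, alpha = 0,
                                   lambda = c(1, 0.1, 1e-4))
  pred <- predict(fs$fit, newx = Xs, s = 1e-4, type = "class")
  expect_equal(mean(pred == as.character(ys)), 1)
  # single-feature input is padded internally, coefficient shape preserved
  f1 <- fit_multinomial_elasticnet(Xs[, 1, drop = FALSE], ys, alpha = 0,
                                   lambda = 0.01)
  expect_equal(rownames(f1$coefficients), "f1")
  expect_error(fit_multinomial_elasticnet(cbind(Xs, NA), ys, 0.5),
               "non-finite")
})

test_that("sample calls require a strict majority of correct cells", {
  pred <- c(rep("LTR", 51), rep("NonR", 49))
  expect_true(sample_call(pred, "LTR")$correct)
  half <- c(rep("LTR", 50), rep("NonR", 50))
  expect_false(sample_call(half, "LTR")$correct)
  expect_equal(sample_call(c("a", "a", "b"), "b")$predicted, "a")
  expect_error(sample_call(character(), "a"), "1 predicted cell")
})

test_that("balanced accuracy is the mean of per-class recalls", {
  expect_equal(balanced_accuracy(c("a", "a", "b"), c("a", "a", "b")), 1)
  expect_equal(balanced_accuracy(rep(c("a", "b"), each = 50),
                                 rep("a", 100)), 0.5)
  set.seed(8)
  truth <- rep(c("a", "b"), each = 500)
  rand <- sample(c("a", "b"), 1000, replace = TRUE)
  expect_lt(abs(balanced_accuracy(truth, rand) - 0.5), 0.05)
  # classes absent from truth are ignored
  expect_equal(balanced_accuracy(c("a", "a"), c("a", "b")), 0.5)
})

# small planted cohort shared by the CV tests below
planted_cv_fixture <- function(seed) {
  ds <- simulate_dataset(small_config(
    seed = seed, planted_de = tem_planted(n_rna = 6, n_adt = 2),
    n_donors_per_group = c(LTR = 4L, NonR = 3L), cells_per_sample = 120L
  ))
  rna <- normalize_rna(ds$gene_counts)
  lin <- normalize_rna(ds$gene_counts, log = FALSE)
  adt <- normalize_adt(ds$adt_counts, ds$isotype_names, ds$adt_background)
  grp <- sample_group_map(ds)
  de <- rbind(
    de_test(pseudobulk(lin, ds$cell_meta, strata = "TEM"), grp,
            modality = "RNA"),
    de_test(pseudobulk(adt, ds$cell_meta, strata = "TEM"), grp,
            modality = "ADT")
  )
  fm <- build_feature_matrix(rna, adt, select_features(de, "lenient"),
                             ds$cell_meta, stratum = "TEM")
  list(ds = ds, fm = fm)
}

test_that("leave-one-sample-out CV holds out whole samples and predicts", {
  fx <- planted_cv_fixture(101L)
  cfg <- cv_config(alpha_grid = c(0.1, 0.9), nlambda = 30L, seed = 2L)
  cv <- loso_cv(fx$fm$X, fx$fm$y, fx$fm$sample_ids, cfg)
  n_samples <- length(unique(fx$fm$sample_ids))
  expect_equal(nrow(cv$sample_calls), n_samples)   # one fold per sample
  expect_true(cv$leakage_checked)
  # held-out cells never appear in training: cross-check via predictions
  for (s in unique(fx$fm$sample_ids)) {
    cells <- which(fx$fm$sample_ids == s)
    expect_setequal(cv$cell_predictions$cell[
      cv$cell_predictions$sample_id == s], cells)
  }
  # probabilities sum to one
  pr <- as.matrix(cv$cell_predictions[, cv$classes])
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
  # strong planted signal: high per-sample accuracy
  expect_gte(mean(cv$sample_calls$correct), 6 / 7)
  expect_gt(cv$balanced_accuracy, 0.7)
  # chosen hyperparameters come from the searched grid
  expect_true(all(cv$chosen$alpha %in% cfg$alpha_grid))
})

test_that("coefficient integration recovers planted directions", {
  fx <- planted_cv_fixture(102L)
  cv <- loso_cv(fx$fm$X, fx$fm$y, fx$fm$sample_ids,
                cv_config(alpha_grid = c(0.1, 0.5), nlambda = 30L,
                          seed = 3L))
  sig <- integrate_coefficients(cv)
  expect_true(nrow(sig) >= 1)
  expect_equal(max(abs(sig$coefficient)), 1)
  planted <- tem_planted(n_rna = 6, n_adt = 2)
  hits <- sig[sig$feature %in% planted$feature, ]
  # planted features are up in LTR (first group) -> negative contrast
  expect_gte(mean(hits$direction == "LTR"), 0.8)
  expect_gte(nrow(hits), 0.5 * nrow(planted))
  # features zeroed in every fold never enter the signature
  zeroed <- rownames(cv$coef_contrast)[
    rowSums(cv$coef_contrast != 0) == 0]
  expect_false(any(sub("^(RNA|ADT):", "", zeroed) %in% sig$feature))
  expect_error(integrate_coefficients(cv$coef_contrast[, 1:2]), "3 folds")
})

test_that("sample-level label permutation drops accuracy to chance", {
  fx <- planted_cv_fixture(103L)
  samples <- unique(fx$fm$sample_ids)
  true_lab <- setNames(as.character(
    fx$fm$y[match(samples, fx$fm$sample_ids)]), samples)
  acc <- vapply(1:6, function(i) {
    perm <- setNames(sample(true_lab), samples)
    y_perm <- factor(perm[fx$fm$sample_ids], levels = levels(fx$fm$y))
    cv <- loso_cv(fx$fm$X, y_perm, fx$fm$sample_ids,
                  cv_config(alpha_grid = 0.5, nlambda = 20L,
                            seed = 10L + i))
    mean(cv$sample_calls$correct)
  }, numeric(1))
  expect_gte(mean(acc), 0.2)
  expect_lte(mean(acc), 0.8)
})

test_that("degenerate CV inputs are rejected or skipped", {
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- factor(rep(c("A", "B"), 15))
  expect_error(loso_cv(X, y, rep("s1", 30)), ">= 3 samples")
  expect_error(loso_cv(X, factor(rep("A", 30)),
                       rep(c("s1", "s2", "s3"), 10)), "2 response classes")
})
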