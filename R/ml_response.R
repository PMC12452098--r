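#' Confounder association tests for sample covariates
#'
#' Screens clinical covariates for association with the response label:
#' chi-squared test (without continuity correction) for categorical
#' covariates, Welch t-test for continuous ones. Report-only: no covariate
#' is added to the classifier automatically.
#'
#' @param covariates data.frame of per-sample covariates (age, gender, TPS,
#'   regimen, ...).
#' @param labels response group per sample (two groups).
#' @return data.frame: `covariate`, `type`, `statistic`, `p_value`.
#' @export
confounder_tests <- function(covariates, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2 || min(table(labels)) < 2) {
    stop_cfg("need two groups with >= 2 samples each")
  }
  rows <- lapply(names(covariates), function(v) {
    x <- covariates[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("covariate `", v, "` is constant; p = 1", call. = FALSE)
      return(data.frame(covariate = v, type = "constant", statistic = NA_real_,
                        p_value = 1, stringsAsFactors = FALSE))
    }
    if (is.numeric(x)) {
      tt <- t.test(x ~ labels)
      data.frame(covariate = v, type = "continuous",
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      ct <- suppressWarnings(chisq.test(table(x, labels), correct = FALSE))
      data.frame(covariate = v, type = "categorical",
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Assemble the cell-level feature matrix for classification
#'
#' Concatenates log-normalized RNA and denoised ADT columns for the
#' candidate features (the lenient differential set), restricted to one
#' cell-type stratum. V(D)J segment genes are excluded defensively. Feature
#' order is deterministic: sorted by modality, then name, with columns
#' prefixed `RNA:` / `ADT:`.
#'
#' @param rna_norm cells x genes log-normalized matrix.
#' @param adt_norm cells x markers denoised matrix.
#' @param features data.frame with `feature` and `modality` columns (e.g.
#'   from [select_features()]); duplicated features are used once.
#' @param cell_meta per-cell metadata (`sample_id`, `response_group`, and
#'   the subset column).
#' @param stratum subset label to restrict to, or `NULL` for all cells.
#' @param subset_col metadata column holding subset labels.
#' @return list: `X` (cells x features), `y` (factor), `sample_ids`,
#'   `features` (ordered data.frame).
#' @export
build_feature_matrix <- function(rna_norm, adt_norm, features, cell_meta,
                                 stratum = NULL, subset_col = "true_subset") {
  features <- unique(features[, c("feature", "modality")])
  rna_f <- exclude_vdj_features(features$feature[features$modality == "RNA"])
  adt_f <- features$feature[features$modality == "ADT"]
  if (!length(rna_f) && !length(adt_f)) {
    stop_cfg("empty feature list after V(D)J exclusion")
  }
  feats <- rbind(
    data.frame(feature = sort(adt_f), modality = "ADT",
               stringsAsFactors = FALSE),
    data.frame(feature = sort(rna_f), modality = "RNA",
               stringsAsFactors = FALSE)
  )
  keep <- if (is.null(stratum)) rep(TRUE, nrow(cell_meta))
          else cell_meta[[subset_col]] == stratum
  cols <- lapply(seq_len(nrow(feats)), function(i) {
    m <- if (feats$modality[i] == "RNA") rna_norm else adt_norm
    if (!feats$feature[i] %in% colnames(m)) {
      stop_cfg("feature `", feats$feature[i], "` absent from its modality")
    }
    m[keep, feats$feature[i]]
  })
  X <- do.call(cbind, cols)
  colnames(X) <- paste0(feats$modality, ":", feats$feature)
  list(X = X, y = factor(cell_meta$response_group[keep]),
       sample_ids = cell_meta$sample_id[keep], features = feats)
}

#' Downsample cells to balanced class sizes
#'
#' @param labels per-cell class labels (>= 2 classes, all non-empty).
#' @param seed RNG seed for the draw.
#' @return sorted integer indices of the retained cells; every class is
#'   represented by exactly the minority-class count.
#' @export
balance_cells <- function(labels, seed = 1L) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab == 0)) {
    stop_cfg("need >= 2 classes, each with at least one cell")
  }
  m <- min(tab)
  with_seed(seed, {
    idx <- unlist(lapply(levels(labels), function(l) {
      i <- which(labels == l)
      if (length(i) > m) sample(i, m) else i
    }))
  })
  sort(idx)
}

#' Fit a multinomial elastic-net logistic regression
#'
#' Penalized multinomial logistic regression minimizing the negative
#' log-likelihood plus `lambda * (alpha * L1 + (1 - alpha)/2 * L2)`.
#' Features are standardized internally; coefficients are returned on the
#' original scale.
#'
#' @param X cells x features matrix (finite values).
#' @param y class labels.
#' @param alpha elastic-net mixing in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param lambda penalty strength; one value or a path (if `NULL`, glmnet's
#'   automatic path is used).
#' @return list: `coefficients` (features x classes matrix at the smallest
#'   lambda), `intercepts`, `fit` (the underlying glmnet object), `classes`.
#' @export
fit_multinomial_elasticnet <- function(X, y, alpha, lambda = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_cfg("non-finite values in the feature matrix")
  y <- as.factor(y)
  p <- ncol(X)
  if (p == 1) { # the solver needs >= 2 columns; pad with an all-zero dummy
    X <- cbind(X, `.dummy` = 0)
  }
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = alpha,
                        lambda = lambda, standardize = TRUE)
  s <- min(fit$lambda)
  cf <- glmnet::coef.glmnet(fit, s = s)
  coefs <- vapply(cf, function(v) as.numeric(v)[-1], numeric(ncol(X)))
  if (p == 1) coefs <- coefs[1, , drop = FALSE]
  X <- X[, seq_len(p), drop = FALSE]
  intercepts <- vapply(cf, function(v) as.numeric(v)[1], numeric(1))
  rownames(coefs) <- colnames(X)
  list(coefficients = coefs, intercepts = intercepts, fit = fit,
       classes = levels(y))
}

#' Cross-validation configuration for the response classifier
#'
#' @param alpha_grid elastic-net mixing values searched per fold.
#' @param inner_folds inner cross-validation folds for the lambda path
#'   (cells stratified by class).
#' @param nlambda length of the lambda path.
#' @param balancing downsample training cells to balanced classes.
#' @param lambda_rule `"min"` (inner-deviance minimizer) or `"1se"`.
#' @param min_cells_per_sample samples with fewer cells in the stratum are
#'   excluded with a warning.
#' @param seed RNG seed controlling balancing and inner-fold assignment.
#' @return list of class `icisig_cv_config`.
#' @export
cv_config <- function(alpha_grid = seq(0, 1, by = 0.05), inner_folds = 6L,
                      nlambda = 50L, balancing = TRUE,
                      lambda_rule = c("min", "1se"),
                      min_cells_per_sample = 10L, seed = 1L) {
  if (any(alpha_grid < 0 | alpha_grid > 1)) {
    stop_cfg("alpha values must lie in [0, 1]")
  }
  if (!is_count(inner_folds, 2L)) stop_cfg("inner_folds must be >= 2")
  structure(list(alpha_grid = alpha_grid,
                 inner_folds = as.integer(inner_folds),
                 nlambda = as.integer(nlambda), balancing = isTRUE(balancing),
                 lambda_rule = match.arg(lambda_rule),
                 min_cells_per_sample = as.integer(min_cells_per_sample),
                 seed = as.integer(seed)),
            class = "icisig_cv_config")
}

#' Leave-one-sample-out cross-validated response classification
#'
#' For each outer fold, all cells of one sample are held out; on the
#' remaining cells the elastic-net mixing parameter and penalty strength
#' are chosen by a grid search over `alpha_grid` with inner k-fold
#' cross-validation (cells stratified by class, deviance loss), the model
#' is refit on the full training set at the chosen `(alpha, lambda)`, and
#' the held-out cells are predicted. Multiple visits of one donor are
#' distinct samples and are held out separately. Every fold asserts that no
#' held-out cell entered its training set.
#'
#' @param X cells x features matrix (e.g. from [build_feature_matrix()]).
#' @param y per-cell response labels.
#' @param sample_ids per-cell sample ids defining the outer folds.
#' @param config an [cv_config()].
#' @return object of class `icisig_cv_result`: `cell_predictions`
#'   (data.frame with truth, predicted label and class probabilities),
#'   `sample_calls` (per-sample majority call and correctness),
#'   `chosen` (per-fold alpha/lambda), `coef_contrast` (features x folds;
#'   for two classes, coefficient of the second level minus the first),
#'   `coef_per_class` (list of per-fold features x classes matrices),
#'   `balanced_accuracy`, `classes`, `skipped_folds`, `leakage_checked`.
#' @export
loso_cv <- function(X, y, sample_ids, config = cv_config()) {
  X <- as.matrix(X)
  y <- as.factor(y)
  sample_ids <- as.character(sample_ids)
  samples <- sort(unique(sample_ids))
  if (length(samples) < 3) stop_cfg("need >= 3 samples for outer folds")
  if (nlevels(y) < 2) stop_cfg("need >= 2 response classes")
  n_per_sample <- table(sample_ids)
  small <- names(n_per_sample)[n_per_sample < config$min_cells_per_sample]
  if (length(small)) {
    warning("excluding sample(s) with too few cells: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !sample_ids %in% small
    X <- X[keep, , drop = FALSE]; y <- droplevels(y[keep])
    sample_ids <- sample_ids[keep]
    samples <- setdiff(samples, small)
  }

  cells <- list(); calls <- list(); chosen <- list()
  contrast <- list(); per_class <- list(); skipped <- character()
  for (fi in seq_along(samples)) {
    s <- samples[fi]
    test_idx <- which(sample_ids == s)
    train_idx <- which(sample_ids != s)
    stopifnot(length(intersect(train_idx, test_idx)) == 0) # leakage guard
    ytr <- droplevels(y[train_idx])
    if (nlevels(ytr) < 2) {
      warning("fold ", s, " skipped: training set has one class",
              call. = FALSE)
      skipped <- c(skipped, s)
      next
    }
    if (config$balancing) {
      bal <- balance_cells(y[train_idx], seed = config$seed + fi)
      train_idx <- train_idx[bal]
      ytr <- droplevels(y[train_idx])
    }
    stopifnot(length(intersect(train_idx, test_idx)) == 0)
    Xtr <- X[train_idx, , drop = FALSE]

    foldid <- with_seed(config$seed * 131L + fi, {
      f <- integer(length(ytr))
      for (l in levels(ytr)) {
        i <- which(ytr == l)
        f[i] <- sample(rep_len(seq_len(config$inner_folds), length(i)))
      }
      f
    })
    best <- NULL
    for (a in config$alpha_grid) {
      cv <- glmnet::cv.glmnet(Xtr, ytr, family = "multinomial", alpha = a,
                              foldid = foldid, nlambda = config$nlambda,
                              type.measure = "deviance")
      lam <- if (config$lambda_rule == "min") cv$lambda.min else cv$lambda.1se
      dev <- cv$cvm[match(lam, cv$lambda)]
      if (is.null(best) || dev < best$dev) {
        best <- list(alpha = a, lambda = lam, dev = dev, cv = cv)
      }
    }
    p3 <- predict(best$cv, newx = X[test_idx, , drop = FALSE],
                  s = best$lambda, type = "response")
    prob <- matrix(p3, nrow = dim(p3)[1],
                   dimnames = list(NULL, dimnames(p3)[[2]]))
    pred <- colnames(prob)[max.col(prob, ties.method = "first")]

    cf <- glmnet::coef.glmnet(best$cv, s = best$lambda)
    cmat <- vapply(cf, function(v) as.numeric(v)[-1], numeric(ncol(X)))
    rownames(cmat) <- colnames(X)
    per_class[[s]] <- cmat
    if (nlevels(ytr) == 2) {
      contrast[[s]] <- cmat[, 2] - cmat[, 1]
    }
    chosen[[s]] <- data.frame(sample_id = s, alpha = best$alpha,
                              lambda = best$lambda,
                              inner_deviance = best$dev,
                              stringsAsFactors = FALSE)
    cells[[s]] <- data.frame(
      cell = test_idx, sample_id = s, truth = as.character(y[test_idx]),
      predicted = pred, prob,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    calls[[s]] <- cbind(sample_id = s,
                        sample_call(pred, as.character(y[test_idx])[1]))
  }
  cell_predictions <- do.call(rbind, cells)
  rownames(cell_predictions) <- NULL
  sample_calls <- do.call(rbind, calls)
  rownames(sample_calls) <- NULL
  structure(
    list(cell_predictions = cell_predictions, sample_calls = sample_calls,
         chosen = do.call(rbind, chosen),
         coef_contrast = if (length(contrast)) do.call(cbind, contrast),
         coef_per_class = per_class,
         balanced_accuracy = balanced_accuracy(cell_predictions$truth,
                                               cell_predictions$predicted),
         classes = levels(y), skipped_folds = skipped,
         leakage_checked = TRUE),
    class = "icisig_cv_result"
  )
}

#' @export
print.icisig_cv_result <- function(x, ...) {
  cat(sprintf("leave-one-sample-out CV: %d folds, %d cells\n",
              nrow(x$sample_calls), nrow(x$cell_predictions)))
  cat(sprintf("  per-cell balanced accuracy: %.3f\n", x$balanced_accuracy))
  cat(sprintf("  per-sample accuracy: %.3f (%d/%d)\n",
              mean(x$sample_calls$correct), sum(x$sample_calls$correct),
              nrow(x$sample_calls)))
  invisible(x)
}

#' Majority-vote sample call from per-cell predictions
#'
#' The sample-level prediction is the modal per-cell label; the sample
#' counts as correctly predicted only when the true label is assigned to
#' strictly more than 50% of its cells (exactly half is incorrect).
#'
#' @param predictions per-cell predicted labels of one sample.
#' @param truth the sample's true label.
#' @return one-row data.frame: `predicted`, `prop_true_label`, `correct`.
#' @export
sample_call <- function(predictions, truth) {
  if (!length(predictions)) stop_cfg("need >= 1 predicted cell")
  tab <- table(predictions)
  modal <- names(tab)[which.max(tab)]
  prop <- mean(predictions == truth)
  data.frame(predicted = modal, prop_true_label = prop,
             correct = prop > 0.5, stringsAsFactors = FALSE)
}

#' Balanced accuracy
#'
#' Mean of per-class recalls over the classes present in the truth.
#'
#' @param truth,predictions label vectors of equal length.
#' @return value in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, predictions) {
  truth <- as.character(truth); predictions <- as.character(predictions)
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    mean(predictions[truth == cl] == cl)
  }, numeric(1)))
}

#' Integrate per-fold coefficients into a response signature
#'
#' Features robust to training-set changes are those with a non-zero median
#' coefficient across the leave-one-sample-out folds. For two classes the
#' per-fold coefficient is the class contrast (second level minus first),
#' so after rescaling by the maximum absolute median, +1 marks the feature
#' most associated with the second group and -1 the feature most associated
#' with the first.
#'
#' @param cv an `icisig_cv_result` from [loso_cv()] (>= 3 folds), or a
#'   features x folds coefficient matrix.
#' @return data.frame of class `icisig_signature`: `feature`, `modality`,
#'   `median_coef`, `coefficient` (rescaled to \[-1, 1\]), `direction`
#'   (class label the feature points to). Empty, with a warning, when all
#'   medians are zero.
#' @export
integrate_coefficients <- function(cv) {
  if (inherits(cv, "icisig_cv_result")) {
    mat <- cv$coef_contrast
    classes <- cv$classes
    if (is.null(mat)) stop_cfg("class contrast requires a two-class model; ",
                               "use `coef_per_class` directly")
  } else {
    mat <- as.matrix(cv)
    classes <- c("class1", "class2")
  }
  if (ncol(mat) < 3) stop_cfg("need >= 3 folds to integrate coefficients")
  med <- apply(mat, 1, median)
  keep <- med != 0
  if (!any(keep)) {
    warning("all median coefficients are zero: empty signature",
            call. = FALSE)
  }
  med <- med[keep]
  feats <- names(med)
  modality <- ifelse(startsWith(feats, "ADT:"), "ADT",
                     ifelse(startsWith(feats, "RNA:"), "RNA", "unknown"))
  scale <- if (length(med)) max(abs(med)) else 1
  out <- data.frame(
    feature = sub("^(RNA|ADT):", "", feats), modality = modality,
    median_coef = unname(med), coefficient = unname(med) / scale,
    direction = ifelse(med > 0, classes[2], classes[1]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-abs(out$coefficient)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("icisig_signature", "data.frame")
  out
}
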