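#' Module-score configuration
#'
#' @param n_bins number of equal-frequency average-expression bins from
#'   which control genes are drawn (default 25).
#' @param n_ctrl control genes sampled per signature gene (default 100).
#' @param seed RNG seed for control-gene sampling.
#' @return list of class `icisig_module_config`.
#' @export
module_score_config <- function(n_bins = 25L, n_ctrl = 100L, seed = 1L) {
  if (!is_count(n_bins, 2L)) stop_cfg("need >= 2 expression bins")
  if (!is_count(n_ctrl, 1L)) stop_cfg("need >= 1 control gene per signature gene")
  structure(list(n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
                 seed = as.integer(seed)),
            class = "icisig_module_config")
}

#' Per-cell module score of a gene set
#'
#' Scores a signature in each cell as the mean expression of the signature
#' genes minus the mean expression of expression-matched control genes:
#' genes are binned by their average expression across cells
#' (equal-frequency bins) and each signature gene contributes `n_ctrl`
#' control genes sampled from its own bin. This transfers a learned
#' signature to any normalized cell x gene matrix without refitting.
#'
#' @param expr cells x genes normalized expression matrix.
#' @param genes signature gene names; genes absent from the matrix are
#'   dropped and reported via the `missing_genes` attribute (an empty
#'   intersection is an error).
#' @param config an [module_score_config()].
#' @return numeric vector of per-cell scores (named by cell), attribute
#'   `missing_genes`.
#' @export
module_score <- function(expr, genes, config = module_score_config()) {
  expr <- as.matrix(expr)
  present <- intersect(unique(genes), colnames(expr))
  missing <- setdiff(unique(genes), present)
  if (!length(present)) {
    stop_cfg("no signature gene found in the matrix; missing: ",
             paste(missing, collapse = ", "))
  }
  avg <- colMeans(expr)
  # equal-frequency bins over the full gene universe
  br <- quantile(avg, probs = seq(0, 1, length.out = config$n_bins + 1),
                 names = FALSE)
  bin <- cut(avg, breaks = unique(br), include.lowest = TRUE, labels = FALSE)
  names(bin) <- colnames(expr)
  ctrl <- with_seed(config$seed, {
    unlist(lapply(present, function(g) {
      pool <- names(bin)[bin == bin[[g]]]
      pool <- setdiff(pool, g)
      if (!length(pool)) return(character())
      sample(pool, config$n_ctrl, replace = length(pool) < config$n_ctrl)
    }))
  })
  score <- rowMeans(expr[, present, drop = FALSE]) -
    rowMeans(expr[, ctrl, drop = FALSE])
  attr(score, "missing_genes") <- missing
  score
}

#' Compare module scores between patient groups
#'
#' Welch two-sided t-test of per-cell scores, one baseline group against
#' each other group (e.g. complete response as baseline against progressive
#' disease and adverse-event groups).
#'
#' @param scores per-cell module scores.
#' @param groups per-cell group labels.
#' @param baseline baseline group label; defaults to the first level.
#' @return data.frame: `group`, `baseline`, `t`, `p_value`,
#'   `mean_group`, `mean_baseline`. Two groups with zero variance and
#'   equal means give p = 1.
#' @export
compare_scores <- function(scores, groups, baseline = NULL) {
  groups <- as.factor(groups)
  if (is.null(baseline)) baseline <- levels(groups)[1]
  if (!baseline %in% levels(groups)) stop_cfg("unknown baseline group")
  others <- setdiff(levels(groups), baseline)
  x0 <- scores[groups == baseline]
  rows <- lapply(others, function(g) {
    x1 <- scores[groups == g]
    if (length(x1) < 2 || length(x0) < 2) stop_cfg("need >= 2 cells per group")
    if (sd(x1) == 0 && sd(x0) == 0) {
      tstat <- if (mean(x1) == mean(x0)) 0 else Inf * sign(mean(x1) - mean(x0))
      p <- if (mean(x1) == mean(x0)) 1 else 0
    } else {
      tt <- t.test(x1, x0) # Welch by default
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(group = g, baseline = baseline, t = tstat, p_value = p,
               mean_group = mean(x1), mean_baseline = mean(x0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Negative-control module score from a random gene set
#'
#' Scores a randomly drawn gene set of the same size as the signature,
#' optionally on a random subset of cells. Serves as the calibration
#' control: group comparisons on these scores should be null.
#'
#' @param expr cells x genes normalized matrix.
#' @param size number of genes to draw (match the signature size).
#' @param config an [module_score_config()]; its seed controls both the
#'   gene draw and the control-gene sampling.
#' @param exclude genes excluded from the draw (conventionally the tested
#'   signature itself).
#' @param n_cells if non-`NULL`, score only this many randomly selected
#'   cells.
#' @return per-cell scores; attribute `gene_set` records the drawn genes.
#' @export
random_control_score <- function(expr, size, config = module_score_config(),
                                 exclude = NULL, n_cells = NULL) {
  universe <- setdiff(colnames(expr), exclude)
  if (size > length(universe)) stop_cfg("random set larger than universe")
  drawn <- with_seed(config$seed * 7L + 1L, sample(universe, size))
  if (!is.null(n_cells)) {
    if (n_cells > nrow(expr)) stop_cfg("n_cells exceeds available cells")
    rows <- with_seed(config$seed * 7L + 2L, sample(nrow(expr), n_cells))
    expr <- expr[rows, , drop = FALSE]
  }
  s <- module_score(expr, drawn, config)
  attr(s, "gene_set") <- drawn
  s
}
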