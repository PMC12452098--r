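#' Aggregate single-cell expression into pseudobulk profiles
#'
#' Averages expression per sample, either across all cells (`"ALL"` stratum)
#' or within cell-type strata, to avoid pseudo-replication when testing
#' between patient groups. The arithmetic mean is taken on whatever scale
#' the input matrix carries; for fold-change estimation the linear
#' (library-size normalized, unlogged) scale is used so a planted
#' multiplicative effect is recovered as the same fold change.
#'
#' @param expr cells x features matrix (normalized).
#' @param cell_meta per-cell metadata with `sample_id` and (for cell-type
#'   strata) a subset label column.
#' @param strata `"ALL"` and/or subset names to aggregate within.
#' @param subset_col name of the subset label column in `cell_meta`.
#' @param min_cells (stratum, sample) combinations with fewer cells are
#'   dropped with a warning.
#' @return object of class `icisig_pseudobulk`: per stratum a list with
#'   `mean` (samples x features) and `n_cells`.
#' @export
pseudobulk <- function(expr, cell_meta, strata = "ALL",
                       subset_col = "true_subset", min_cells = 10) {
  known <- c("ALL", unique(as.character(cell_meta[[subset_col]])))
  bad <- setdiff(strata, known)
  if (length(bad)) stop_cfg("unknown stratum: ", paste(bad, collapse = ", "))
  out <- lapply(setNames(strata, strata), function(st) {
    in_st <- if (st == "ALL") rep(TRUE, nrow(cell_meta))
             else cell_meta[[subset_col]] == st
    sid <- cell_meta$sample_id[in_st]
    n <- table(sid)
    keep_samples <- names(n)[n >= min_cells]
    dropped <- setdiff(names(n), keep_samples)
    if (length(dropped)) {
      warning(sprintf("stratum %s: dropping %d sample(s) with < %d cells",
                      st, length(dropped), min_cells), call. = FALSE)
    }
    m <- rowsum(as.matrix(expr[in_st, , drop = FALSE])[
      sid %in% keep_samples, , drop = FALSE],
      group = sid[sid %in% keep_samples])
    m <- m / as.vector(n[rownames(m)])
    list(mean = m, n_cells = setNames(as.integer(n[rownames(m)]), rownames(m)))
  })
  structure(out, class = "icisig_pseudobulk")
}

#' Remove V(D)J segment genes from a feature list
#'
#' TCR/immunoglobulin variable, diversity and joining segment genes reflect
#' patient-specific repertoires rather than regulation, and are excluded
#' before differential expression.
#'
#' @param features character vector of gene names.
#' @return `features` without V(D)J segment genes.
#' @export
exclude_vdj_features <- function(features) {
  prefixes <- c("TRAV", "TRAJ", "TRBV", "TRBD", "TRBJ", "TRGV", "TRGJ",
                "TRDV", "TRDD", "TRDJ", "IGHV", "IGHD", "IGHJ", "IGKV",
                "IGKJ", "IGLV", "IGLJ")
  hit <- Reduce(`|`, lapply(prefixes, function(p) startsWith(features, p)))
  features[!hit]
}

#' Group differential expression on pseudobulk profiles
#'
#' Two-sided Wilcoxon rank-sum test per feature on the per-sample pseudobulk
#' means of the two groups, with `log2FC = log2((mean1 + eps) / (mean2 +
#' eps))` where group 1 is the first level of `sample_groups`.
#'
#' @param pb an [pseudobulk()] object.
#' @param sample_groups named vector sample_id -> group.
#' @param pseudocount `eps` keeping fold changes of zero-mean features
#'   finite.
#' @param modality label recorded in the result (`"RNA"` or `"ADT"`).
#' @return data.frame: `feature`, `stratum`, `modality`, `log2fc`,
#'   `p_value`. Strata with fewer than two samples in either group are
#'   skipped with a warning.
#' @export
de_test <- function(pb, sample_groups, pseudocount = 1e-9,
                    modality = "RNA") {
  stopifnot(inherits(pb, "icisig_pseudobulk"))
  lev <- unique(as.character(sample_groups))
  if (length(lev) != 2) stop_cfg("exactly two groups are required")
  res <- lapply(names(pb), function(st) {
    m <- pb[[st]]$mean
    g <- as.character(sample_groups[rownames(m)])
    if (sum(g == lev[1], na.rm = TRUE) < 2 ||
        sum(g == lev[2], na.rm = TRUE) < 2) {
      warning("stratum ", st, " skipped: need >= 2 samples per group",
              call. = FALSE)
      return(NULL)
    }
    i1 <- which(g == lev[1]); i2 <- which(g == lev[2])
    p <- apply(m, 2, function(v) wilcox_p(v[i1], v[i2]))
    # NaN (negative means on z-scored modalities) is propagated silently and
    # treated as non-selectable downstream
    lfc <- suppressWarnings(
      log2((colMeans(m[i1, , drop = FALSE]) + pseudocount) /
             (colMeans(m[i2, , drop = FALSE]) + pseudocount)))
    data.frame(feature = colnames(m), stratum = st, modality = modality,
               log2fc = as.numeric(lfc), p_value = as.numeric(p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "groups") <- lev
  out
}

#' Select differential features at the strict or lenient cutoff
#'
#' Strict (`p < 0.05` and `|log2FC| >= 0.5`) defines reported markers;
#' lenient (`p < 0.1` and `|log2FC| >= 0.2`) defines the candidate feature
#' pool for classification, deliberately permissive so features that only
#' help in combination are not excluded.
#'
#' @param de data.frame from [de_test()].
#' @param mode `"strict"` or `"lenient"`.
#' @return the selected rows of `de`.
#' @export
select_features <- function(de, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  keep <- if (mode == "strict") {
    de$p_value < 0.05 & abs(de$log2fc) >= 0.5
  } else {
    de$p_value < 0.1 & abs(de$log2fc) >= 0.2
  }
  keep[is.na(keep)] <- FALSE # undefined fold change (e.g. negative means)
  de[keep, , drop = FALSE]
}
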