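#' Define a marker panel for subset or state assignment
#'
#' A panel maps each label to positive markers (expected high) and optional
#' negative markers (expected low). Markers may be genes or surface markers;
#' both are looked up by name in the matrices given to
#' [score_cell_labels()].
#'
#' @param x named list: label -> list(positive = character,
#'   negative = character (optional)).
#' @return validated panel of class `icisig_marker_panel`.
#' @export
marker_panel <- function(x) {
  if (!length(x) || is.null(names(x)) || anyDuplicated(names(x))) {
    stop_cfg("panel must be a non-empty, uniquely named list")
  }
  x <- lapply(x, function(e) {
    if (is.character(e)) e <- list(positive = e)
    if (is.null(e$positive) || !length(e$positive)) {
      stop_cfg("every label needs at least one positive marker")
    }
    list(positive = e$positive,
         negative = if (is.null(e$negative)) character() else e$negative)
  })
  structure(x, class = "icisig_marker_panel")
}

#' Score and assign cell labels from a marker panel
#'
#' For each cell and label, score = mean of the label's positive-marker
#' normalized values minus mean of its negative-marker values; the assigned
#' label is the argmax. Exact ties are resolved to the lexicographically
#' smallest label and flagged.
#'
#' @param rna_norm cells x genes normalized matrix (may be `NULL` if the
#'   panel is ADT-only).
#' @param adt_norm cells x markers normalized matrix (may be `NULL`).
#' @param panel an [marker_panel()].
#' @return data.frame: `cell_id`, `label`, `score`, `tie`.
#' @export
score_cell_labels <- function(rna_norm, adt_norm, panel) {
  panel <- if (inherits(panel, "icisig_marker_panel")) panel
           else marker_panel(panel)
  lookup <- function(markers) {
    cols <- lapply(markers, function(m) {
      if (!is.null(rna_norm) && m %in% colnames(rna_norm)) rna_norm[, m]
      else if (!is.null(adt_norm) && m %in% colnames(adt_norm)) adt_norm[, m]
      else stop_cfg("marker `", m, "` absent from the dataset features")
    })
    do.call(cbind, cols)
  }
  n_cells <- nrow(if (!is.null(rna_norm)) rna_norm else adt_norm)
  scores <- vapply(panel, function(e) {
    s <- rowMeans(lookup(e$positive))
    if (length(e$negative)) s <- s - rowMeans(lookup(e$negative))
    s
  }, numeric(n_cells))
  scores <- matrix(scores, nrow = n_cells,
                   dimnames = list(rownames(if (!is.null(rna_norm)) rna_norm
                                            else adt_norm), names(panel)))
  labels <- names(panel)
  ord <- order(labels) # lexicographic tie-break via which.max on sorted cols
  scores_sorted <- scores[, ord, drop = FALSE]
  best <- apply(scores_sorted, 1, which.max)
  maxscore <- scores_sorted[cbind(seq_along(best), best)]
  tie <- rowSums(scores_sorted == maxscore) > 1
  ids <- rownames(scores)
  if (is.null(ids)) ids <- sprintf("cell%d", seq_along(best))
  data.frame(cell_id = ids, label = labels[ord][best], score = maxscore,
             tie = tie, stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample label composition
#'
#' @param labels character vector of per-cell labels (order matching
#'   `cell_meta`), or the data.frame returned by [score_cell_labels()].
#' @param cell_meta per-cell metadata with a `sample_id` column.
#' @return matrix sample x label of within-sample fractions; rows sum to 1.
#'   Samples without cells are excluded with a warning.
#' @export
proportions_per_sample <- function(labels, cell_meta) {
  if (is.data.frame(labels)) labels <- labels$label
  if (length(labels) != nrow(cell_meta)) {
    stop_cfg("one label per cell is required")
  }
  keep <- !is.na(cell_meta$sample_id)
  if (any(!keep)) warning("cells without sample_id excluded", call. = FALSE)
  tab <- table(sample_id = cell_meta$sample_id[keep], label = labels[keep])
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("sample(s) with zero cells excluded: ",
            paste(rownames(tab)[empty], collapse = ", "), call. = FALSE)
    tab <- tab[!empty, , drop = FALSE]
  }
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  prop
}

#' Compare per-sample composition between response groups
#'
#' Two-sided Wilcoxon rank-sum test per label on the per-sample fractions,
#' reported with the direction of the difference. No multiple-testing
#' correction is applied: composition trends are read at face value on the
#' raw p-values.
#'
#' @param props sample x label proportion matrix from
#'   [proportions_per_sample()].
#' @param sample_groups named character/factor vector: sample_id -> group
#'   (exactly two groups, >= 2 samples each).
#' @return data.frame: `label`, `p_value`, `direction` (group with the
#'   larger median fraction, or `"none"`), `median_group1`, `median_group2`.
#' @export
compare_proportions <- function(props, sample_groups) {
  g <- sample_groups[rownames(props)]
  if (any(is.na(g))) stop_cfg("every sample needs a group assignment")
  lev <- unique(as.character(g))
  if (length(lev) != 2) stop_cfg("exactly two groups are required")
  if (min(table(g)) < 2) stop_cfg("need >= 2 samples per group")
  res <- lapply(colnames(props), function(lab) {
    x <- props[g == lev[1], lab]
    y <- props[g == lev[2], lab]
    p <- wilcox_p(x, y)
    m1 <- median(x); m2 <- median(y)
    dir <- if (m1 > m2) lev[1] else if (m2 > m1) lev[2] else "none"
    data.frame(label = lab, p_value = p, direction = dir,
               median_group1 = m1, median_group2 = m2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "groups") <- lev
  out
}

# Two-sided rank-sum p: exact distribution for small tie-free samples,
# normal approximation with tie correction otherwise; identical data -> 1.
wilcox_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1) return(1)
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}
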