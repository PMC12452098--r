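#' Per-cell quality-control metrics
#'
#' Computes the five QC metrics used to filter cells: the number of detected
#' genes (NODG), the number of UMIs (NUMI), the percentage of UMIs on
#' mitochondrial (pMito) and ribosomal (pRibo) genes, and the number of
#' detected proteins (NODP), defined as log10 of the summed ADT counts per
#' cell, isotype controls included.
#'
#' Cells with zero total UMIs have undefined pMito/pRibo and cells with zero
#' total ADT counts have undefined NODP; these are reported as `NA` and fail
#' the corresponding filter rather than raising an error.
#'
#' @param gene_counts cells x genes count matrix (dense or sparse).
#' @param adt_counts cells x markers count matrix (same cell order).
#' @param mito_prefix prefix identifying mitochondrial genes.
#' @param ribo_prefixes prefixes identifying ribosomal genes.
#' @return data.frame with one row per cell: `cell_id`, `nodg`, `numi`,
#'   `pmito`, `pribo` (percent), `nodp`.
#' @export
compute_qc_metrics <- function(gene_counts, adt_counts,
                               mito_prefix = "MT-",
                               ribo_prefixes = c("RPS", "RPL")) {
  if (nrow(gene_counts) != nrow(adt_counts)) {
    stop_cfg("gene and ADT matrices must share the cell axis")
  }
  if (!nzchar(mito_prefix) || !length(ribo_prefixes)) {
    stop_cfg("prefix sets must be non-empty")
  }
  genes <- colnames(gene_counts)
  mito <- startsWith(genes, mito_prefix)
  ribo <- Reduce(`|`, lapply(ribo_prefixes, function(p) startsWith(genes, p)))
  numi <- Matrix::rowSums(gene_counts)
  nodg <- Matrix::rowSums(gene_counts > 0)
  pmito <- ifelse(numi > 0,
                  100 * Matrix::rowSums(gene_counts[, mito, drop = FALSE]) / numi,
                  NA_real_)
  pribo <- ifelse(numi > 0,
                  100 * Matrix::rowSums(gene_counts[, ribo, drop = FALSE]) / numi,
                  NA_real_)
  adt_total <- Matrix::rowSums(adt_counts)
  nodp <- ifelse(adt_total > 0, log10(adt_total), NA_real_)
  ids <- rownames(gene_counts)
  if (is.null(ids)) ids <- sprintf("cell%d", seq_along(numi))
  data.frame(cell_id = ids, nodg = as.numeric(nodg), numi = as.numeric(numi),
             pmito = pmito, pribo = pribo, nodp = nodp,
             stringsAsFactors = FALSE)
}

#' QC thresholds
#'
#' `default_qc_thresholds()` returns the stringent thresholds used for blood
#' CD8+ T-cell CITE-seq data: NODG in \[340, 2500\], NUMI in \[500, 7000\],
#' pMito in \[0, 6\]%, pRibo in \[18, 55\]% and NODP strictly greater
#' than 2.75. Two-sided ranges are closed intervals (a cell at the bound
#' passes); the NODP bound is strict.
#'
#' @param lower_inclusive logical, whether finite lower bounds of two-sided
#'   ranges are inclusive (the default convention).
#' @return data.frame with columns `metric`, `lower`, `upper`,
#'   `lower_inclusive`, `upper_inclusive`.
#' @export
default_qc_thresholds <- function(lower_inclusive = TRUE) {
  data.frame(
    metric = c("nodg", "numi", "pmito", "pribo", "nodp"),
    lower = c(340, 500, 0, 18, 2.75),
    upper = c(2500, 7000, 6, 55, Inf),
    lower_inclusive = c(rep(lower_inclusive, 4), FALSE),
    upper_inclusive = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Data-driven QC thresholds from pairwise metric densities
#'
#' Derives per-metric cutoffs from the density structure of pairs of QC
#' metrics. For each metric of each pair, a Gaussian kernel density
#' (Silverman bandwidth) of the marginal is computed; if the density is
#' multimodal, the candidate cutoff is the deepest valley between the two
#' highest modes, assigned as a lower or upper bound depending on which side
#' of the main mode it falls. When several pairs propose different values
#' for the same metric, the more stringent (narrower) value is kept. For a
#' unimodal marginal with no valley the bounds fall back to the 1%/99%
#' quantiles, with a warning.
#'
#' @param metrics data.frame from [compute_qc_metrics()] (>= 200 cells).
#' @param metric_pairs list of length-2 character vectors naming metric
#'   columns to contrast.
#' @return thresholds data.frame as in [default_qc_thresholds()], restricted
#'   to the metrics appearing in `metric_pairs`.
#' @export
auto_qc_thresholds <- function(metrics,
                               metric_pairs = list(c("nodg", "numi"),
                                                   c("pmito", "pribo"),
                                                   c("nodg", "nodp"))) {
  if (nrow(metrics) < 200) stop_cfg("auto thresholds need at least 200 cells")
  for (p in metric_pairs) {
    if (length(p) != 2 || p[1] == p[2]) {
      stop_cfg("metric pairs must contrast two distinct metrics")
    }
    if (!all(p %in% names(metrics))) stop_cfg("unknown metric in pair")
  }
  wanted <- unique(unlist(metric_pairs))
  res <- lapply(setNames(wanted, wanted), function(m) {
    votes <- lapply(metric_pairs, function(p) {
      if (m %in% p) marginal_cutoffs(metrics[[m]]) else NULL
    })
    combine_cutoff_votes(Filter(Negate(is.null), votes))
  })
  data.frame(
    metric = wanted,
    lower = vapply(res, `[[`, numeric(1), "lower"),
    upper = vapply(res, `[[`, numeric(1), "upper"),
    lower_inclusive = TRUE, upper_inclusive = TRUE,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# When pairs propose different cutoffs for one metric, the more stringent
# (narrower) value wins: highest lower bound, lowest upper bound.
combine_cutoff_votes <- function(votes) {
  c(lower = max(vapply(votes, `[[`, numeric(1), "lower")),
    upper = min(vapply(votes, `[[`, numeric(1), "upper")))
}

# Valley detection on one metric's marginal density.
marginal_cutoffs <- function(x) {
  x <- x[is.finite(x)]
  d <- density(x, bw = "nrd0")
  dy <- diff(d$y)
  peaks <- which(diff(sign(dy)) == -2) + 1L
  if (length(peaks) < 2) {
    warning("unimodal marginal: falling back to quantile bounds",
            call. = FALSE)
    q <- quantile(x, c(0.01, 0.99), names = FALSE)
    return(list(lower = q[1], upper = q[2]))
  }
  peaks <- peaks[order(d$y[peaks], decreasing = TRUE)][1:2]
  lo <- min(peaks); hi <- max(peaks)
  valley <- d$x[(lo:hi)[which.min(d$y[lo:hi])]]
  # the main population is the side of the valley holding more cells; the
  # minor mode on the other side is cut away
  if (mean(x > valley) >= 0.5) list(lower = valley, upper = Inf)
  else list(lower = -Inf, upper = valley)
}

#' Filter cells on QC thresholds
#'
#' A cell passes iff every metric lies within its bounds; `NA` metrics fail.
#'
#' @param metrics data.frame from [compute_qc_metrics()].
#' @param thresholds thresholds data.frame.
#' @return logical vector, one element per cell, named by `cell_id`.
#' @export
filter_cells <- function(metrics, thresholds) {
  pass <- rep(TRUE, nrow(metrics))
  for (i in seq_len(nrow(thresholds))) {
    t <- thresholds[i, ]
    x <- metrics[[t$metric]]
    if (is.null(x)) stop_cfg("metric `", t$metric, "` missing from metrics")
    lo_ok <- if (t$lower_inclusive) x >= t$lower else x > t$lower
    hi_ok <- if (t$upper_inclusive) x <= t$upper else x < t$upper
    ok <- lo_ok & hi_ok
    ok[is.na(ok)] <- FALSE
    pass <- pass & ok
  }
  names(pass) <- metrics$cell_id
  pass
}

#' Per-cell QC report
#'
#' @inheritParams filter_cells
#' @return `metrics` with appended `pass` and `fail_reasons` columns.
#' @export
qc_report <- function(metrics, thresholds) {
  reasons <- vapply(seq_len(nrow(metrics)), function(i) {
    bad <- character()
    for (j in seq_len(nrow(thresholds))) {
      t <- thresholds[j, ]
      x <- metrics[[t$metric]][i]
      lo_ok <- if (t$lower_inclusive) x >= t$lower else x > t$lower
      hi_ok <- if (t$upper_inclusive) x <= t$upper else x < t$upper
      if (is.na(lo_ok) || is.na(hi_ok) || !lo_ok || !hi_ok) {
        bad <- c(bad, t$metric)
      }
    }
    paste(bad, collapse = ";")
  }, character(1))
  out <- metrics
  out$pass <- unname(filter_cells(metrics, thresholds))
  out$fail_reasons <- reasons
  out
}

#' Normalize RNA counts
#'
#' Library-size normalization to `scale_factor` counts per cell, optionally
#' log-transformed: `log(1 + count / cell_total * scale_factor)` (natural
#' log), the standard log-normalization of single-cell toolkits. The linear
#' variant (`log = FALSE`) is used when averaging expression into pseudobulk
#' profiles, so that group fold changes stay on the count scale.
#'
#' @param counts cells x genes count matrix.
#' @param scale_factor target library size (default 10,000).
#' @param log apply `log1p` after scaling.
#' @return matrix of the same shape (dense).
#' @export
normalize_rna <- function(counts, scale_factor = 1e4, log = TRUE) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    stop_cfg("cells with zero total counts must be filtered before ",
             "normalization")
  }
  out <- as.matrix(counts) / totals * scale_factor
  if (log) out <- log1p(out)
  out
}

#' Denoise and normalize ADT counts against an ambient background
#'
#' Each marker is z-scored against its distribution in ambient background
#' barcodes (empty droplets); afterwards each cell's mean isotype-control
#' z-score — an estimate of that cell's technical staining component — is
#' subtracted from all of its markers. This retains the two central ideas of
#' background-anchored ADT denoising (ambient correction and removal of
#' per-cell technical noise) in a transparent closed form.
#'
#' @param adt_counts cells x markers count matrix, isotype controls included.
#' @param isotype_names marker names of the isotype controls (>= 1).
#' @param background ambient-only barcodes x markers matrix. If `NULL`, the
#'   cells in the lowest decile of total ADT counts are used as background,
#'   with a warning.
#' @return matrix of denoised values, same shape as `adt_counts`.
#' @export
normalize_adt <- function(adt_counts, isotype_names, background = NULL) {
  adt_counts <- as.matrix(adt_counts)
  if (!length(isotype_names) || !all(isotype_names %in% colnames(adt_counts))) {
    stop_cfg("isotype controls must name columns of `adt_counts`")
  }
  if (is.null(background)) {
    warning("no ambient background supplied; using lowest-decile cells",
            call. = FALSE)
    tot <- rowSums(adt_counts)
    background <- adt_counts[tot <= quantile(tot, 0.1), , drop = FALSE]
  }
  background <- as.matrix(background)[, colnames(adt_counts), drop = FALSE]
  mu <- colMeans(background)
  sdev <- apply(background, 2, sd)
  low <- sdev < 1e-8
  if (any(low)) {
    warning("zero background variance for marker(s): ",
            paste(colnames(adt_counts)[low], collapse = ", "),
            "; flooring sd at 1e-8", call. = FALSE)
    sdev[low] <- 1e-8
  }
  z <- sweep(sweep(adt_counts, 2, mu), 2, sdev, "/")
  tech <- rowMeans(z[, isotype_names, drop = FALSE])
  z - tech
}
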