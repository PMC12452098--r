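#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` that at least `k` of the `n` genes of
#' interest are annotated to a set, when `M` of the `N` background genes
#' carry the annotation — equivalent to a one-sided Fisher's exact test on
#' the 2x2 table.
#'
#' @param N background size. @param M annotated genes in the background.
#' @param n interest-list size. @param k annotated genes in the interest
#'   list.
#' @return the exact upper-tail p-value.
#' @export
hypergeom_enrichment <- function(N, M, n, k) {
  if (M > N || n > N) stop_cfg("M and n must not exceed N")
  if (k > min(M, n)) stop_cfg("k cannot exceed min(M, n)")
  if (k < 0 || M < 0 || n < 0) stop_cfg("counts must be nonnegative")
  phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin, name-stable wrapper
#' around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_cfg("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set for over-representation in a gene list of interest
#' against a background universe, with BH correction across sets.
#'
#' @param genes character vector of genes of interest.
#' @param background character vector, the gene universe.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame: `set`, `N`, `M`, `n`, `k`, `p_value`, `p_adjusted`,
#'   ordered by p-value.
#' @export
enrich_gene_sets <- function(genes, background, gene_sets) {
  genes <- intersect(unique(genes), background)
  N <- length(unique(background))
  n <- length(genes)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(unique(gene_sets[[s]]), background)
    M <- length(set)
    k <- length(intersect(genes, set))
    data.frame(set = s, N = N, M = M, n = n, k = k,
               p_value = hypergeom_enrichment(N, M, n, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Read or write gene sets in GMT format
#'
#' @param path file path. Each GMT line is `name<TAB>description<TAB>genes...`.
#' @param gene_sets named list of character vectors.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(s) {
    paste(c(s, s, gene_sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
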