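#' Write a dataset to disk in 10x-style plain-text formats
#'
#' Writes the RNA and ADT count matrices as MatrixMarket triplets with
#' `features.tsv`/`barcodes.tsv` sidecars (10x convention, uncompressed),
#' the TCR records as an AIRR rearrangement-style TSV and the per-cell
#' metadata as CSV.
#'
#' @param ds an `icisig_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly. `read_dataset()` returns a list with the same
#'   core slots (`gene_counts`, `adt_counts`, `cell_meta`, `tcr`); simulation
#'   truth is not serialized.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "icisig_dataset"))
  for (sub in c("rna", "adt")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  write_mtx_triplet(ds$gene_counts, file.path(dir, "rna"))
  write_mtx_triplet(ds$adt_counts, file.path(dir, "adt"))
  utils::write.table(ds$tcr, file.path(dir, "tcr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(ds$cell_meta, file.path(dir, "cell_meta.csv"),
                   row.names = FALSE)
  writeLines(ds$isotype_names, file.path(dir, "isotype_controls.txt"))
  invisible(dir)
}

# cells are columns in the 10x convention; our matrices are cells x features
write_mtx_triplet <- function(mat, dir) {
  m <- Matrix::Matrix(t(as.matrix(mat)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(id = rownames(m), name = rownames(m)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  gene <- read_mtx_triplet(file.path(dir, "rna"))
  adt <- as.matrix(read_mtx_triplet(file.path(dir, "adt")))
  tcr <- utils::read.delim(file.path(dir, "tcr.tsv"),
                           stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(dir, "cell_meta.csv"),
                          stringsAsFactors = FALSE)
  iso_file <- file.path(dir, "isotype_controls.txt")
  iso <- if (file.exists(iso_file)) readLines(iso_file) else character()
  structure(
    list(gene_counts = gene, adt_counts = adt, adt_background = NULL,
         cell_meta = meta, tcr = tcr, isotype_names = iso, truth = NULL,
         config = NULL),
    class = "icisig_dataset"
  )
}

read_mtx_triplet <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)
  rownames(m) <- feats[[1]]
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  Matrix::t(m)
}
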