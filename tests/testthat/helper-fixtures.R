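# Small in-code fixtures shared by the tests.

# A tiny SingleCellExperiment with known counts; genes x cells.
tiny_sce <- function(counts = NULL, genes = NULL, cells = NULL,
                     species = "mouse") {
  if (is.null(counts)) {
    counts <- matrix(c(1, 2, 5,
                       0, 0, 7), nrow = 3,
                     dimnames = list(c("Irf3", "Tbk1", "Actb"),
                                     c("c1", "c2")))
  }
  if (!is.null(genes)) rownames(counts) <- genes
  if (!is.null(cells)) colnames(counts) <- cells
  coactivate:::.makeSCE(methods::as(counts, "CsparseMatrix"),
                        species = species)
}

# Fast small synthetic config for tests.
small_cfg <- function(...) {
  syntheticConfig(nCells = 300, nGenes = 120, ...)
}

write_tiny_mtx <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "4 3 5",
               "1 1 2", "2 1 1", "3 2 4", "4 3 1", "1 3 3"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("Kdr", "Flt1", "Pecam1", "Actb"),
             file.path(dir, "features.tsv"))
  writeLines(c("b1", "b2", "b3"), file.path(dir, "barcodes.tsv"))
  dir
}
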