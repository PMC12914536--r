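#' @importFrom Matrix readMM writeMM colSums rowSums t sparseMatrix
#' @importFrom SummarizedExperiment assay assay<- assayNames rowData colData
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

# Internal constructor shared by readers and the simulator.
.makeSCE <- function(counts, cellMeta = NULL, species = "mouse") {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(cellMeta))
    cellMeta <- S4Vectors::DataFrame(row.names = colnames(counts))
  canonical <- as.character(harmonizeGenes(rownames(counts), species, species))
  if (anyDuplicated(canonical)) {
    # alias collapse merged two symbols (e.g. Tmem173 + Sting1): keep the
    # row with the larger total count, report the drop
    totals <- Matrix::rowSums(counts)
    keep <- !logical(nrow(counts))
    for (sym in unique(canonical[duplicated(canonical)])) {
      rows <- which(canonical == sym)
      drop <- rows[-which.max(totals[rows])]
      keep[drop] <- FALSE
      message(sprintf("duplicate canonical symbol '%s': dropping row(s) %s (lower total count)",
                      sym, paste(rownames(counts)[drop], collapse = ", ")))
    }
    counts <- counts[keep, , drop = FALSE]
    canonical <- canonical[keep]
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = cellMeta,
    rowData = S4Vectors::DataFrame(symbol = rownames(counts),
                                   canonical = canonical,
                                   species = species,
                                   row.names = rownames(counts)))
  sce
}

.validateCounts <- function(x, what = "counts") {
  v <- if (methods::is(x, "sparseMatrix")) x@x else as.numeric(x)
  bad <- which(!is.finite(v) | v < 0 | v != round(v))
  if (length(bad)) {
    # report matrix coordinates of the first offender
    if (methods::is(x, "sparseMatrix")) {
      trip <- methods::as(x, "TsparseMatrix")
      i <- trip@i[bad[1L]] + 1L; j <- trip@j[bad[1L]] + 1L
      val <- trip@x[bad[1L]]
    } else {
      idx <- which(!is.finite(x) | x < 0 | x != round(x), arr.ind = TRUE)[1L, ]
      i <- idx[1L]; j <- idx[2L]; val <- x[i, j]
    }
    stop(sprintf("invalid %s value %g at (row %d, col %d): entries must be finite, non-negative integers",
                 what, val, i, j))
  }
  invisible(TRUE)
}

#' Read a cell-by-gene count matrix
#'
#' Reads either a 10x-style MatrixMarket bundle (a directory with
#' `matrix.mtx`, `features.tsv` and `barcodes.tsv`, genes x cells on disk)
#' or a delimited text matrix (header row of gene symbols, one row per
#' cell, first column of cell identifiers). Counts are validated to be
#' finite non-negative integers; a violation reports its coordinates.
#'
#' @param path Directory (for `mtx_dir`) or file (for `delimited`).
#' @param format `"mtx_dir"` or `"delimited"`.
#' @param species Species tag recorded in the gene metadata; one of
#'   `"mouse"`, `"human"`, `"pig"`, `"macaque"`.
#' @param sep Field separator for `delimited` (default tab).
#' @return A [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (genes as rows), gene metadata (`symbol`, `canonical`,
#'   `species`) and any cell metadata found alongside the matrix.
#' @seealso [writeMatrix()], [logNormalize()]
#' @export
readMatrix <- function(path, format = c("mtx_dir", "delimited"),
                       species = "mouse", sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("path does not exist: %s", path))
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    if (!file.exists(feat)) feat <- file.path(path, "genes.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc)) if (!file.exists(f))
      stop(sprintf("mtx_dir bundle is missing '%s'", basename(f)))
    counts <- tryCatch(Matrix::readMM(mtx), error = function(e)
      stop(sprintf("malformed MatrixMarket file '%s': %s", mtx,
                   conditionMessage(e))))
    features <- utils::read.delim(feat, header = FALSE,
                                  stringsAsFactors = FALSE)
    barcodes <- utils::read.delim(bc, header = FALSE,
                                  stringsAsFactors = FALSE)[[1L]]
    if (nrow(features) != nrow(counts))
      stop(sprintf("features.tsv has %d rows but matrix declares %d genes",
                   nrow(features), nrow(counts)))
    if (length(barcodes) != ncol(counts))
      stop(sprintf("barcodes.tsv has %d rows but matrix declares %d cells",
                   length(barcodes), ncol(counts)))
    symbols <- features[[1L]]
    if (anyDuplicated(symbols))
      stop(sprintf("duplicate gene symbols in features file: %s",
                   paste(unique(symbols[duplicated(symbols)]), collapse = ", ")))
    if (anyDuplicated(barcodes)) stop("duplicate cell barcodes")
    dimnames(counts) <- list(symbols, barcodes)
    .validateCounts(counts)
    meta_path <- file.path(path, "cell_meta.tsv")
    cellMeta <- NULL
    if (file.exists(meta_path)) {
      cm <- utils::read.delim(meta_path, header = TRUE,
                              stringsAsFactors = FALSE)
      rownames(cm) <- cm[[1L]]
      cellMeta <- S4Vectors::DataFrame(cm[barcodes, -1L, drop = FALSE])
    }
    .makeSCE(counts, cellMeta, species)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop(sprintf("malformed delimited matrix header in '%s': need a cell-id column plus at least one gene column", path))
    cells <- as.character(df[[1L]])
    genes <- colnames(df)[-1L]
    if (anyDuplicated(genes))
      stop(sprintf("duplicate gene columns: %s",
                   paste(unique(genes[duplicated(genes)]), collapse = ", ")))
    if (anyDuplicated(cells)) stop("duplicate cell identifiers")
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    .validateCounts(m)
    counts <- Matrix::t(methods::as(m, "CsparseMatrix"))  # genes x cells
    dimnames(counts) <- list(genes, cells)
    .makeSCE(counts, NULL, species)
  }
}

#' Write a count matrix
#'
#' Inverse of [readMatrix()]: `mtx_dir` writes `matrix.mtx`,
#' `features.tsv`, `barcodes.tsv` and (when cell metadata are present)
#' `cell_meta.tsv`; `delimited` writes cells as rows and genes as columns.
#' Reading the result back reproduces the counts exactly.
#'
#' @param m A SingleCellExperiment with a `counts` assay.
#' @param path Output directory (`mtx_dir`) or file (`delimited`).
#' @param format `"mtx_dir"` or `"delimited"`.
#' @return Invisibly, `path`.
#' @export
writeMatrix <- function(m, path, format = c("mtx_dir", "delimited")) {
  format <- match.arg(format)
  counts <- SummarizedExperiment::assay(m, "counts")
  if (ncol(counts) == 0L || nrow(counts) == 0L)
    stop("refusing to write an empty matrix (0 cells or 0 genes)")
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(path)) stop(sprintf("cannot create directory '%s'", path))
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    rd <- SummarizedExperiment::rowData(m)
    utils::write.table(
      data.frame(symbol = rownames(counts), canonical = rd$canonical,
                 species = rd$species),
      file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
    cd <- SummarizedExperiment::colData(m)
    if (ncol(cd) > 0L) {
      utils::write.table(
        cbind(data.frame(cell = colnames(counts)),
              as.data.frame(cd, optional = TRUE)),
        file.path(path, "cell_meta.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
  } else {
    out <- cbind(data.frame(cell = colnames(counts)),
                 as.data.frame(as.matrix(Matrix::t(counts))))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Gene order is preserved verbatim; no harmonization is applied at read
#' time (see [harmonizeGenes()]).
#'
#' @param path GMT file.
#' @param species Species tag attached to every signature.
#' @return A [SignatureSet].
#' @examples
#' sigs <- defaultSignatures()
#' sigGenes(sigs[["Endothelial activation/proliferation"]])
#' @export
readSignatures <- function(path, species = "mouse") {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than one gene (fields: %d)",
                   i, length(fields)))
    GeneSignature(name = fields[1L], genes = fields[-(1:2)],
                  species = species,
                  source = sprintf("%s: %s", basename(path), fields[2L]))
  })
  SignatureSet(sigs)
}

#' Read a cell-type marker panel from a GMT file
#'
#' @param path GMT file; each line `cell_type<TAB>description<TAB>markers...`.
#' @return A [MarkerPanel].
#' @export
readMarkerPanel <- function(path) {
  sigs <- readSignatures(path)
  MarkerPanel(lapply(sigs, function(s) MarkerSet(s@name, s@genes)))
}

#' Packaged default signatures and marker panel
#'
#' `defaultSignatures()` returns the four packaged pathway signatures
#' (cGAS-STING, 20 genes; Angiogenesis, 27; Hallmark angiogenesis, 36;
#' Endothelial activation/proliferation, 5) in mouse symbol convention.
#' `defaultMarkerPanel()` returns a literature-standard retinal cell-type
#' marker panel (endothelial, rod, bipolar, Muller glia, microglia);
#' the panel is an editable default, not a study-verbatim list.
#'
#' @return A [SignatureSet] or [MarkerPanel].
#' @export
defaultSignatures <- function() {
  readSignatures(system.file("extdata", "pathway_signatures.gmt",
                             package = "coactivate", mustWork = TRUE),
                 species = "mouse")
}

#' @rdname defaultSignatures
#' @export
defaultMarkerPanel <- function() {
  readMarkerPanel(system.file("extdata", "retina_markers.gmt",
                              package = "coactivate", mustWork = TRUE))
}
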