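#' Library-size log-normalization
#'
#' Scales each cell's counts to a common library size and log-transforms:
#' `logcounts[g, c] = log(pseudocount + counts[g, c] * targetSum / total_c)`
#' (natural log). This is the de facto single-cell standard (Seurat /
#' scanpy defaults with `targetSum = 1e4`, `pseudocount = 1`). The
#' configuration is recorded in `metadata(m)$normalization` for
#' provenance, and the transform is recomputed from counts on every call,
#' so repeated normalization is idempotent.
#'
#' @param m SingleCellExperiment with a `counts` assay.
#' @param targetSum Library-size scaling target (default 10000).
#' @param pseudocount Added before the log (default 1).
#' @return `m` with a `logcounts` assay added.
#' @examples
#' sce <- simulateDataset(syntheticConfig(nCells = 50, nGenes = 80, seed = 1))$matrix
#' sce <- logNormalize(sce)
#' @export
logNormalize <- function(m, targetSum = 1e4, pseudocount = 1) {
  stopifnot(targetSum > 0, pseudocount > 0)
  counts <- SummarizedExperiment::assay(m, "counts")
  totals <- Matrix::colSums(counts)
  zero <- which(totals == 0)
  if (length(zero))
    stop(sprintf("cannot normalize cells with zero total counts: %s",
                 paste(colnames(counts)[zero], collapse = ", ")))
  sf <- targetSum / totals
  norm <- methods::as(counts %*% Matrix::Diagonal(x = sf), "CsparseMatrix")
  if (pseudocount == 1) {
    norm@x <- log1p(norm@x)  # zeros stay zero: sparsity preserved
  } else {
    # general pseudocount shifts zero entries to log(pseudocount): dense
    norm <- methods::as(log(pseudocount + as.matrix(norm)), "CsparseMatrix")
  }
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(m, "logcounts") <- methods::as(norm, "generalMatrix")
  S4Vectors::metadata(m)$normalization <-
    list(target_sum = targetSum, log_base = "natural",
         pseudocount = pseudocount)
  m
}

#' Filter genes by detection frequency
#'
#' Keeps genes whose expression exceeds `exprThreshold` in strictly more
#' than `minCells` cells. The defaults (0.1, 10) follow the common
#' trajectory-analysis convention of selecting features detected above 0.1
#' in more than 10 cells.
#'
#' @param m SingleCellExperiment.
#' @param exprThreshold Detection threshold (>= 0); a gene counts as
#'   detected in a cell when its value is strictly above this.
#' @param minCells Strict lower bound on the number of detecting cells.
#' @param layer Assay to threshold (default `"counts"`, matching the
#'   count-based detection rule of trajectory tools; `"logcounts"` is
#'   available once [logNormalize()] has run).
#' @return Character vector of kept gene names (possibly empty, with a
#'   warning).
#' @export
detectGenes <- function(m, exprThreshold = 0.1, minCells = 10,
                        layer = c("counts", "logcounts")) {
  if (exprThreshold < 0) stop("'exprThreshold' must be non-negative")
  layer <- match.arg(layer)
  if (!layer %in% SummarizedExperiment::assayNames(m))
    stop(sprintf("layer '%s' not present; run logNormalize() first?", layer))
  x <- SummarizedExperiment::assay(m, layer)
  ncell <- Matrix::rowSums(x > exprThreshold)
  keep <- rownames(m)[ncell > minCells]
  if (!length(keep))
    warning("no genes pass the detection filter")
  keep
}
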