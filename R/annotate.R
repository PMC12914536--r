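#' Marker-based per-cell cell-type annotation
#'
#' Assigns each cell the cell type whose marker set has the highest mean
#' expression (on the chosen layer) in that cell; cells whose best-vs-
#' second-best margin falls below `minMargin` — including exact ties —
#' are labeled `"unassigned"`. Annotation is performed per cell, so it is
#' deterministic and independent of any clustering; if a clustering is
#' available in the cell metadata, cluster-level labels can be recovered
#' by majority vote over the per-cell calls.
#'
#' @param m SingleCellExperiment with the scoring layer present.
#' @param panel A [MarkerPanel]; markers are matched through
#'   [harmonizeGenes()] and missing markers raise a warning.
#' @param minMargin Abstention threshold on the score margin (default 0:
#'   pure argmax, ties abstain).
#' @param layer Assay used for marker means (default `"logcounts"`).
#' @return An [AnnotationResult].
#' @examples
#' d <- simulateDataset(syntheticConfig(nCells = 200, seed = 1))
#' m <- logNormalize(d$matrix)
#' ann <- annotateCells(m, defaultMarkerPanel())
#' table(cellLabels(ann), truthLabels(d$truth))
#' @export
annotateCells <- function(m, panel, minMargin = 0, layer = "logcounts") {
  if (!methods::is(panel, "MarkerPanel")) panel <- MarkerPanel(panel)
  if (length(panel) == 0L) stop("empty marker panel")
  if (!layer %in% SummarizedExperiment::assayNames(m))
    stop(sprintf("layer '%s' not present; run logNormalize() first?", layer))
  sp <- SummarizedExperiment::rowData(m)$species[1L]
  canon <- SummarizedExperiment::rowData(m)$canonical
  x <- SummarizedExperiment::assay(m, layer)
  pl <- as.list(panel)
  scores <- vapply(pl, function(ms) {
    idx <- match(harmonizeGenes(ms@markers, sp, sp), canon)
    missing <- ms@markers[is.na(idx)]
    if (length(missing))
      warning(sprintf("markers of '%s' absent from the matrix: %s",
                      ms@cellType, paste(missing, collapse = ", ")))
    idx <- idx[!is.na(idx)]
    if (!length(idx))
      stop(sprintf("no markers of '%s' present in the matrix", ms@cellType))
    Matrix::colSums(x[idx, , drop = FALSE]) / length(idx)
  }, numeric(ncol(m)))
  if (ncol(m) == 1L) scores <- matrix(scores, nrow = 1L,
                                      dimnames = list(colnames(m), names(panel)))
  best <- max.col(scores, ties.method = "first")
  # margin: best minus second-best panel score
  ord_top2 <- apply(scores, 1L, function(r) {
    s <- sort(r, decreasing = TRUE)
    if (length(s) > 1L) s[1L] - s[2L] else s[1L]
  })
  labels <- names(panel)[best]
  margin <- as.numeric(ord_top2)
  tie <- margin <= 1e-8 * (1 + abs(scores[cbind(seq_len(nrow(scores)), best)]))
  margin[tie] <- 0
  abstain <- if (minMargin > 0) margin < minMargin else tie
  labels[abstain] <- "unassigned"
  names(labels) <- names(margin) <- colnames(m)
  new("AnnotationResult", labels = labels, margin = margin, panel = panel,
      scores = scores)
}

#' Subset a matrix to its endothelial cells
#'
#' @param m SingleCellExperiment the annotation was computed on.
#' @param annotation An [AnnotationResult] aligned with `m`.
#' @param label The endothelial label in the panel (default
#'   `"Endothelial"`).
#' @return The EC-only SingleCellExperiment (metadata preserved); the
#'   assigned label is stored in `colData(m)$cell_type_call`.
#' @export
selectEndothelial <- function(m, annotation, label = "Endothelial") {
  if (!identical(names(cellLabels(annotation)), colnames(m)))
    stop("annotation is not aligned with the matrix")
  keep <- cellLabels(annotation) == label
  if (!any(keep))
    stop(sprintf("no cells labeled '%s'; check that the marker panel matches the dataset",
                 label))
  out <- m[, keep]
  SummarizedExperiment::colData(out)$cell_type_call <- label
  out
}

#' Call angiogenic (activated) endothelial cells
#'
#' Scores each EC on the endothelial activation/proliferation marker
#' signature (additively, the same rule as [scoreSignature()]) and calls
#' a cell angiogenic when its score exceeds either a fixed threshold or
#' the given quantile of the EC score distribution (default: quantile
#' mode at q = 0.75, i.e. the top quarter of ECs).
#'
#' @param ecMatrix SingleCellExperiment containing endothelial cells.
#' @param activationMarkers A [GeneSignature]; default the packaged
#'   endothelial activation/proliferation set
#'   (Mki67, Cxcr4, Dll4, Aplnr, Esm1).
#' @param method `"quantile"` (default) or `"threshold"`.
#' @param cutoff The quantile (default 0.75) or score threshold.
#' @param layer Scoring layer (default `"logcounts"`).
#' @return An [AngiogenicCall].
#' @export
callAngiogenic <- function(ecMatrix, activationMarkers = NULL,
                           method = c("quantile", "threshold"),
                           cutoff = NULL, layer = "logcounts") {
  method <- match.arg(method)
  if (is.null(cutoff)) cutoff <- if (method == "quantile") 0.75 else 0
  if (is.null(activationMarkers))
    activationMarkers <- defaultSignatures()[["Endothelial activation/proliferation"]]
  sv <- scoreSignature(ecMatrix, activationMarkers, layer = layer,
                       scale = "sum")
  vals <- scoreValues(sv)
  thr <- if (method == "quantile")
    stats::quantile(vals, probs = cutoff, names = FALSE, type = 7)
  else cutoff
  call <- vals > thr
  new("AngiogenicCall", isAngiogenic = call, evidence = sv,
      method = method, cutoff = cutoff)
}
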