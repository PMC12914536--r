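#' Additive per-cell signature scores
#'
#' The core scoring rule: for each cell, the score is the sum (or mean)
#' of the expression of the signature genes found in the matrix,
#' on the chosen layer. Signature genes are matched through
#' [harmonizeGenes()] against the matrix's canonical symbols, so e.g. a
#' signature listing `Tmem173` scores a matrix row named `Sting1`.
#' Missing genes reduce the reported coverage but never error, unless no
#' signature gene is present at all.
#'
#' @param m SingleCellExperiment.
#' @param sig A [GeneSignature].
#' @param layer `"logcounts"` (default; run [logNormalize()] first) or
#'   `"counts"`.
#' @param scale `"sum"` (default) or `"mean"` over the genes used.
#' @return A [ScoreVector] with per-cell values, the number of genes used
#'   and the coverage fraction.
#' @examples
#' d <- simulateDataset(syntheticConfig(nCells = 100, seed = 1))
#' m <- logNormalize(d$matrix)
#' sv <- scoreSignature(m, defaultSignatures()[["cGAS-STING"]])
#' sigCoverage(sv)
#' @export
scoreSignature <- function(m, sig, layer = c("logcounts", "counts"),
                           scale = c("sum", "mean")) {
  layer <- match.arg(layer)
  scale <- match.arg(scale)
  if (!layer %in% SummarizedExperiment::assayNames(m))
    stop(sprintf("layer '%s' not present; run logNormalize() first?", layer))
  sp <- SummarizedExperiment::rowData(m)$species[1L]
  genes <- harmonizeGenes(sigGenes(sig), sigSpecies(sig), sp)
  genes <- genes[!duplicated(genes)]
  canon <- SummarizedExperiment::rowData(m)$canonical
  idx <- match(genes, canon)
  used <- which(!is.na(idx))
  if (!length(used))
    stop(sprintf("MissingSignature: no genes of signature '%s' are present in the matrix",
                 sigName(sig)))
  x <- SummarizedExperiment::assay(m, layer)[idx[used], , drop = FALSE]
  vals <- Matrix::colSums(x)
  if (scale == "mean") vals <- vals / length(used)
  names(vals) <- colnames(m)
  new("ScoreVector", signatureName = sigName(sig), values = vals,
      nGenesUsed = length(used),
      coverage = length(used) / length(genes),
      layer = layer, scale = scale)
}

#' Score every signature in a set
#'
#' @param m SingleCellExperiment.
#' @param sigs A [SignatureSet].
#' @param ... Passed to [scoreSignature()].
#' @return Named list of [ScoreVector]s.
#' @export
scoreSignatureSet <- function(m, sigs, ...) {
  out <- lapply(sigs, scoreSignature, m = m, ...)
  names(out) <- names(sigs)
  out
}

#' Summarize scores by group with cell-count normalization
#'
#' Per-group summary of a score vector: size, mean, median and total
#' score, plus `normalized_n`, the group size divided by the largest
#' group size (so the largest group is exactly 1), the convention used
#' when comparing developmental stages with unequal cell counts.
#' Labels outside any expected set are kept as their own group.
#'
#' @param scores A [ScoreVector] (or bare numeric vector).
#' @param groups Per-cell labels aligned with the scores (character or
#'   factor; factor level order is preserved in the output).
#' @return data.frame with columns `group`, `n`, `mean`, `median`,
#'   `total`, `normalized_n`.
#' @export
summarizeByGroup <- function(scores, groups) {
  vals <- if (methods::is(scores, "ScoreVector")) scoreValues(scores) else scores
  if (length(vals) != length(groups))
    stop("'groups' must be aligned with the scores")
  g <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  n <- as.integer(table(g))
  out <- data.frame(
    group = levels(g),
    n = n,
    mean = as.numeric(tapply(vals, g, mean)),
    median = as.numeric(tapply(vals, g, stats::median)),
    total = as.numeric(tapply(vals, g, sum)),
    stringsAsFactors = FALSE)
  out$normalized_n <- out$n / max(out$n)
  out
}
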