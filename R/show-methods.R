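#' @describeIn GeneSignature-class Compact display.
#' @param object A GeneSignature.
#' @export
setMethod("show", "GeneSignature", function(object) {
  g <- object@genes
  head_g <- paste(utils::head(g, 5), collapse = ", ")
  cat(sprintf("GeneSignature '%s' (%s): %d genes [%s%s]\n",
              object@name, object@species, length(g), head_g,
              if (length(g) > 5) ", ..." else ""))
})

#' @export
setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet of %d signatures: %s\n", length(object),
              paste(names(object), collapse = ", ")))
})

#' @export
setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel of %d cell types: %s\n", length(object),
              paste(names(object), collapse = ", ")))
})

#' @export
setMethod("show", "ScoreVector", function(object) {
  cat(sprintf("ScoreVector '%s' on %d cells (layer %s, %s; %d genes, coverage %.2f)\n",
              object@signatureName, length(object@values), object@layer,
              object@scale, object@nGenesUsed, object@coverage))
  print(summary(object@values))
})

#' @export
setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: statistic = %.4g, NES = %.4g, p = %.4g (%s, %s%s)\n",
              object@statistic, object@nes, object@pValue, object@pMethod,
              object@side,
              if (object@nPermutations > 0L)
                sprintf(", %d permutations", object@nPermutations) else ""))
})

#' @export
setMethod("show", "CoactivationResult", function(object) {
  cat(sprintf("CoactivationResult: %s vs %s on %s\n  n = %d, rho = %.4f, p = %.4g (%s)\n",
              object@signatureX, object@signatureY, object@subset,
              object@n, object@rho, object@pValue, object@pMethod))
})

#' @export
setMethod("show", "AnnotationResult", function(object) {
  tab <- table(object@labels)
  cat(sprintf("AnnotationResult on %d cells:\n", length(object@labels)))
  print(tab)
})

#' @export
setMethod("show", "AngiogenicCall", function(object) {
  cat(sprintf("AngiogenicCall (%s, cutoff %.3g): %d / %d ECs angiogenic\n",
              object@method, object@cutoff, sum(object@isAngiogenic),
              length(object@isAngiogenic)))
})

#' @export
setMethod("show", "StratificationResult", function(object) {
  cat(sprintf("StratificationResult by '%s': %s (boundaries %s)\n",
              object@stratifiedBy,
              paste(sprintf("%s=%d", levels(object@groupLabels),
                            tabulate(object@groupLabels)), collapse = ", "),
              paste(signif(object@boundaries, 4), collapse = ", ")))
})

#' @export
setMethod("show", "HighLowContrast", function(object) {
  cat(sprintf("HighLowContrast '%s' by %s (%s): log2FC = %.4f, p = %.4g (n high/low = %d/%d)\n",
              object@gene, object@stratifiedBy, object@mode, object@log2FC,
              object@pValue, object@nHigh, object@nLow))
})

#' @export
setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d cells (%d ECs, %d angiogenic), latent rho = %.3g\n",
              length(object@labels), nrow(object@latent),
              sum(object@angiogenicFlag), object@config$rho))
})
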