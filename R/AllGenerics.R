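# Accessor generics; slots are internal, these are the supported surface.

#' @rdname GeneSignature-class
#' @export
setGeneric("sigName", function(x) standardGeneric("sigName"))
#' @rdname GeneSignature-class
#' @export
setGeneric("sigGenes", function(x) standardGeneric("sigGenes"))
#' @rdname GeneSignature-class
#' @export
setGeneric("sigSpecies", function(x) standardGeneric("sigSpecies"))

#' @rdname ScoreVector-class
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname ScoreVector-class
#' @export
setGeneric("sigCoverage", function(x) standardGeneric("sigCoverage"))
#' @rdname ScoreVector-class
#' @export
setGeneric("nGenesUsed", function(x) standardGeneric("nGenesUsed"))

#' @rdname CoactivationResult-class
#' @export
setGeneric("rhoValue", function(x) standardGeneric("rhoValue"))
#' @rdname CoactivationResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname AnnotationResult-class
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
#' @rdname AnnotationResult-class
#' @export
setGeneric("labelMargin", function(x) standardGeneric("labelMargin"))

#' @rdname AngiogenicCall-class
#' @export
setGeneric("isAngiogenic", function(x) standardGeneric("isAngiogenic"))

#' @rdname StratificationResult-class
#' @export
setGeneric("strataLabels", function(x) standardGeneric("strataLabels"))
#' @rdname StratificationResult-class
#' @export
setGeneric("strataBoundaries", function(x) standardGeneric("strataBoundaries"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("truthLatent", function(x) standardGeneric("truthLatent"))
#' @rdname SyntheticTruth-class
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname SyntheticTruth-class
#' @export
setGeneric("truthAngiogenic", function(x) standardGeneric("truthAngiogenic"))
#' @rdname SyntheticTruth-class
#' @export
setGeneric("truthConfig", function(x) standardGeneric("truthConfig"))

#' @export
setMethod("sigName", "GeneSignature", function(x) x@name)
#' @export
setMethod("sigGenes", "GeneSignature", function(x) x@genes)
#' @export
setMethod("sigSpecies", "GeneSignature", function(x) x@species)

#' @export
setMethod("scoreValues", "ScoreVector", function(x) x@values)
#' @export
setMethod("sigCoverage", "ScoreVector", function(x) x@coverage)
#' @export
setMethod("nGenesUsed", "ScoreVector", function(x) x@nGenesUsed)

#' @export
setMethod("rhoValue", "CoactivationResult", function(x) x@rho)
#' @export
setMethod("pValue", "CoactivationResult", function(x) x@pValue)
#' @export
setMethod("pValue", "EnrichmentResult", function(x) x@pValue)
#' @export
setMethod("pValue", "HighLowContrast", function(x) x@pValue)

#' @export
setMethod("cellLabels", "AnnotationResult", function(x) x@labels)
#' @export
setMethod("labelMargin", "AnnotationResult", function(x) x@margin)

#' @export
setMethod("isAngiogenic", "AngiogenicCall", function(x) x@isAngiogenic)

#' @export
setMethod("strataLabels", "StratificationResult", function(x) x@groupLabels)
#' @export
setMethod("strataBoundaries", "StratificationResult", function(x) x@boundaries)

#' @export
setMethod("truthLatent", "SyntheticTruth", function(x) x@latent)
#' @export
setMethod("truthLabels", "SyntheticTruth", function(x) x@labels)
#' @export
setMethod("truthAngiogenic", "SyntheticTruth", function(x) x@angiogenicFlag)
#' @export
setMethod("truthConfig", "SyntheticTruth", function(x) x@config)

#' Convert a CoactivationResult to a one-row data.frame
#'
#' @param x A CoactivationResult.
#' @param row.names,optional,... Passed through for generic consistency.
#' @export
as.data.frame.CoactivationResult <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(signature_x = x@signatureX, signature_y = x@signatureY,
             subset = x@subset, n = x@n, rho = x@rho, p_value = x@pValue,
             p_method = x@pMethod,
             seed = if (is.na(x@seed)) NA_integer_ else x@seed,
             stringsAsFactors = FALSE)
}
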