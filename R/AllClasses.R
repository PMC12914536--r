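#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

.SPECIES <- c("mouse", "human", "pig", "macaque")

#' GeneSignature: a named, ordered gene list
#'
#' The unit of signature scoring: a pathway name, an ordered vector of gene
#' symbols, a species tag governing symbol case conventions, and a free-text
#' source annotation.
#'
#' @slot name Signature name (unique within a [SignatureSet]).
#' @slot genes Character vector of gene symbols, non-empty, no duplicates.
#' @slot species One of `"mouse"`, `"human"`, `"pig"`, `"macaque"`.
#' @slot source Free-text provenance, e.g. the GMT file of origin.
#'
#' @examples
#' GeneSignature("demo", c("Kdr", "Flt1"), species = "mouse")
#' @export
setClass("GeneSignature",
  representation(name = "character", genes = "character",
                 species = "character", source = "character"))

setValidity("GeneSignature", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@genes) == 0L)
    msg <- c(msg, "'genes' must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, sprintf("duplicate gene symbols: %s",
                          paste(unique(object@genes[duplicated(object@genes)]),
                                collapse = ", ")))
  if (length(object@species) != 1L || !object@species %in% .SPECIES)
    msg <- c(msg, sprintf("'species' must be one of %s",
                          paste(.SPECIES, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' @param name,genes,species,source See slots.
#' @rdname GeneSignature-class
#' @export
GeneSignature <- function(name, genes, species = "mouse", source = "") {
  new("GeneSignature", name = name, genes = as.character(genes),
      species = species, source = source)
}

#' SignatureSet: a collection of GeneSignature objects with unique names
#'
#' A thin [S4Vectors::SimpleList] subclass; element names mirror the
#' signature names and must be unique.
#'
#' @examples
#' ss <- SignatureSet(GeneSignature("a", "Kdr"), GeneSignature("b", "Flt1"))
#' names(ss)
#' @export
setClass("SignatureSet", contains = "SimpleList",
         prototype = prototype(elementType = "GeneSignature"))

setValidity("SignatureSet", function(object) {
  if (length(object) == 0L) return(TRUE)
  ok <- vapply(object, is, logical(1), "GeneSignature")
  if (!all(ok)) return("all elements must be GeneSignature objects")
  nms <- vapply(object, function(s) s@name, character(1))
  if (anyDuplicated(nms))
    return(sprintf("signature names must be unique; duplicated: %s",
                   paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  TRUE
})

#' @param ... GeneSignature objects (or a single list of them).
#' @rdname SignatureSet-class
#' @export
SignatureSet <- function(...) {
  sigs <- list(...)
  if (length(sigs) == 1L && is.list(sigs[[1L]]) && !is(sigs[[1L]], "GeneSignature"))
    sigs <- sigs[[1L]]
  names(sigs) <- vapply(sigs, function(s) s@name, character(1))
  new("SignatureSet", S4Vectors::SimpleList(sigs))
}

#' MarkerSet and MarkerPanel: cell-type marker definitions
#'
#' A `MarkerSet` holds the marker genes of one cell type; a `MarkerPanel`
#' is a list of MarkerSets in which each marker belongs to at most one set
#' (the panel validation rule), so that marker-based annotation is
#' unambiguous.
#'
#' @slot cellType Cell-type label.
#' @slot markers Non-empty character vector of marker gene symbols.
#'
#' @examples
#' MarkerPanel(MarkerSet("Endothelial", c("Pecam1", "Cdh5")),
#'             MarkerSet("Rod", c("Rho", "Nrl")))
#' @export
setClass("MarkerSet",
  representation(cellType = "character", markers = "character"))

setValidity("MarkerSet", function(object) {
  msg <- NULL
  if (length(object@cellType) != 1L || !nzchar(object@cellType))
    msg <- c(msg, "'cellType' must be a single non-empty string")
  if (length(object@markers) == 0L)
    msg <- c(msg, "'markers' must be non-empty")
  if (anyDuplicated(object@markers))
    msg <- c(msg, "duplicate markers within a MarkerSet")
  if (is.null(msg)) TRUE else msg
})

#' @param cellType,markers See slots.
#' @rdname MarkerSet-class
#' @export
MarkerSet <- function(cellType, markers) {
  new("MarkerSet", cellType = cellType, markers = as.character(markers))
}

#' @rdname MarkerSet-class
#' @export
setClass("MarkerPanel", contains = "SimpleList",
         prototype = prototype(elementType = "MarkerSet"))

setValidity("MarkerPanel", function(object) {
  if (length(object) == 0L) return("a MarkerPanel must contain at least one MarkerSet")
  ok <- vapply(object, is, logical(1), "MarkerSet")
  if (!all(ok)) return("all elements must be MarkerSet objects")
  types <- vapply(object, function(s) s@cellType, character(1))
  if (anyDuplicated(types))
    return("cell types must be unique within a panel")
  all_markers <- unlist(lapply(object, function(s) s@markers))
  if (anyDuplicated(all_markers))
    return(sprintf("a marker may appear in at most one MarkerSet; shared: %s",
                   paste(unique(all_markers[duplicated(all_markers)]),
                         collapse = ", ")))
  TRUE
})

#' @param ... MarkerSet objects (or a single list of them).
#' @rdname MarkerSet-class
#' @export
MarkerPanel <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "MarkerSet"))
    sets <- sets[[1L]]
  names(sets) <- vapply(sets, function(s) s@cellType, character(1))
  new("MarkerPanel", S4Vectors::SimpleList(sets))
}

#' ScoreVector: per-cell scores for one signature
#'
#' @slot signatureName Name of the scored signature.
#' @slot values Named numeric vector of per-cell (or per-sample) scores.
#' @slot nGenesUsed Number of signature genes found in the matrix.
#' @slot coverage Fraction of signature genes found, in (0, 1].
#' @slot layer Expression layer the scores were computed on.
#' @slot scale `"sum"` or `"mean"`.
#' @export
setClass("ScoreVector",
  representation(signatureName = "character", values = "numeric",
                 nGenesUsed = "integer", coverage = "numeric",
                 layer = "character", scale = "character"))

setValidity("ScoreVector", function(object) {
  msg <- NULL
  if (!all(is.finite(object@values)))
    msg <- c(msg, "score values must be finite")
  if (length(object@coverage) != 1L || object@coverage <= 0 || object@coverage > 1)
    msg <- c(msg, "'coverage' must lie in (0, 1]")
  if (length(object@nGenesUsed) != 1L || object@nGenesUsed < 1L)
    msg <- c(msg, "'nGenesUsed' must be a positive integer")
  if (is.null(msg)) TRUE else msg
})

#' EnrichmentResult: a KS or GSEA enrichment statistic
#'
#' @slot statistic KS D (two-sided D in \[0,1\], or a signed one-sided D)
#'   or the GSEA enrichment score ES.
#' @slot nes Normalized enrichment score (GSEA only; `NA` for KS).
#' @slot pValue Nominal p-value in \[0,1\].
#' @slot pMethod How the p-value was obtained
#'   (`"exact"`, `"asymptotic"`, `"permutation"`).
#' @slot nPermutations Number of permutations (0 when not permutation-based).
#' @slot side `"two-sided"`, `"greater"` or `"less"`.
#' @slot seed RNG seed used for the permutation null (`NA` otherwise).
#' @export
setClass("EnrichmentResult",
  representation(statistic = "numeric", nes = "numeric", pValue = "numeric",
                 pMethod = "character", nPermutations = "integer",
                 side = "character", seed = "integer"))

setValidity("EnrichmentResult", function(object) {
  msg <- NULL
  if (!is.finite(object@statistic)) msg <- c(msg, "'statistic' must be finite")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "'pValue' must lie in [0, 1]")
  if (object@nPermutations > 0L &&
      object@pValue < 1 / (object@nPermutations + 1) - 1e-12)
    msg <- c(msg, "permutation p-value below its attainable minimum")
  if (!object@side %in% c("two-sided", "greater", "less"))
    msg <- c(msg, "invalid 'side'")
  if (is.null(msg)) TRUE else msg
})

#' CoactivationResult: a Spearman co-activation test
#'
#' Result of a rank-correlation test between two per-cell score vectors
#' (or two single-gene expression vectors) on one cell subset.
#'
#' @slot signatureX,signatureY Names of the correlated score vectors.
#' @slot subset Free-text description of the cell selection.
#' @slot n Number of cells (or samples) used.
#' @slot rho Spearman rank correlation, in \[-1, 1\].
#' @slot pValue P-value of the correlation test.
#' @slot pMethod `"exact"`, `"permutation"` or `"t-approximation"`.
#' @slot seed RNG seed for Monte-Carlo permutation (`NA` otherwise).
#' @export
setClass("CoactivationResult",
  representation(signatureX = "character", signatureY = "character",
                 subset = "character", n = "integer", rho = "numeric",
                 pValue = "numeric", pMethod = "character", seed = "integer"))

setValidity("CoactivationResult", function(object) {
  msg <- NULL
  if (abs(object@rho) > 1 + 1e-12) msg <- c(msg, "|rho| must be <= 1")
  if (object@n < 3L) msg <- c(msg, "'n' must be >= 3 for a reported p-value")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "'pValue' must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' AnnotationResult: per-cell marker-based cell-type calls
#'
#' @slot labels Named character vector: one cell-type label per cell, or
#'   the sentinel `"unassigned"`.
#' @slot margin Named numeric vector: difference between the best and
#'   second-best marker-set score, always >= 0.
#' @slot panel The [MarkerPanel] used.
#' @slot scores Cell x cell-type matrix of mean marker expression.
#' @export
setClass("AnnotationResult",
  representation(labels = "character", margin = "numeric",
                 panel = "MarkerPanel", scores = "matrix"))

setValidity("AnnotationResult", function(object) {
  msg <- NULL
  if (length(object@labels) != length(object@margin))
    msg <- c(msg, "'labels' and 'margin' must be aligned")
  if (any(object@margin < 0)) msg <- c(msg, "'margin' must be >= 0")
  known <- c(vapply(object@panel, function(s) s@cellType, character(1)),
             "unassigned")
  if (!all(object@labels %in% known))
    msg <- c(msg, "labels must come from the panel or be 'unassigned'")
  if (is.null(msg)) TRUE else msg
})

#' AngiogenicCall: activated-EC calls on an endothelial subset
#'
#' @slot isAngiogenic Named logical vector over EC cells.
#' @slot evidence Per-cell activation-marker scores (a [ScoreVector]).
#' @slot method `"threshold"` or `"quantile"`.
#' @slot cutoff The threshold value or quantile used.
#' @export
setClass("AngiogenicCall",
  representation(isAngiogenic = "logical", evidence = "ScoreVector",
                 method = "character", cutoff = "numeric"))

setValidity("AngiogenicCall", function(object) {
  if (length(object@isAngiogenic) != length(object@evidence@values))
    return("'isAngiogenic' must align with the evidence scores")
  TRUE
})

#' StratificationResult: low/mid/high activity strata
#'
#' @slot groupLabels Named factor with ordered levels (low < mid < high for
#'   k = 3) partitioning the cells.
#' @slot boundaries Empirical quantile cutpoints of the stratifying score.
#' @slot stratifiedBy Name of the stratifying score.
#' @export
setClass("StratificationResult",
  representation(groupLabels = "factor", boundaries = "numeric",
                 stratifiedBy = "character"))

#' HighLowContrast: a single-gene high-vs-low expression contrast
#'
#' @slot gene Target gene symbol.
#' @slot stratifiedBy Stratifying gene or signature name.
#' @slot mode `"halves"` or `"tertile-extremes"`.
#' @slot log2FC log2 fold change (mean high + eps) / (mean low + eps).
#' @slot pValue Rank-sum p-value.
#' @slot nHigh,nLow Group sizes.
#' @slot pseudocount The eps used in the fold change.
#' @export
setClass("HighLowContrast",
  representation(gene = "character", stratifiedBy = "character",
                 mode = "character", log2FC = "numeric", pValue = "numeric",
                 nHigh = "integer", nLow = "integer", pseudocount = "numeric"))

#' SyntheticTruth: ground truth emitted with a simulated dataset
#'
#' @slot latent [S4Vectors::DataFrame] with one row per endothelial cell:
#'   columns `cell`, `aSting`, `aAngio` (the bivariate latent activities).
#' @slot labels Named character vector of true cell types for all cells.
#' @slot angiogenicFlag Named logical vector over EC cells: which carry the
#'   activation program.
#' @slot config The full simulation configuration (list), echoed verbatim.
#' @export
setClass("SyntheticTruth",
  representation(latent = "DataFrame", labels = "character",
                 angiogenicFlag = "logical", config = "list"))

setValidity("SyntheticTruth", function(object) {
  msg <- NULL
  ec <- names(object@labels)[object@labels == object@config$ecType]
  if (!setequal(object@latent$cell, ec))
    msg <- c(msg, "latent activities must be defined exactly on EC cells")
  if (!setequal(names(object@angiogenicFlag), ec))
    msg <- c(msg, "angiogenicFlag must be defined exactly on EC cells")
  if (is.null(msg)) TRUE else msg
})
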