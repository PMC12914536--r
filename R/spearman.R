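# Spearman rank correlation with exact-enumeration, Monte-Carlo and
# t-approximation p-values. The exact null enumerates all n! permutations;
# with the rank marginals fixed, every permuted rho is affine in the sum of
# rank products, which keeps full enumeration cheap up to n = 9.

.permEnv <- new.env(parent = emptyenv())

# all permutations of 1..n as an (n!) x n integer matrix, cached
.allPermutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.permEnv[[key]])) return(.permEnv[[key]])
  build <- function(k) {
    if (k == 1L) return(matrix(1L, 1L, 1L))
    sp <- build(k - 1L)
    p <- nrow(sp)
    out <- matrix(0L, k * p, k)
    for (i in seq_len(k)) {
      out[(i - 1L) * p + seq_len(p), 1L] <- i
      out[(i - 1L) * p + seq_len(p), -1L] <- sp + (sp >= i)
    }
    out
  }
  res <- build(n)
  if (n <= 9L) .permEnv[[key]] <- res
  res
}

.spearmanRho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  ssx <- sum(dx^2); ssy <- sum(dy^2)
  if (ssx == 0 || ssy == 0)
    stop("Spearman rho is undefined for a constant vector")
  sum(dx * dy) / sqrt(ssx * ssy)
}

# exact two-sided permutation p by full enumeration of rank permutations
.spearmanExactP <- function(x, y) {
  n <- length(x)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); ssx <- sum(dx^2)
  dy <- ry - mean(ry); ssy <- sum(dy^2)
  if (ssx == 0 || ssy == 0)
    stop("Spearman rho is undefined for a constant vector")
  rho <- sum(dx * dy) / sqrt(ssx * ssy)
  P <- .allPermutations(n)
  Y <- matrix(ry[P], nrow(P), n)
  S <- as.vector(Y %*% rx)                       # sum of rank products
  rho_perm <- (S - n * mean(rx) * mean(ry)) / sqrt(ssx * ssy)
  p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  list(rho = rho, p = p)
}

.spearmanMCPermP <- function(x, y, nPermutations, seed) {
  n <- length(x)
  rho <- .spearmanRho(x, y)
  hits <- .withSeed(seed, {
    h <- 0L
    for (b in seq_len(nPermutations)) {
      r <- .spearmanRho(x, sample(y))
      if (abs(r) >= abs(rho) - 1e-12) h <- h + 1L
    }
    h
  })
  list(rho = rho, p = (hits + 1) / (nPermutations + 1))
}

.spearmanTApproxP <- function(x, y) {
  n <- length(x)
  rho <- .spearmanRho(x, y)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Spearman co-activation test between two score vectors
#'
#' Rank correlation (midrank ties) between two per-cell signature scores
#' on the same cells, with a p-value by exact enumeration of all rank
#' permutations (n <= 9), seeded Monte-Carlo permutation, or the usual
#' t-approximation. `"auto"` picks exact for n <= 9 and the
#' t-approximation otherwise.
#'
#' @param x,y [ScoreVector]s (or bare numeric vectors) aligned on the
#'   same cells; n >= 3.
#' @param pMethod `"auto"`, `"exact"`, `"permutation"` or
#'   `"t-approximation"`.
#' @param nPermutations Monte-Carlo permutation count (default 10000).
#' @param seed RNG seed, mandatory for `pMethod = "permutation"`.
#' @param subset Free-text descriptor of the cell selection, recorded in
#'   the result.
#' @return A [CoactivationResult].
#' @examples
#' r <- spearmanCoactivation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
#' rhoValue(r); pValue(r)
#' @export
spearmanCoactivation <- function(x, y,
                                 pMethod = c("auto", "exact", "permutation",
                                             "t-approximation"),
                                 nPermutations = 10000, seed = NA_integer_,
                                 subset = "all cells") {
  pMethod <- match.arg(pMethod)
  nx <- if (methods::is(x, "ScoreVector")) sigName_or(x) else "x"
  ny <- if (methods::is(y, "ScoreVector")) sigName_or(y) else "y"
  vx <- if (methods::is(x, "ScoreVector")) scoreValues(x) else as.numeric(x)
  vy <- if (methods::is(y, "ScoreVector")) scoreValues(y) else as.numeric(y)
  if (length(vx) != length(vy))
    stop("'x' and 'y' must be aligned on the same cells")
  if (!is.null(names(vx)) && !is.null(names(vy)) &&
      !identical(names(vx), names(vy)))
    stop("'x' and 'y' are named but their cell names differ")
  n <- length(vx)
  if (n < 3L) stop("need at least 3 observations")
  if (pMethod == "auto")
    pMethod <- if (n <= 9L) "exact" else "t-approximation"
  res <- switch(pMethod,
    "exact" = {
      if (n > 9L) stop("exact enumeration supported only for n <= 9")
      .spearmanExactP(vx, vy)
    },
    "permutation" = {
      if (is.na(seed)) stop("'seed' is required for permutation p-values")
      .spearmanMCPermP(vx, vy, nPermutations, seed)
    },
    "t-approximation" = .spearmanTApproxP(vx, vy))
  new("CoactivationResult", signatureX = nx, signatureY = ny,
      subset = subset, n = as.integer(n), rho = res$rho, pValue = res$p,
      pMethod = pMethod,
      seed = if (pMethod == "permutation") as.integer(seed) else NA_integer_)
}

sigName_or <- function(sv) {
  if (length(sv@signatureName)) sv@signatureName else "score"
}

#' Spearman correlation between two single genes
#'
#' The same machinery as [spearmanCoactivation()] applied to the
#' expression vectors of two genes on a cell subset.
#'
#' @param m SingleCellExperiment.
#' @param geneA,geneB Gene symbols (harmonized to the matrix species
#'   before lookup).
#' @param subset Optional cell selection: character vector of cell names
#'   or logical/integer index; default all cells.
#' @param layer Assay to correlate (default `"logcounts"`).
#' @param ... Passed to [spearmanCoactivation()].
#' @return A [CoactivationResult].
#' @export
geneGeneCorrelation <- function(m, geneA, geneB, subset = NULL,
                                layer = "logcounts", ...) {
  if (!layer %in% SummarizedExperiment::assayNames(m))
    stop(sprintf("layer '%s' not present", layer))
  sp <- SummarizedExperiment::rowData(m)$species[1L]
  canon <- SummarizedExperiment::rowData(m)$canonical
  sub_desc <- if (is.null(subset)) "all cells" else "cell subset"
  msub <- if (is.null(subset)) m else m[, subset]
  vecs <- lapply(c(geneA, geneB), function(g) {
    gc <- harmonizeGenes(g, sp, sp)
    i <- match(gc, canon)
    if (is.na(i)) stop(sprintf("gene '%s' not present in the matrix", g))
    as.numeric(SummarizedExperiment::assay(msub, layer)[i, ])
  })
  res <- spearmanCoactivation(vecs[[1L]], vecs[[2L]], subset = sub_desc, ...)
  res@signatureX <- geneA
  res@signatureY <- geneB
  res
}
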