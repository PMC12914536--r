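# Weighted running-sum (GSEA) enrichment score with a gene-label
# permutation null.

.gseaRunningES <- function(hits, weights, weightP) {
  N <- length(hits)
  Nh <- sum(hits)
  inc <- numeric(N)
  if (weightP == 0) {
    inc[hits] <- 1 / Nh
  } else {
    w <- abs(weights[hits])^weightP
    tot <- sum(w)
    if (tot == 0) inc[hits] <- 1 / Nh else inc[hits] <- w / tot
  }
  inc[!hits] <- -1 / (N - Nh)
  run <- cumsum(inc)
  mx <- max(run); mn <- min(run)
  # signed maximum deviation; an exact tie in magnitude resolves to the
  # positive deviation (deterministic, tolerance guards fp accumulation)
  if (mx >= -mn - 1e-9) mx else mn
}

#' GSEA running-sum enrichment score with permutation null
#'
#' The classic weighted Kolmogorov-Smirnov-style running sum: walking down
#' the ranked gene list, the sum increases at each gene-set hit (by the
#' hit's `|score|^weightP`, normalized so that hits total 1) and decreases
#' by `1/(N - Nh)` at each miss; the enrichment score ES is the signed
#' maximum deviation. With `weightP = 0` this is the unweighted KS
#' running-sum statistic. The null distribution is generated by gene-label
#' permutation (random gene sets of the same size at fixed ranking);
#' NES = ES / mean(|null ES|) over null draws of matching sign, and the
#' nominal p-value is the matching-sign permutation tail with the +1
#' correction, so p >= 1/(nPermutations + 1).
#'
#' @param ranking Named numeric vector: ranking scores with gene names.
#'   Sorted in decreasing score order internally; ties keep their input
#'   order (stable).
#' @param geneSet A [GeneSignature] (or character vector of genes); must
#'   overlap the ranking and be a proper subset of it.
#' @param weightP 0 (unweighted) or 1 (score-weighted).
#' @param nPermutations Gene-label permutations (default 1000).
#' @param seed RNG seed for the permutation null (mandatory).
#' @return An [EnrichmentResult] with ES, NES and the nominal p-value.
#' @examples
#' r <- c(a = 3, b = 2, c = 1, d = 0.5)
#' gseaES(r, c("a"), weightP = 0, nPermutations = 100, seed = 1)
#' @export
gseaES <- function(ranking, geneSet, weightP = 1, nPermutations = 1000,
                   seed) {
  if (missing(seed)) stop("'seed' is required for the permutation null")
  if (!weightP %in% c(0, 1)) stop("'weightP' must be 0 or 1")
  if (is.null(names(ranking))) stop("'ranking' must be a named vector")
  genes <- if (methods::is(geneSet, "GeneSignature")) sigGenes(geneSet)
           else as.character(geneSet)
  ord <- order(ranking, decreasing = TRUE)   # stable: ties keep input order
  r <- ranking[ord]
  hits <- names(r) %in% genes
  N <- length(r); Nh <- sum(hits)
  if (Nh == 0L) stop("gene set has no overlap with the ranking")
  if (Nh == N) stop("degenerate gene set: covers the whole ranking (miss denominator zero)")
  es <- .gseaRunningES(hits, r, weightP)
  null_es <- .withSeed(seed, {
    vapply(seq_len(nPermutations), function(b) {
      h <- logical(N)
      h[sample.int(N, Nh)] <- TRUE
      .gseaRunningES(h, r, weightP)
    }, numeric(1))
  })
  same_sign <- if (es >= 0) null_es >= 0 else null_es < 0
  n_side <- sum(same_sign)
  if (n_side == 0L) {
    nes <- NA_real_
    p <- 1 / (nPermutations + 1)
  } else {
    nes <- es / mean(abs(null_es[same_sign]))
    p <- (1 + sum(abs(null_es[same_sign]) >= abs(es) - 1e-12)) / (1 + n_side)
  }
  new("EnrichmentResult", statistic = es, nes = nes, pValue = p,
      pMethod = "permutation", nPermutations = as.integer(nPermutations),
      side = if (es >= 0) "greater" else "less", seed = as.integer(seed))
}
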