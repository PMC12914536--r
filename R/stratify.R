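#' Stratify cells by signature-score quantiles
#'
#' Partitions cells into `k` ordered activity strata (low / mid / high for
#' k = 3) by empirical score quantiles. Cells are assigned in stable rank
#' order (ties broken by input order, boundary cells falling to the lower
#' stratum first), so group sizes differ by at most one from n/k and the
#' partition depends only on the score ranks.
#'
#' @param scores A [ScoreVector] or numeric vector.
#' @param k Number of strata (default 3; must be >= 2 and <= n).
#' @return A [StratificationResult]; for k = 3 the ordered levels are
#'   `low < mid < high`, otherwise `stratum1 < ... < stratumk`.
#' @examples
#' strataLabels(stratifyByScore(c(5, 1, 9, 3, 7, 2, 8, 4, 6)))
#' @export
stratifyByScore <- function(scores, k = 3) {
  nm <- if (methods::is(scores, "ScoreVector")) scores@signatureName else "score"
  vals <- if (methods::is(scores, "ScoreVector")) scoreValues(scores) else scores
  n <- length(vals)
  if (k < 2) stop("'k' must be at least 2")
  if (n < k) stop("need at least k observations")
  lev <- if (k == 3) c("low", "mid", "high") else paste0("stratum", seq_len(k))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(vals)                     # stable for ties (radix)
  lab <- integer(n)
  lab[ord] <- rep(seq_len(k), times = sizes)
  g <- factor(lev[lab], levels = lev, ordered = TRUE)
  names(g) <- names(vals)
  bounds <- stats::quantile(vals, probs = seq_len(k - 1) / k, names = FALSE,
                            type = 7)
  new("StratificationResult", groupLabels = g, boundaries = bounds,
      stratifiedBy = nm)
}

# Wilcoxon rank-sum via the normal approximation; a fully tied pooled
# sample has zero variance, which is the null exactly (p = 1).
.rankSum <- function(b, a) {
  if (length(unique(c(a, b))) == 1L)
    return(list(W = length(a) * length(b) / 2, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(b, a, exact = FALSE,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1
  list(W = unname(wt$statistic), p = p)
}

# Jonckheere-Terpstra ordered-trend statistic with normal approximation.
# J = sum over ordered group pairs (i < j) of the Mann-Whitney count of
# group-j values exceeding group-i values (ties count 1/2).
.jonckheereTrend <- function(values, groups) {
  gl <- levels(groups)
  ni <- tabulate(groups)
  J <- 0
  for (i in seq_along(gl)[-length(gl)]) {
    xi <- values[groups == gl[i]]
    for (j in (i + 1):length(gl)) {
      xj <- values[groups == gl[j]]
      cmp <- outer(xj, xi, ">") + 0.5 * outer(xj, xi, "==")
      J <- J + sum(cmp)
    }
  }
  n <- length(values)
  mu <- (n^2 - sum(ni^2)) / 4
  sigma2 <- (n^2 * (2 * n + 3) - sum(ni^2 * (2 * ni + 3))) / 72
  z <- if (sigma2 > 0) (J - mu) / sqrt(sigma2) else 0
  list(J = J, mean = mu, z = z,
       p_increasing = stats::pnorm(z, lower.tail = FALSE))
}

#' Contrast a second score across activity strata
#'
#' Pairwise two-sample rank-sum (Wilcoxon) tests between every pair of
#' strata on a second score, plus a Jonckheere-Terpstra rank statistic
#' for a monotone increasing trend across the ordered strata.
#'
#' @param strata A [StratificationResult].
#' @param otherScores A [ScoreVector] (or numeric) aligned with the
#'   stratified cells.
#' @return List with `contrasts` (data.frame: group pair, group sizes,
#'   median difference, Wilcoxon W and p) and `trend` (list: J statistic,
#'   null mean, z, one-sided p for an increasing trend).
#' @export
contrastAcrossStrata <- function(strata, otherScores) {
  vals <- if (methods::is(otherScores, "ScoreVector"))
    scoreValues(otherScores) else otherScores
  g <- strataLabels(strata)
  if (length(vals) != length(g))
    stop("'otherScores' must be aligned with the strata")
  if (any(tabulate(g) == 0L)) stop("empty stratum")
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- vals[g == pairs[1, i]]
    b <- vals[g == pairs[2, i]]
    wt <- .rankSum(b, a)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               n_a = length(a), n_b = length(b),
               median_a = stats::median(a), median_b = stats::median(b),
               W = wt$W, p_value = wt$p,
               stringsAsFactors = FALSE)
  })
  list(contrasts = do.call(rbind, rows),
       trend = .jonckheereTrend(vals, g),
       test_family = "Wilcoxon rank-sum (normal approximation) + Jonckheere-Terpstra trend")
}

#' High-vs-low contrast of a target gene
#'
#' Stratifies cells by a gene's expression or a signature's score and
#' contrasts a target gene's normalized expression between the high and
#' low groups: `log2FC = log2((mean_high + eps) / (mean_low + eps))`
#' with a rank-sum p-value. `mode = "halves"` splits at the median (stable
#' ties), `"tertile-extremes"` contrasts the top against the bottom
#' tertile.
#'
#' @param m SingleCellExperiment with `logcounts`.
#' @param stratifyBy A gene symbol or a [GeneSignature] to stratify on.
#' @param targetGene Target gene symbol.
#' @param mode `"halves"` or `"tertile-extremes"`.
#' @param pseudocount The eps in the fold change (default 1e-9).
#' @return A [HighLowContrast].
#' @export
highLowGeneContrast <- function(m, stratifyBy, targetGene,
                                mode = c("halves", "tertile-extremes"),
                                pseudocount = 1e-9) {
  mode <- match.arg(mode)
  if (!"logcounts" %in% SummarizedExperiment::assayNames(m))
    stop("run logNormalize() first")
  sp <- SummarizedExperiment::rowData(m)$species[1L]
  canon <- SummarizedExperiment::rowData(m)$canonical
  getGene <- function(g) {
    i <- match(harmonizeGenes(g, sp, sp), canon)
    if (is.na(i)) stop(sprintf("gene '%s' not present in the matrix", g))
    as.numeric(SummarizedExperiment::assay(m, "logcounts")[i, ])
  }
  if (methods::is(stratifyBy, "GeneSignature")) {
    strat_vals <- scoreValues(scoreSignature(m, stratifyBy))
    strat_name <- sigName(stratifyBy)
  } else {
    strat_vals <- getGene(stratifyBy)
    strat_name <- stratifyBy
  }
  target <- getGene(targetGene)
  k <- if (mode == "halves") 2L else 3L
  st <- stratifyByScore(strat_vals, k = k)
  g <- strataLabels(st)
  lev <- levels(g)
  lo <- target[g == lev[1L]]
  hi <- target[g == lev[length(lev)]]
  if (!length(lo) || !length(hi)) stop("empty high or low group")
  wt <- .rankSum(hi, lo)
  new("HighLowContrast", gene = targetGene, stratifiedBy = strat_name,
      mode = mode,
      log2FC = log2((mean(hi) + pseudocount) / (mean(lo) + pseudocount)),
      pValue = wt$p, nHigh = length(hi), nLow = length(lo),
      pseudocount = pseudocount)
}
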