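# Two-sample Kolmogorov-Smirnov statistic with a small-sample exact
# p-value computed by integer lattice path counting (no floating-point
# band comparisons), and the asymptotic Kolmogorov distribution otherwise.

# D statistics in exact integer units: value / (na * nb)
.ksDnum <- function(a, b) {
  na <- length(a); nb <- length(b)
  z <- c(a, b)
  ord <- order(z)
  isA <- rep(c(TRUE, FALSE), c(na, nb))[ord]
  # running (i * nb - j * na), evaluated only at the end of tied runs
  steps <- ifelse(isA, nb, -na)
  run <- cumsum(steps)
  zs <- z[ord]
  keep <- c(diff(zs) != 0, TRUE)
  r <- run[keep]
  list(num_abs = max(abs(r)), num_plus = max(r), num_minus = max(-r),
       na = na, nb = nb, ties = any(duplicated(z)))
}

# exact Pr(D >= d) by counting monotone lattice paths from (0,0) to
# (na, nb) whose running |i*nb - j*na| stays strictly below dnum
.ksExactP <- function(dnum, na, nb, signed = 0L) {
  # signed = 0: two-sided; +1: only i*nb - j*na bounded above;
  # -1: only j*na - i*nb bounded above
  N <- matrix(0, na + 1L, nb + 1L)
  N[1L, 1L] <- 1
  for (i in 0:na) {
    for (j in 0:nb) {
      if (i == 0L && j == 0L) next
      dev <- i * nb - j * na
      ok <- switch(as.character(signed),
                   "0" = abs(dev) < dnum,
                   "1" = dev < dnum,
                   "-1" = -dev < dnum)
      if (!ok) { N[i + 1L, j + 1L] <- 0; next }
      acc <- 0
      if (i > 0L) acc <- acc + N[i, j + 1L]
      if (j > 0L) acc <- acc + N[i + 1L, j]
      N[i + 1L, j + 1L] <- acc
    }
  }
  1 - N[na + 1L, nb + 1L] / choose(na + nb, na)
}

# asymptotic survival function of the Kolmogorov distribution
.ksAsymptoticP <- function(d, na, nb, side) {
  lambda <- sqrt(na * nb / (na + nb)) * d
  if (lambda == 0) return(1)
  if (side == "two-sided") {
    k <- seq_len(100)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  } else {
    p <- exp(-2 * lambda^2)
  }
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov enrichment test
#'
#' Compares the per-cell score distributions of two cell groups with the
#' two-sample KS statistic, the group-comparison statistic behind
#' signature-score contrasts between conditions or strata. The exact
#' p-value (all group-assignment orderings equally likely) is computed by
#' integer lattice-path counting when the pooled sample has no ties and
#' `length(a) * length(b) <= 10000`; otherwise the asymptotic Kolmogorov
#' distribution is used.
#'
#' @param scoresA,scoresB Score values of the two groups ([ScoreVector]s
#'   or numeric vectors), both non-empty.
#' @param side `"two-sided"` (D = max |Fa - Fb|), `"greater"`
#'   (D+ = max(Fa - Fb)) or `"less"` (D- = max(Fb - Fa)).
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   p-value.
#' @return An [EnrichmentResult] with `statistic` = the D variant chosen.
#' @examples
#' ksEnrichment(c(1, 2, 3), c(4, 5, 6))  # fully separated: D = 1
#' @export
ksEnrichment <- function(scoresA, scoresB,
                         side = c("two-sided", "greater", "less"),
                         exact = NULL) {
  side <- match.arg(side)
  a <- if (methods::is(scoresA, "ScoreVector")) scoreValues(scoresA) else as.numeric(scoresA)
  b <- if (methods::is(scoresB, "ScoreVector")) scoreValues(scoresB) else as.numeric(scoresB)
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  info <- .ksDnum(a, b)
  dnum <- switch(side, "two-sided" = info$num_abs,
                 "greater" = info$num_plus, "less" = info$num_minus)
  d <- dnum / (info$na * info$nb)
  if (is.null(exact))
    exact <- !info$ties && info$na * info$nb <= 10000
  if (exact && info$ties) {
    warning("ties in the pooled sample: falling back to the asymptotic p-value")
    exact <- FALSE
  }
  if (exact) {
    signed <- switch(side, "two-sided" = 0L, "greater" = 1L, "less" = -1L)
    p <- if (dnum == 0) 1 else .ksExactP(dnum, info$na, info$nb, signed)
    method <- "exact"
  } else {
    p <- .ksAsymptoticP(d, info$na, info$nb, side)
    method <- "asymptotic"
  }
  new("EnrichmentResult", statistic = d, nes = NA_real_, pValue = p,
      pMethod = method, nPermutations = 0L, side = side,
      seed = NA_integer_)
}
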