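test_that("spearman handles monotone, antitone and undefined inputs", {
  expect_equal(rhoValue(spearmanCoactivation(c(1, 2, 3), c(10, 20, 30))), 1)
  expect_equal(rhoValue(spearmanCoactivation(c(1, 2, 3), c(3, 2, 1))), -1)
  expect_error(spearmanCoactivation(c(1, 1, 1), c(1, 2, 3)),
               "constant")
  expect_error(spearmanCoactivation(1:2, 1:2), "at least 3")
})

test_that("exact rho and p match full enumeration and cor.test", {
  r <- spearmanCoactivation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                            pMethod = "exact")
  o <- oracle_spearman_exact(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(rhoValue(r), o$rho)
  expect_equal(pValue(r), o$p)
  ct <- stats::cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                        method = "spearman")
  expect_equal(rhoValue(r), unname(ct$estimate))
  expect_equal(pValue(r), ct$p.value)

  set.seed(13)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- spearmanCoactivation(x, y, pMethod = "exact")
    o <- oracle_spearman_exact(x, y)
    expect_equal(rhoValue(r), o$rho, tolerance = 1e-12)
    expect_equal(pValue(r), o$p, tolerance = 1e-12)
  }
})

test_that("exact enumeration handles midrank ties", {
  x <- c(1, 2, 2, 3, 4)
  y <- c(5, 5, 7, 8, 9)
  r <- spearmanCoactivation(x, y, pMethod = "exact")
  o <- oracle_spearman_exact(x, y)
  expect_equal(rhoValue(r), o$rho)
  expect_equal(pValue(r), o$p)
})

test_that("rho is monotone-invariant and antisymmetric", {
  set.seed(3)
  x <- rnorm(30); y <- rnorm(30)
  r0 <- rhoValue(spearmanCoactivation(x, y))
  expect_equal(rhoValue(spearmanCoactivation(exp(x), y^3 + 5 * y)), r0)
  expect_equal(rhoValue(spearmanCoactivation(x, -y)), -r0)
})

test_that("Monte-Carlo permutation p agrees with exact p and is seeded", {
  set.seed(4)
  x <- rnorm(8); y <- x + rnorm(8, sd = 2)
  ex <- pValue(spearmanCoactivation(x, y, pMethod = "exact"))
  mc1 <- spearmanCoactivation(x, y, pMethod = "permutation",
                              nPermutations = 4000, seed = 7)
  mc2 <- spearmanCoactivation(x, y, pMethod = "permutation",
                              nPermutations = 4000, seed = 7)
  expect_identical(pValue(mc1), pValue(mc2))
  expect_lt(abs(pValue(mc1) - ex), 0.03)
  expect_error(spearmanCoactivation(x, y, pMethod = "permutation"),
               "seed")
})

test_that("exact permutation p-values are super-uniform under the null", {
  # full enumeration for n = 5,6: P(p <= a) <= a for every attainable a
  for (n in 5:6) {
    P <- oracle_perms(n)
    x <- seq_len(n)
    pv <- apply(P, 1L, function(y)
      pValue(spearmanCoactivation(x, as.numeric(y), pMethod = "exact")))
    for (a in c(0.01, 0.05, 0.1, 0.5))
      expect_lte(mean(pv <= a), a + 1e-12)
  }
})

test_that("gene-gene correlation mirrors the score machinery", {
  d <- simulateDataset(small_cfg(seed = 51))
  m <- logNormalize(d$matrix)
  r <- geneGeneCorrelation(m, "Sting1", "Sting1")
  expect_equal(rhoValue(r), 1)
  expect_error(geneGeneCorrelation(m, "Sting1", "NotAGene"), "NotAGene")
  # duplicated-with-vanishing-noise vector approaches rho = 1
  set.seed(1)
  x <- rnorm(200)
  rhos <- vapply(c(0.5, 1e-3, 1e-9), function(s)
    rhoValue(spearmanCoactivation(x, x + rnorm(200, sd = s))), 1)
  expect_true(all(diff(rhos) > 0))
  expect_gt(rhos[3], 0.9999)
})

test_that("tertile stratification yields balanced, rank-based groups", {
  st <- stratifyByScore(c(5, 1, 9, 3, 7, 2, 8, 4, 6), k = 3)
  g <- strataLabels(st)
  expect_equal(as.integer(table(g)), c(3L, 3L, 3L))
  expect_setequal(which(g == "low"), c(2, 4, 6))   # scores 1, 3, 2
  expect_setequal(which(g == "high"), c(3, 5, 7))  # scores 9, 7, 8
  expect_error(stratifyByScore(1:9, k = 1), "at least 2")
})

test_that("stratification matches the rank-then-chunk oracle under ties", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(5:40, 1); k <- sample(2:4, 1)
    vals <- sample(1:5, n, replace = TRUE)  # heavy ties
    st <- stratifyByScore(vals, k = k)
    lab <- as.integer(strataLabels(st))
    expect_identical(lab, oracle_stratify(vals, k))
    expect_lte(diff(range(tabulate(lab, k))), 1L)
  }
  st_const <- stratifyByScore(rep(3, 10), k = 3)
  expect_lte(diff(range(table(strataLabels(st_const)))), 1)
})

test_that("stratification depends only on score ranks", {
  set.seed(11)
  vals <- rnorm(50)
  st1 <- strataLabels(stratifyByScore(vals))
  st2 <- strataLabels(stratifyByScore(exp(vals) * 3 + 1))
  expect_identical(st1, st2)
})

test_that("contrasts across strata behave at the null and self-contrast", {
  vals <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  st <- stratifyByScore(vals)
  null_ct <- contrastAcrossStrata(st, rep(1, 9))
  expect_true(all(null_ct$contrasts$p_value == 1))
  expect_equal(null_ct$trend$J, null_ct$trend$mean)
  self_ct <- contrastAcrossStrata(st, vals)
  med <- self_ct$contrasts
  expect_true(all(med$median_b[med$group_a == "low"] >
                  med$median_a[med$group_a == "low"]))
  expect_equal(self_ct$trend$J, 27)  # all 27 cross-pairs concordant
  expect_lt(self_ct$trend$p_increasing, 0.01)
  expect_error(contrastAcrossStrata(st, rep(1, 5)), "aligned")
})

test_that("high-vs-low gene contrasts have forced signs", {
  genes <- c("Sting1", "Kdr", "Actb")
  set.seed(12)
  n <- 60
  sting <- c(rep(0, n / 2), rpois(n / 2, 20))
  kdr_hi <- c(rep(0, n / 2), rpois(n / 2, 15) + 1)
  counts <- rbind(Sting1 = sting, Kdr = kdr_hi, Actb = rpois(n, 10) + 1)
  colnames(counts) <- sprintf("c%02d", 1:n)
  m <- logNormalize(tiny_sce(counts))
  hl <- highLowGeneContrast(m, "Sting1", "Kdr")
  expect_gt(hl@log2FC, 0)
  expect_lt(pValue(hl), 0.01)
  # target identical in both groups (equal library sizes) -> log2FC = 0
  sting2 <- c(rep(0, n / 2), rep(20, n / 2))
  counts2 <- rbind(Sting1 = sting2, Kdr = 7, Actb = 30 - sting2)
  colnames(counts2) <- sprintf("c%02d", 1:n)
  m2 <- logNormalize(tiny_sce(counts2))
  hl2 <- highLowGeneContrast(m2, "Sting1", "Kdr")
  expect_equal(hl2@log2FC, 0)
  expect_equal(pValue(hl2), 1)
  hl3 <- highLowGeneContrast(m, "Sting1", "Kdr", mode = "tertile-extremes")
  expect_gt(hl3@log2FC, 0)
})
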