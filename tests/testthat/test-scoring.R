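test_that("signature scores are additive over signature genes", {
  m <- tiny_sce()  # Irf3/Tbk1/Actb x (c1, c2); c1 = (1,2,5), c2 = (0,0,7)
  sig <- GeneSignature("demo", c("Irf3", "Tbk1"))
  sv <- scoreSignature(m, sig, layer = "counts")
  expect_equal(unname(scoreValues(sv)), c(3, 0))
  expect_equal(sigCoverage(sv), 1)
  sv_mean <- scoreSignature(m, sig, layer = "counts", scale = "mean")
  expect_equal(unname(scoreValues(sv_mean)), c(1.5, 0))
})

test_that("missing signature genes reduce coverage, zero overlap errors", {
  m <- tiny_sce()
  sig <- GeneSignature("partial", c("Irf3", "NotAGene"))
  sv <- scoreSignature(m, sig, layer = "counts")
  expect_equal(sigCoverage(sv), 0.5)
  expect_identical(nGenesUsed(sv), 1L)
  expect_equal(unname(scoreValues(sv)), c(1, 0))
  expect_error(scoreSignature(m, GeneSignature("none", c("Xxx", "Yyy")),
                              layer = "counts"),
               "MissingSignature.*none")
})

test_that("scores are linear: disjoint signatures add, cell permutation permutes", {
  d <- simulateDataset(small_cfg(seed = 41))
  m <- logNormalize(d$matrix)
  sigs <- defaultSignatures()
  a <- sigGenes(sigs[["cGAS-STING"]])
  b <- sigGenes(sigs[["Angiogenesis"]])
  su <- scoreSignature(m, GeneSignature("union", c(a, b)))
  sa <- scoreSignature(m, sigs[["cGAS-STING"]])
  sb <- scoreSignature(m, sigs[["Angiogenesis"]])
  expect_equal(scoreValues(su), scoreValues(sa) + scoreValues(sb))
  perm <- sample(ncol(m))
  sp <- scoreSignature(m[, perm], sigs[["cGAS-STING"]])
  expect_equal(scoreValues(sp), scoreValues(sa)[perm])
})

test_that("signature matching goes through symbol harmonization", {
  # matrix uses canonical Sting1; the signature lists the Tmem173 alias
  counts <- matrix(c(4, 1, 2, 3), 2,
                   dimnames = list(c("Sting1", "Actb"), c("c1", "c2")))
  m <- tiny_sce(counts)
  sv <- scoreSignature(m, GeneSignature("s", "Tmem173"), layer = "counts")
  expect_equal(unname(scoreValues(sv)), c(4, 2))
  expect_equal(sigCoverage(sv), 1)
})

test_that("KS enrichment handles degenerate and separated groups", {
  same <- ksEnrichment(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 0)
  expect_equal(pValue(same), 1)
  sep <- ksEnrichment(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep@statistic, 1)
  expect_error(ksEnrichment(numeric(0), 1:3), "non-empty")
})

test_that("KS D and exact p match the enumeration oracle and ks.test", {
  set.seed(77)
  for (i in 1:20) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- round(rnorm(na), 3); b <- round(rnorm(nb, 0.5), 3)
    if (anyDuplicated(c(a, b))) next
    r <- ksEnrichment(a, b)
    expect_equal(r@statistic, oracle_ks_d(a, b))
    expect_equal(pValue(r), oracle_ks_exact_p(a, b), tolerance = 1e-12)
    kt <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(r@statistic, unname(kt$statistic))
    expect_equal(pValue(r), kt$p.value, tolerance = 1e-9)
  }
})

test_that("KS D is invariant under monotone transforms of both groups", {
  set.seed(8)
  a <- rexp(20); b <- rexp(25) * 1.5
  d0 <- ksEnrichment(a, b)@statistic
  for (f in list(function(x) x^3, log1p, function(x) 5 * x - 2)) {
    expect_equal(ksEnrichment(f(a), f(b))@statistic, d0)
  }
})

test_that("one-sided KS D+ reflects stochastic ordering", {
  a <- c(1, 2, 3, 4); b <- c(2.5, 3.5, 4.5, 5.5)
  rg <- ksEnrichment(a, b, side = "greater")
  rl <- ksEnrichment(a, b, side = "less")
  expect_equal(rg@statistic, oracle_ks_d(a, b, "greater"))
  expect_equal(rl@statistic, oracle_ks_d(a, b, "less"))
  expect_lt(pValue(rg), pValue(rl))
})

test_that("GSEA ES matches hand computation and the brute-force oracle", {
  r <- c(a = 3, b = 2, c = 1, d = 0.5)
  es <- gseaES(r, "a", weightP = 0, nPermutations = 50, seed = 1)
  expect_equal(es@statistic, 1)   # single hit at rank 1, unweighted
  set.seed(99)
  for (i in 1:40) {
    N <- sample(10:50, 1)
    genes <- paste0("g", seq_len(N))
    scores <- stats::setNames(round(rnorm(N), 4), genes)
    set_size <- sample(1:min(10, N - 1), 1)
    gs <- sample(genes, set_size)
    for (wp in c(0, 1)) {
      es_pkg <- gseaES(scores, gs, weightP = wp, nPermutations = 10,
                       seed = i)@statistic
      expect_equal(es_pkg, oracle_gsea_es(scores, gs, wp))
    }
  }
})

test_that("uniformly spread gene sets have vanishing unweighted ES", {
  es_at_N <- vapply(c(40, 400, 4000), function(N) {
    genes <- paste0("g", seq_len(N))
    scores <- stats::setNames(seq(N, 1), genes)
    gs <- genes[seq(4, N, by = 4)]  # every 4th position
    abs(gseaES(scores, gs, weightP = 0, nPermutations = 10,
               seed = 1)@statistic)
  }, 1)
  expect_true(all(diff(es_at_N) < 0))
  expect_lt(es_at_N[3], 0.01)
})

test_that("GSEA rejects degenerate gene sets", {
  r <- c(a = 2, b = 1)
  expect_error(gseaES(r, c("a", "b"), nPermutations = 10, seed = 1),
               "degenerate")
  expect_error(gseaES(r, "zzz", nPermutations = 10, seed = 1), "overlap")
})

test_that("GSEA permutation p-values are super-uniform under the null", {
  N <- 60
  genes <- paste0("g", seq_len(N))
  set.seed(123)
  pvals <- vapply(1:400, function(b) {
    scores <- stats::setNames(rnorm(N), genes)
    gs <- sample(genes, 8)
    pValue(gseaES(scores, gs, weightP = 1, nPermutations = 99, seed = b))
  }, 1)
  # empirical rejection at 0.05 within binomial 99% bounds around 0.05
  phat <- mean(pvals <= 0.05)
  bound <- 2.576 * sqrt(0.05 * 0.95 / length(pvals))
  expect_lte(phat, 0.05 + bound)
})

test_that("group summaries normalize cell counts to the largest group", {
  scores <- c(rep(2, 100), rep(4, 50))
  groups <- c(rep("P6", 100), rep("P12", 50))
  tab <- summarizeByGroup(scores, factor(groups, levels = c("P6", "P12")))
  expect_equal(tab$normalized_n, c(1, 0.5))
  expect_equal(tab$mean, c(2, 4))
  expect_equal(tab$median, c(2, 4))
  expect_equal(tab$total, c(200, 200))
  one <- summarizeByGroup(1:5, rep("only", 5))
  expect_equal(one$normalized_n, 1)
  # unknown labels form their own group
  tab2 <- summarizeByGroup(1:4, c("a", "a", "b", "mystery"))
  expect_setequal(tab2$group, c("a", "b", "mystery"))
})
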