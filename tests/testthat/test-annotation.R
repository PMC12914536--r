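make_panel <- function() {
  MarkerPanel(MarkerSet("Endothelial", c("Pecam1", "Cdh5", "Kdr")),
              MarkerSet("Rod", c("Rho", "Nrl")),
              MarkerSet("Microglia", c("Cx3cr1", "C1qa")))
}

test_that("argmax annotation labels a cell by its expressed markers", {
  genes <- c("Pecam1", "Cdh5", "Kdr", "Rho", "Nrl", "Cx3cr1", "C1qa")
  counts <- matrix(0, length(genes), 2,
                   dimnames = list(genes, c("ec", "rod")))
  counts[c("Pecam1", "Cdh5", "Kdr"), "ec"] <- 5
  counts[c("Rho", "Nrl"), "rod"] <- 5
  m <- logNormalize(tiny_sce(counts))
  ann <- annotateCells(m, make_panel())
  expect_identical(unname(cellLabels(ann)[["ec"]]), "Endothelial")
  expect_identical(unname(cellLabels(ann)[["rod"]]), "Rod")
  expect_true(all(labelMargin(ann) >= 0))
})

test_that("tied marker scores abstain to 'unassigned'", {
  genes <- c("Pecam1", "Cdh5", "Kdr", "Rho", "Nrl", "Cx3cr1", "C1qa")
  # uniform expression across all markers makes every panel score equal
  counts2 <- matrix(4, length(genes), 1, dimnames = list(genes, "c1"))
  m2 <- logNormalize(tiny_sce(counts2))
  ann2 <- annotateCells(m2, make_panel(), minMargin = 0.1)
  expect_identical(unname(cellLabels(ann2)[["c1"]]), "unassigned")
  ann3 <- annotateCells(m2, make_panel())  # ties abstain even at margin 0
  expect_identical(unname(cellLabels(ann3)[["c1"]]), "unassigned")
})

test_that("annotation is invariant to gene and cell order", {
  d <- simulateDataset(small_cfg(seed = 21))
  m <- logNormalize(d$matrix)
  ann <- suppressWarnings(annotateCells(m, defaultMarkerPanel()))
  gperm <- sample(nrow(m)); cperm <- sample(ncol(m))
  ann2 <- suppressWarnings(annotateCells(m[gperm, cperm],
                                         defaultMarkerPanel()))
  expect_identical(cellLabels(ann2), cellLabels(ann)[cperm])
})

test_that("raising min_margin only moves labels to 'unassigned'", {
  d <- simulateDataset(small_cfg(seed = 22))
  m <- logNormalize(d$matrix)
  a0 <- suppressWarnings(annotateCells(m, defaultMarkerPanel(),
                                       minMargin = 0))
  a1 <- suppressWarnings(annotateCells(m, defaultMarkerPanel(),
                                       minMargin = 0.5))
  changed <- cellLabels(a1) != cellLabels(a0)
  expect_true(all(cellLabels(a1)[changed] == "unassigned"))
})

test_that("marker-based annotation recovers the generator's labels", {
  accs <- vapply(1:3, function(s) {
    d <- simulateDataset(small_cfg(seed = 100 + s))
    m <- logNormalize(d$matrix)
    ann <- suppressWarnings(annotateCells(m, defaultMarkerPanel()))
    mean(cellLabels(ann) == truthLabels(d$truth))
  }, 1)
  expect_true(all(accs >= 0.95))
})

test_that("endothelial selection keeps exactly the EC-labeled cells", {
  d <- simulateDataset(small_cfg(seed = 23))
  m <- logNormalize(d$matrix)
  ann <- suppressWarnings(annotateCells(m, defaultMarkerPanel()))
  ec <- selectEndothelial(m, ann)
  expect_identical(colnames(ec),
                   names(which(cellLabels(ann) == "Endothelial")))
  expect_identical(SummarizedExperiment::colData(ec)$stage,
                   SummarizedExperiment::colData(m)[colnames(ec), "stage"])
  # subset-then-score equals score-then-subset
  sig <- defaultSignatures()[["cGAS-STING"]]
  s_sub <- scoreValues(scoreSignature(ec, sig))
  s_all <- scoreValues(scoreSignature(m, sig))[colnames(ec)]
  expect_equal(s_sub, s_all)
  # all-EC annotation is the identity subset
  ann_all <- ann
  lbl <- cellLabels(ann)
  lbl[] <- "Endothelial"
  ann_all@labels <- lbl
  expect_identical(colnames(selectEndothelial(m, ann_all)), colnames(m))
  # and zero ECs is an error advising a panel check
  lbl[] <- "Rod"
  ann_none <- ann
  ann_none@labels <- lbl
  expect_error(selectEndothelial(m, ann_none), "panel")
})

test_that("quantile-mode angiogenic calls pick the top quantile exactly", {
  genes <- c("Mki67", "Cxcr4", "Dll4", "Aplnr", "Esm1")
  counts <- matrix(0, 5, 8, dimnames = list(genes, paste0("ec", 1:8)))
  counts[1, ] <- c(1, 2, 3, 4, 5, 6, 7, 8) * 10
  counts[2, ] <- 1  # keep totals positive
  m <- tiny_sce(counts)
  call <- callAngiogenic(m, method = "quantile", cutoff = 0.75,
                         layer = "counts")
  expect_identical(sum(isAngiogenic(call)), 2L)
  expect_identical(names(which(isAngiogenic(call))), c("ec7", "ec8"))
  # zero expression of every marker is never angiogenic under a threshold
  counts0 <- counts; counts0[, 1] <- c(0, 0, 0, 0, 0)
  counts0["Cxcr4", 1] <- 0; counts0[1, 1] <- 0
  counts0 <- rbind(counts0, Actb = 1)
  m0 <- logNormalize(tiny_sce(counts0))
  call0 <- callAngiogenic(m0, method = "threshold", cutoff = 1e-6)
  expect_false(isAngiogenic(call0)[["ec1"]])
})

test_that("angiogenic recall against generator truth is high", {
  recalls <- vapply(1:2, function(s) {
    d <- simulateDataset(syntheticConfig(seed = 300 + s))
    m <- logNormalize(d$matrix)
    ec_cells <- names(which(truthLabels(d$truth) == "Endothelial"))
    call <- callAngiogenic(m[, ec_cells])
    fl <- truthAngiogenic(d$truth)[ec_cells]
    sum(isAngiogenic(call) & fl) / sum(fl)
  }, 1)
  expect_true(all(recalls >= 0.9))
})

test_that("angiogenic fraction tracks 1 - q for distinct scores", {
  d <- simulateDataset(small_cfg(seed = 31))
  m <- logNormalize(d$matrix)
  ec_cells <- names(which(truthLabels(d$truth) == "Endothelial"))
  for (q in c(0.5, 0.75, 0.9)) {
    call <- callAngiogenic(m[, ec_cells], cutoff = q)
    frac <- mean(isAngiogenic(call))
    expect_lt(abs(frac - (1 - q)), 0.05)
  }
})
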