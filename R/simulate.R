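# Negative-binomial scRNA-seq simulator with a known latent co-activation
# structure: multiple cell types with distinct marker programs, an
# endothelial subset carrying a bivariate latent (cGAS-STING activity,
# angiogenesis activity) with configurable correlation rho, and optional
# developmental-stage and batch structure.

#' Build a synthetic-dataset configuration
#'
#' Defaults describe a well-separated multi-type retinal tissue: five cell
#' types with literature-standard marker programs, an endothelial subset
#' (20% of cells) whose bivariate latent activities have correlation
#' `rho`, negative-binomial counts with the signature genes of the two
#' packaged pathway programs loading log-linearly on their latent, and an
#' angiogenic EC subpopulation (a fixed 25% of ECs) carrying the
#' activation-marker program.
#'
#' @param nCells Total number of cells.
#' @param typeProportions Named fractions per cell type, summing to 1;
#'   names must match the marker panel's cell types.
#' @param nGenes Total genes (signature + marker genes plus filler).
#' @param fillerMean Baseline NB mean of the filler genes. Fillers stand
#'   in for the rest of the transcriptome: their aggregate mass sets the
#'   per-cell library size, so the default (5, against `baseMean = 1`
#'   program genes and ~1000 genes total) reproduces the small library
#'   fraction that signature genes occupy in real data. This matters
#'   because library-size normalization couples gene groups
#'   compositionally; a gene-poor simulation with a small library would
#'   induce spurious negative co-activation between the two scored
#'   programs.
#' @param rho Latent Pearson correlation of (a_sting, a_angio) in the EC
#'   subset, in \[-1, 1\].
#' @param loading Latent-to-log-mean effect size for signature genes.
#' @param baseMean Baseline NB mean per gene per cell.
#' @param nbDispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param noiseSd SD of the per-cell-per-gene Gaussian noise on the
#'   log-mean.
#' @param markerLogFC Log-fold elevation of a type's markers in its cells.
#' @param activationLogFC Log-fold elevation of activation markers in
#'   angiogenic ECs.
#' @param angiogenicFraction Fraction of ECs carrying the activation
#'   program (flagged count is exactly `round(fraction * nEC)`).
#' @param batchEffectSd SD of per-(gene, batch) log-mean shifts (0 = off).
#' @param nBatches Number of batches (cells assigned round-robin).
#' @param stageLabels Optional character vector of developmental stages;
#'   cells are split evenly across stages.
#' @param stageRho Optional per-stage latent correlation (same length as
#'   `stageLabels`); defaults to `rho` everywhere.
#' @param seed Integer RNG seed; the simulation is fully determined by
#'   the configuration including this seed.
#' @param ecType Label of the endothelial type in `typeProportions`.
#' @param stingGenes,angioGenes,activationGenes Gene symbol vectors of
#'   the two scored programs and the activation markers; defaults are the
#'   packaged signatures, harmonized to canonical mouse symbols.
#' @param markerPanel A [MarkerPanel]; defaults to the packaged retinal
#'   panel.
#' @return A validated configuration list of class `coact_config`.
#' @export
syntheticConfig <- function(nCells = 2000,
                            typeProportions = c(Endothelial = 0.2,
                                                Rod = 0.4, Bipolar = 0.15,
                                                Muller = 0.15,
                                                Microglia = 0.1),
                            nGenes = 1000, rho = 0.6, loading = 0.8,
                            baseMean = 1, fillerMean = 5,
                            nbDispersion = 0.5,
                            noiseSd = 0.3, markerLogFC = 2.5,
                            activationLogFC = 2,
                            angiogenicFraction = 0.25,
                            batchEffectSd = 0, nBatches = 1,
                            stageLabels = NULL, stageRho = NULL,
                            seed = 1, ecType = "Endothelial",
                            stingGenes = NULL, angioGenes = NULL,
                            activationGenes = NULL, markerPanel = NULL) {
  if (is.null(markerPanel)) markerPanel <- defaultMarkerPanel()
  sigs <- NULL
  getSig <- function(nm) {
    if (is.null(sigs)) sigs <<- defaultSignatures()
    harmonizeGenes(sigGenes(sigs[[nm]]), "mouse", "mouse")
  }
  if (is.null(stingGenes)) stingGenes <- getSig("cGAS-STING")
  if (is.null(angioGenes)) angioGenes <- getSig("Angiogenesis")
  if (is.null(activationGenes))
    activationGenes <- getSig("Endothelial activation/proliferation")
  cfg <- list(nCells = as.integer(nCells),
              typeProportions = typeProportions, nGenes = as.integer(nGenes),
              rho = rho, loading = loading, baseMean = baseMean,
              fillerMean = fillerMean,
              nbDispersion = nbDispersion, noiseSd = noiseSd,
              markerLogFC = markerLogFC, activationLogFC = activationLogFC,
              angiogenicFraction = angiogenicFraction,
              batchEffectSd = batchEffectSd, nBatches = as.integer(nBatches),
              stageLabels = stageLabels, stageRho = stageRho,
              seed = as.integer(seed), ecType = ecType,
              stingGenes = as.character(stingGenes),
              angioGenes = as.character(angioGenes),
              activationGenes = as.character(activationGenes),
              markerPanel = markerPanel)
  class(cfg) <- "coact_config"
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  tp <- cfg$typeProportions
  if (is.null(names(tp)) || any(!nzchar(names(tp))))
    stop("'typeProportions' must be named by cell type")
  if (any(tp < 0) || abs(sum(tp) - 1) > 1e-8)
    stop("'typeProportions' must be non-negative and sum to 1")
  if (!cfg$ecType %in% names(tp))
    stop(sprintf("'ecType' (%s) must appear in typeProportions", cfg$ecType))
  if (abs(cfg$rho) > 1) stop("'rho' must lie in [-1, 1]")
  for (f in c("loading", "baseMean", "fillerMean", "nbDispersion"))
    if (cfg[[f]] < 0 || (f != "loading" && cfg[[f]] <= 0))
      stop(sprintf("'%s' must be positive", f))
  if (cfg$noiseSd < 0 || cfg$batchEffectSd < 0)
    stop("noise and batch-effect SDs must be non-negative")
  if (cfg$angiogenicFraction < 0 || cfg$angiogenicFraction > 1)
    stop("'angiogenicFraction' must lie in [0, 1]")
  if (!is.null(cfg$stageLabels)) {
    if (is.null(cfg$stageRho)) cfg$stageRho <- rep(cfg$rho, length(cfg$stageLabels))
    if (length(cfg$stageRho) != length(cfg$stageLabels))
      stop("'stageRho' must match 'stageLabels' in length")
    if (any(abs(cfg$stageRho) > 1)) stop("stage rho values must lie in [-1, 1]")
  }
  named <- unique(c(cfg$stingGenes, cfg$angioGenes, cfg$activationGenes,
                    unlist(lapply(cfg$markerPanel, function(s) s@markers))))
  if (cfg$nGenes < length(named))
    stop(sprintf("'nGenes' (%d) is smaller than the number of named genes (%d)",
                 cfg$nGenes, length(named)))
  overlap <- intersect(cfg$stingGenes, cfg$angioGenes)
  if (length(overlap))
    message(sprintf("note: the two scored programs share genes (%s); shared genes inflate score co-activation by construction",
                    paste(overlap, collapse = ", ")))
  invisible(cfg)
}

# deterministic largest-remainder allocation of n cells to proportions
.allocateCells <- function(n, props) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a single-cell dataset with known co-activation
#'
#' Draws, per endothelial cell, a bivariate-normal latent activity pair
#' with correlation `rho`; counts are negative-binomial with
#' `mu = baseMean * exp(loading * a + markers + batch + noise)`, where the
#' matching latent applies to the signature genes of ECs, a fixed
#' log-fold elevation to each type's marker genes, and the activation
#' program to a flagged EC subpopulation. The draw order is fixed
#' (latents, flags, batch shifts, noise, counts), so the output is fully
#' determined by the configuration.
#'
#' @param cfg A configuration from [syntheticConfig()].
#' @return List with `matrix` (a SingleCellExperiment with `counts`;
#'   stage and batch in the cell metadata) and `truth`
#'   (a [SyntheticTruth]).
#' @examples
#' d <- simulateDataset(syntheticConfig(nCells = 100, seed = 7))
#' dim(d$matrix)
#' @export
simulateDataset <- function(cfg) {
  .validateConfig(cfg)
  nC <- cfg$nCells; nG <- cfg$nGenes
  types <- names(cfg$typeProportions)
  sizes <- .allocateCells(nC, cfg$typeProportions)
  labels <- rep(types, sizes)
  cells <- sprintf("cell%05d", seq_len(nC))
  names(labels) <- cells

  panel_genes <- lapply(cfg$markerPanel, function(s)
    harmonizeGenes(s@markers, "mouse", "mouse"))
  names(panel_genes) <- names(cfg$markerPanel)
  named <- unique(c(cfg$stingGenes, cfg$angioGenes, cfg$activationGenes,
                    unlist(panel_genes)))
  genes <- c(named, sprintf("Filler%04d", seq_len(nG - length(named))))

  stages <- if (is.null(cfg$stageLabels)) "P6" else cfg$stageLabels
  stage_rho <- if (is.null(cfg$stageLabels)) cfg$rho
               else if (is.null(cfg$stageRho)) rep(cfg$rho, length(stages))
               else cfg$stageRho
  stage_of <- stages[((seq_len(nC) - 1L) %% length(stages)) + 1L]
  batch_of <- ((seq_len(nC) - 1L) %% cfg$nBatches) + 1L

  ec <- which(labels == cfg$ecType)
  nEC <- length(ec)

  out <- .withSeed(cfg$seed, {
    # 1. latents (ECs only), per stage rho
    aS <- aA <- numeric(nEC)
    z1 <- stats::rnorm(nEC); z2 <- stats::rnorm(nEC)
    r_ec <- stage_rho[match(stage_of[ec], stages)]
    aS <- z1
    aA <- r_ec * z1 + sqrt(1 - r_ec^2) * z2
    # 2. angiogenic flags: deterministic count, random positions
    nFlag <- round(cfg$angiogenicFraction * nEC)
    flag <- logical(nEC)
    if (nFlag > 0 && nEC > 0) flag[sample.int(nEC, nFlag)] <- TRUE
    # 3. batch shifts
    batch_shift <- if (cfg$nBatches > 1L && cfg$batchEffectSd > 0)
      matrix(stats::rnorm(nG * cfg$nBatches, 0, cfg$batchEffectSd),
             nG, cfg$nBatches)
    else matrix(0, nG, cfg$nBatches)
    # 4. log-mean: named program genes at baseMean, fillers at fillerMean
    logmu <- matrix(log(cfg$baseMean), nG, nC)
    if (nG > length(named))
      logmu[(length(named) + 1L):nG, ] <- log(cfg$fillerMean)
    si <- match(cfg$stingGenes, genes)
    ai <- match(cfg$angioGenes, genes)
    if (nEC > 0) {
      logmu[si, ec] <- logmu[si, ec] +
        matrix(cfg$loading * aS, length(si), nEC, byrow = TRUE)
      logmu[ai, ec] <- logmu[ai, ec] +
        matrix(cfg$loading * aA, length(ai), nEC, byrow = TRUE)
      vi <- match(cfg$activationGenes, genes)
      fcells <- ec[flag]
      if (length(fcells))
        logmu[vi, fcells] <- logmu[vi, fcells] + cfg$activationLogFC
    }
    for (ty in types) {
      gi <- match(panel_genes[[ty]], genes)
      ci <- which(labels == ty)
      if (length(ci)) logmu[gi, ci] <- logmu[gi, ci] + cfg$markerLogFC
    }
    logmu <- logmu + batch_shift[, batch_of]
    # 5. noise, 6. counts
    if (cfg$noiseSd > 0)
      logmu <- logmu + matrix(stats::rnorm(nG * nC, 0, cfg$noiseSd), nG, nC)
    counts <- matrix(
      stats::rnbinom(nG * nC, size = 1 / cfg$nbDispersion, mu = exp(logmu)),
      nG, nC, dimnames = list(genes, cells))
    list(counts = counts, aS = aS, aA = aA, flag = flag)
  })

  cmeta <- S4Vectors::DataFrame(stage = stage_of, batch = batch_of,
                                row.names = cells)
  sce <- .makeSCE(methods::as(out$counts, "CsparseMatrix"), cmeta, "mouse")
  cfg_echo <- cfg
  cfg_echo$markerPanel <- lapply(cfg$markerPanel, function(s)
    list(cellType = s@cellType, markers = s@markers))
  truth <- new("SyntheticTruth",
               latent = S4Vectors::DataFrame(cell = cells[ec],
                                             aSting = out$aS,
                                             aAngio = out$aA),
               labels = labels,
               angiogenicFlag = stats::setNames(out$flag, cells[ec]),
               config = unclass(cfg_echo))
  list(matrix = sce, truth = truth)
}

#' Write a simulated dataset as a plain-text fixture
#'
#' Emits the MatrixMarket bundle ([writeMatrix()]), a `truth.tsv` with the
#' per-cell labels and EC latents, and a `config.json` from which the
#' fixture regenerates bit-identically.
#'
#' @param dataset,truth The two elements returned by [simulateDataset()].
#' @param path Output directory.
#' @return Invisibly, `path`.
#' @export
writeFixture <- function(dataset, truth, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeMatrix(dataset, path, format = "mtx_dir")
  lat <- as.data.frame(truthLatent(truth))
  labs <- truthLabels(truth)
  df <- data.frame(cell = names(labs), cell_type = unname(labs),
                   stringsAsFactors = FALSE)
  df$a_sting <- lat$aSting[match(df$cell, lat$cell)]
  df$a_angio <- lat$aAngio[match(df$cell, lat$cell)]
  fl <- truthAngiogenic(truth)
  df$angiogenic <- fl[match(df$cell, names(fl))]
  utils::write.table(df, file.path(path, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- truthConfig(truth)
  cfg$markerPanel <- cfg$markerPanel  # already plain lists in the echo
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
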