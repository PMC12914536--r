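# Parameter-recovery and calibration harnesses: run the full pipeline
# (simulate -> normalize -> annotate -> select ECs -> score -> correlate)
# against the generator's ground truth.

# Frozen calibration of the generator's rank attenuation at default
# loading/noise: the per-cell signature scores are noisy monotone readouts
# of the Gaussian latents, so the estimated score-level Spearman rho is a
# shrunken version of the latent rho. The attenuation factor was measured
# once from the generator at defaults (full pipeline, n_EC = 2000, latent
# rho = 0.6, 20 seeds: mean estimate 0.506, seed-level sd 0.015) and
# frozen; the band is mean +/- 0.06 (about 4 seed-level SDs). See the
# methods vignette.
.CALIBRATION <- list(rho = 0.6, attenuation = 0.8436, band_halfwidth = 0.06)

#' Frozen calibration band for co-activation recovery
#'
#' @return List with the reference latent `rho` (0.6), the measured
#'   `attenuation` factor of the score-level Spearman estimate at default
#'   generator settings, and the `band` (lower, upper) within which the
#'   mean estimate is expected to fall.
#' @export
calibrationBand <- function() {
  ctr <- .CALIBRATION$attenuation * .CALIBRATION$rho
  list(rho = .CALIBRATION$rho, attenuation = .CALIBRATION$attenuation,
       band = c(lower = ctr - .CALIBRATION$band_halfwidth,
                upper = ctr + .CALIBRATION$band_halfwidth))
}

# one full-pipeline co-activation estimate on a simulated dataset
.pipelineRhoHat <- function(cfg, annotate = TRUE) {
  d <- simulateDataset(cfg)
  m <- logNormalize(d$matrix)
  if (annotate) {
    ann <- suppressWarnings(annotateCells(m, cfg$markerPanel))
    m <- selectEndothelial(m, ann, label = cfg$ecType)
  }
  sigs <- defaultSignatures()
  sx <- scoreSignature(m, sigs[["cGAS-STING"]])
  sy <- scoreSignature(m, sigs[["Angiogenesis"]])
  res <- spearmanCoactivation(sx, sy, pMethod = "t-approximation",
                              subset = "endothelial cells")
  list(rho_hat = rhoValue(res), p = pValue(res), n = res@n, truth = d$truth)
}

#' Latent-correlation recovery experiment
#'
#' For every latent correlation in `rhoGrid` and every seed, simulates a
#' dataset, runs the full pipeline (normalize, marker-based annotation,
#' EC selection, scoring of the two packaged pathway signatures, Spearman
#' co-activation), and summarizes the estimates. `coverage` is the
#' fraction of seeds whose Fisher-z 95% confidence interval for the
#' estimate covers the attenuation-adjusted expectation
#' `attenuation * rho` (see [calibrationBand()]).
#'
#' @param rhoGrid Latent correlations, each in \[-1, 1\].
#' @param nSeeds Seeds per grid point (>= 2).
#' @param cfgBase Base configuration ([syntheticConfig()]); `rho` and
#'   `seed` are overridden per run.
#' @param baseSeed Offset from which per-run seeds are derived.
#' @return List with `table` (data.frame: rho_true, mean_rho_hat, sd,
#'   coverage, mean_n_ec) and `monotone` (TRUE when mean_rho_hat is
#'   strictly increasing in rho_true).
#' @export
recoveryExperiment <- function(rhoGrid, nSeeds = 10, cfgBase = syntheticConfig(),
                               baseSeed = 20000) {
  if (any(abs(rhoGrid) > 1)) stop("grid values must lie in [-1, 1]")
  if (nSeeds < 2) stop("'nSeeds' must be at least 2")
  att <- .CALIBRATION$attenuation
  rows <- lapply(seq_along(rhoGrid), function(gi) {
    rho <- rhoGrid[gi]
    est <- vapply(seq_len(nSeeds), function(s) {
      cfg <- cfgBase
      cfg$rho <- rho
      cfg$seed <- as.integer(baseSeed + 1000L * gi + s)
      r <- .pipelineRhoHat(cfg)
      c(r$rho_hat, r$n)
    }, numeric(2))
    rho_hat <- est[1L, ]; n_ec <- est[2L, ]
    z <- atanh(pmin(pmax(rho_hat, -0.999999), 0.999999))
    half <- 1.96 / sqrt(pmax(n_ec - 3, 1))
    target <- att * rho
    cov <- mean(tanh(z - half) <= target & target <= tanh(z + half))
    data.frame(rho_true = rho, mean_rho_hat = mean(rho_hat),
               sd_rho_hat = stats::sd(rho_hat), coverage = cov,
               mean_n_ec = mean(n_ec))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, monotone = all(diff(tab$mean_rho_hat) > 0))
}

#' Type-I error calibration of the co-activation test under the null
#'
#' Simulates independent EC-only subsets with latent rho = 0, runs the
#' scoring and Spearman test on each, and reports the rejection rate at
#' the nominal level. Under correct calibration the rate is close to
#' `alpha`.
#'
#' @param nSubsets Number of independent subsets (default 2000).
#' @param nCells Cells per subset (default 200).
#' @param alpha Nominal level (default 0.05).
#' @param baseSeed Offset from which per-subset seeds are derived.
#' @param nGenes Genes per simulated subset (generator default).
#' @return List with `rejection_rate`, `nSubsets`, `alpha` and the
#'   vector of p-values.
#' @export
nullCalibration <- function(nSubsets = 2000, nCells = 200, alpha = 0.05,
                            baseSeed = 50000, nGenes = 1000) {
  sigs <- defaultSignatures()
  sx <- sigs[["cGAS-STING"]]; sy <- sigs[["Angiogenesis"]]
  pvals <- vapply(seq_len(nSubsets), function(i) {
    cfg <- syntheticConfig(nCells = nCells,
                           typeProportions = c(Endothelial = 1),
                           nGenes = nGenes, rho = 0,
                           seed = as.integer(baseSeed + i))
    d <- simulateDataset(cfg)
    m <- logNormalize(d$matrix)
    res <- spearmanCoactivation(scoreSignature(m, sx), scoreSignature(m, sy),
                                pMethod = "t-approximation",
                                subset = "simulated EC subset")
    pValue(res)
  }, numeric(1))
  list(rejection_rate = mean(pvals < alpha), nSubsets = nSubsets,
       alpha = alpha, p_values = pvals)
}
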