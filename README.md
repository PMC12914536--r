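# coactivate

Gene-signature scoring and pathway co-activation analysis for
single-cell and bulk transcriptomics.

## The problem

Innate-immune cGAS-STING signaling and the angiogenesis program are both
active in retinal endothelial cells (ECs) — in the fibrovascular
membranes of proliferative diabetic retinopathy, in the developing
postnatal mouse retina, and in adult retinas across species. The
analytical question is whether the two transcriptional programs are
**co-activated at the cell level**: do cells with a more active
cGAS-STING program also carry a more active angiogenesis program?

`coactivate` is for computational biologists who want that analysis as a
tested, reproducible pipeline rather than a notebook: additive per-cell
signature scores, enrichment statistics, rank-correlation co-activation
tests with exact small-sample p-values, marker-based cell selection,
activity stratification — and a negative-binomial simulator with known
latent co-activation so every stage is verifiable by parameter recovery.

## The statistics at the core

For a gene signature $G$ and cell $c$ with log-normalized expression
$x_{c,g} = \log(1 + 10^4\,k_{c,g}/\sum_g k_{c,g})$, the signature score
is the additive readout

$$ s_c(G) = \sum_{g \in G} x_{c,g}, $$

and co-activation of two signatures on a cell subset is Spearman's
rank correlation $\rho$ between $s_\cdot(G_1)$ and $s_\cdot(G_2)$, with
a p-value by full permutation enumeration (n ≤ 9), seeded Monte-Carlo
permutation, or the t-approximation. Around that core sit a two-sample
Kolmogorov-Smirnov test with an exact lattice-path p-value (group
contrasts), the weighted GSEA running-sum statistic with a gene-label
permutation null, tertile stratification with rank-sum and
Jonckheere-Terpstra trend tests, and high-vs-low single-gene contrasts
($\log_2$ fold change with $\varepsilon = 10^{-9}$).

Four pathway signatures are packaged (mouse symbols): cGAS-STING
(20 genes), Angiogenesis (27), Hallmark angiogenesis (36), and the
endothelial activation/proliferation markers (Mki67, Cxcr4, Dll4,
Aplnr, Esm1) used to call angiogenic ECs. Cross-species symbol
harmonization (case conventions plus a curated alias table:
Tmem173→Sting1, Mb21d1→Cgas, Figf→Vegfd, Pigf→Pgf, ...) is applied at
every matching step.

## Worked example

Simulate a 2000-cell retina-like tissue whose ECs carry latent
co-activation ρ = 0.6, then run the full pipeline:

```r
library(coactivate)

cfg <- syntheticConfig(nCells = 2000, rho = 0.6, seed = 42)
d   <- simulateDataset(cfg)
m   <- logNormalize(d$matrix)

ann <- annotateCells(m, defaultMarkerPanel())
ann
#> AnnotationResult on 2000 cells:
#>     Bipolar Endothelial   Microglia      Muller         Rod
#>         302         400         198         300         800

ec   <- selectEndothelial(m, ann)
sigs <- defaultSignatures()
sx   <- scoreSignature(ec, sigs[["cGAS-STING"]])
sy   <- scoreSignature(ec, sigs[["Angiogenesis"]])

spearmanCoactivation(sx, sy, subset = "endothelial cells")
#> CoactivationResult: cGAS-STING vs Angiogenesis on endothelial cells
#>   n = 400, rho = 0.4491, p = 3.026e-21 (t-approximation)
```

The estimate 0.449 is the expected attenuated readout of the latent
ρ = 0.6: scores are noisy monotone functions of the latent activities,
and the package's measured attenuation factor at default settings is
0.844 (`calibrationBand()`), so ≈ 0.84 × 0.6 ≈ 0.51 on average at 2000
ECs (here n = 400, hence more seed-to-seed spread). Stratifying ECs by
cGAS-STING activity shows the angiogenesis score rising across strata:

```r
st <- stratifyByScore(sx)           # low / mid / high tertiles
ct <- contrastAcrossStrata(st, sy)
ct$contrasts
#>   group_a group_b n_a n_b median_a median_b     W      p_value
#> 1     low     mid 134 133 15.26819 21.43681 11997 1.004807e-06
#> 2     low    high 134 133 15.26819 26.56710 13661 5.143261e-14
#> 3     mid    high 133 133 21.43681 26.56710 11074 3.808856e-04
ct$trend
#> trend z = 8.00, one-sided p = 6.43e-16
```

Real datasets enter the same pipeline through
`readMatrix(dir, "mtx_dir")` (10x-style MatrixMarket bundles) or
delimited text, and `runPipeline()` / `pipelinePreset()` wrap the whole
sequence into configured, logged, manifest-carrying runs
(`inst/scripts/coactivate` is a thin command-line wrapper).

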