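# GenomicRRM

Random regression models (RRM) for the genomic analysis of **longitudinal
traits** in genotyped inbred crop panels — the motivating case is
above-ground biomass of soybean recombinant inbred lines tracked from 27
to 83 days after planting (DAP). Quantitative geneticists and breeders can
use it to estimate how genetic control of a developing trait changes over
time, predict breeding-value *trajectories* for selection at any day in
the modeled window, and find SNPs whose effects are confined to specific
developmental periods.

## The model

For line *i* on day *t* in environment–replication *k*:

```
y_ijk = Env_k + Σ_m b_m φ_m(t) + Σ_m a_im φ_m(t) + e_ijk
var(a) = G ⊗ G0,   var(e) = I ⊗ R
```

* `φ_m` — covariance-function basis: normalized Legendre polynomials on
  standardized time, or clamped B-splines (degree 1–2) with interior knots
  (e.g. at 44 and 66 DAP).
* `G` — VanRaden genomic relationship matrix, `Z Z′ / 2Σp(1−p)`, from
  QC-filtered SNP dosages (MAF ≥ 0.05, call rate ≥ 0.90 by default).
* `G0` — covariance of the random regression coefficients, estimated
  together with per-DAP-class residual variances by AI-REML (with EM
  fallback); candidate bases are compared by AIC.
* Time-scale parameters: `Σ = T G0 T′`, heritability
  `h²(j) = Σjj/(Σjj + σ²e(j))`, genetic correlations
  `r(j,j′) = Σjj′/√(Σjj Σj′j′)`, breeding-value trajectories
  `GEBV_i = T ĝ_i`.
* Genomic prediction is evaluated by k-fold cross-validation (accuracy =
  per-DAP correlation of full-data vs reduced-data GEBV over validation
  lines; bias = regression slope of full on reduced).
* The longitudinal GWAS back-solves per-coefficient SNP effects
  `û_m = Z′(Z Z′)⁻¹ ĝ_m`, projects them over time (`T û_s`), ranks the
  top-10 per day by effect magnitude, classifies effect durations
  (long / mid / short / intermittent), and intersects ±25 kb candidate
  windows with a user annotation (BED/GFF3).

A synthetic-data module generates a SoyNAM-like RIL panel (biparental
families of inbred founder mosaics) and phenotypes from exactly this
generative model with full ground truth, so the whole pipeline is testable
without any external data. See `vignettes/GenomicRRM-methods.Rmd` for the
methods account and every numerical design decision.

## Worked example

```r
library(GenomicRRM)

panel <- simulateRilGenotypes(nFamilies = 8, linesPerFamily = 8,
                              nSnps = 800, nChrom = 10, seed = 42)
basis <- timeBasis("bspline", degree = 1, knots = c(44, 66))
h2    <- 0.3 - 0.25 * (1 - abs(standardizeTime(27:83, 27, 83)))  # V-shaped
sim   <- simulatePhenotypes(panel, basis, h2Profile = h2, sigma2e = 1,
                            seed = 42)
grm   <- vanRadenGRM(panel)
fit   <- remlEstimate(sim$phenotypes, basis, grm,
                      residualMode = "heterogeneous")
fit
#> RRMFit: m = 4, 19 residual class(es), converged in 8 iterations
#>   logL(REML) = -31314.9936, AIC = 62687.9872 (29 varcomp parameters)

par <- geneticCorrelation(heritability(geneticCovariance(fit), fit))
round(par@h2[c(1, 15, 29, 43, 57)], 3)   # DAP 27, 41, 55, 69, 83
#> [1] 0.273 0.162 0.057 0.191 0.312
```

The fitted heritability dips mid-season and recovers — the V-shaped
profile the simulation planted (truth 0.30 → 0.05 → 0.30). The GWAS side:

```r
eff <- effectsOverTime(backsolveSnpEffects(fit, grm), basis)
top <- selectTopSnps(eff, k = 10)
head(top$union[, c("snp_id", "chrom", "pos", "nDays")], 3)
#>       snp_id chrom      pos nDays
#> 1 1:12937154 Chr01 12937154    22
#> 2 1:19203774 Chr01 19203774    10
#> 3 1:20680697 Chr01 20680697    31
table(vapply(strsplit(top$union$days, ","),
             function(d) classifyDuration(as.integer(d)), ""))
#> intermittent         long          mid        short
#>            2            3           15           12
```

Each selected SNP carries its presence days in the per-day top-10 and a
duration class (a run of >30 consecutive days is long, <10 short, 10–30
mid, several runs intermittent). `runPipeline(rrmConfig(...), panel,
phenotypes, annotation)` runs every stage and writes the CSV/JSON tables;
`inst/scripts/genomic-rrm` is a command-line wrapper around the same
functions.

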