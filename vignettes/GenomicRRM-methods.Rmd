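---
title: "Random regression models for longitudinal genomic analysis: methods and design"
author: "GenomicRRM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression models for longitudinal genomic analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

GenomicRRM analyzes a longitudinal trait recorded on a panel of genotyped
inbred lines — the motivating case is above-ground biomass of soybean
recombinant inbred lines (RILs) tracked over days after planting (DAP)
27–83. The record for line $i$ on day $t_{ij}$ in environment–replication
combination $k$ is modeled as

$$y_{ijk} = Env_k + \sum_{m=1}^{M} b_m \phi_m(t_{ij})
          + \sum_{m=1}^{M} a_{im} \phi_m(t_{ij}) + e_{ijk},$$

where $Env_k$ is a fixed environment–replication effect, $b_m$ are fixed
regression coefficients describing the population mean curve, $a_{im}$ are
line-specific random regression coefficients describing additive genetic
deviations from that curve, $\phi_m$ are covariance-function basis
functions, and $e_{ijk}$ is a residual. The random structure is

$$\mathrm{var}\begin{pmatrix}\mathbf a\\ \mathbf e\end{pmatrix} =
\begin{pmatrix}\mathbf G \otimes \mathbf G_0 & 0\\
0 & \mathbf I \otimes \mathbf R\end{pmatrix},$$

with $\mathbf G$ the VanRaden (method 1) genomic relationship matrix,
$\mathbf G_0$ the $M \times M$ covariance of the regression coefficients,
and $\mathbf R$ diagonal with either one residual variance or one per DAP
class. The Kronecker ordering is **line-major** (line $i$'s $M$
coefficients are contiguous). The printed structure of such models is
typographically ambiguous about ordering; it is pure bookkeeping, and the
choice is pinned down here by a permutation-invariance test (permuting
lines permutes the coefficient BLUPs and changes nothing else).

Because any fixed rescaling of the basis is absorbed by $\mathbf G_0$, the
fixed population curve uses the same basis and order as the random part.

## Time bases

Two covariance-function bases are implemented in `timeBasis()` /
`basisMatrix()`:

* **Legendre orthogonal polynomials** on time standardized to $[-1, 1]$
  (`standardizeTime()`: DAP 27 $\to -1$, DAP 83 $\to +1$). Column $k+1$ is
  $\phi_k(t) = \sqrt{(2k+1)/2}\,P_k(t)$. The $\sqrt{(2k+1)/2}$
  normalization is the standard covariance-function convention; any fixed
  scaling would be absorbed by $\mathbf G_0$, but it must be fixed and
  documented for reproducibility, and the tests verify orthonormality
  under Gauss–Legendre quadrature.
* **B-splines** of degree 1 or 2 with user interior knots (the motivating
  analysis used knots at 55, or at 44 and 66 DAP), via the Cox–de Boor
  recursion with $0/0 := 0$. Boundary knots are **clamped** (multiplicity
  degree + 1 at both ends): only interior knots are ever printed for such
  models, and clamping is the convention that yields the conventional
  count of `#interior + degree + 1` basis functions with full support over
  the range. The last basis function includes the right endpoint so the
  covariate matrix has no zero row at DAP 83; partition of unity holds on
  the whole grid to machine precision.

## Residual variance classes

Heterogeneous fits use a `ResidualClassMap` of contiguous DAP intervals.
The default map ships the 19 printed intervals
27–33, 34–36, 37, 38–41, 42–43, 44–45, 46, 47–49, 50–53, 54–58, 59–61,
62, 63–65, 66–71, 72–74, 75–76, 77–80, 81–82, 83. The source text
describes these as "18 classes" while printing 19 intervals; rather than
guessing which interval was merged, the printed list is used verbatim and
the count mismatch is surfaced here. Classes with fewer than two records
are merged into their right neighbour (the last class merges leftward)
with a warning, and the merged map is what the fit reports.

## REML estimation

`remlEstimate()` maximizes the restricted likelihood over $\mathbf G_0$
and the residual variances with **average-information (AI) updates**,
step-halving, and an EM fallback:

* The likelihood is always evaluated through the mixed-model-equation
  (MME) factorization — $\log|\mathbf C|$ plus quadratic forms — never by
  inverting the record-level covariance, so cost scales with the number of
  lines, not records.
* An AI step that leaves the parameter space or decreases the objective is
  halved up to eight times; if no halving helps, one EM update (closed
  form, guaranteed uphill) is taken. If neither improves the objective the
  iteration is declared stalled at a (possibly boundary) optimum. The
  accepted-iteration likelihood trail is therefore non-decreasing, which a
  test asserts.
* $\mathbf G_0$ iterates are projected onto the PSD cone when an update
  leaves it, with an eigenvalue floor of $10^{-8}\times$ the phenotypic
  variance. The floor is far below any detectable variance but keeps the
  prior precision numerically tractable; with a much smaller floor the
  $\mathbf G_0^{-1}$ scale mixes catastrophically with the
  $\mathbf G^{-1}$ scale in the MME.
* $\mathbf G$ is always eigendecomposed once; if its smallest eigenvalue
  falls below $10^{-8}\times$ its mean diagonal (the VanRaden matrix with
  frequencies estimated from the panel is always singular in the
  ones-direction), all eigenvalues are lifted by that amount, with a
  message. This is equivalent to the usual small diagonal lift before
  inversion.
* Convergence requires the maximum relative parameter change below `tol`
  ($10^{-6}$) together with a scaled gradient norm below `gradTol`, **or**
  a relative objective change below `logLTol` ($10^{-8}$) on an accepted
  AI step. The objective-change rule is what terminates cleanly at
  boundary optima (e.g. a singular true $\mathbf G_0$), where the
  unconstrained gradient need not vanish; it is deliberately not applied
  to EM steps, which can crawl with tiny gains far from the optimum.
* Initialization follows a scale-aware rule: $\mathbf G_0 =
  (\widehat{\mathrm{var}}(y)/2M)\,\mathbf I$ and residual variances at
  half the per-class phenotypic variance.

Two algebraically identical solver routes exist. The general route
assembles the dense MME (with Jacobi diagonal equilibration before the
Cholesky factorization — without it, the lifted-$\mathbf G$ prior makes
trace terms inaccurate enough to break EM monotonicity). When every
phenotyped line carries the same (env_rep, DAP) record design — true for
the balanced trials the generator emulates, and for every training fold of
the cross-validation — a fast route rotates the random effects by the
eigenvectors of $\mathbf G$, which block-diagonalizes the equations into
$n$ independent $M\times M$ blocks and reduces the per-iteration cost from
$O((nM)^3)$ to $O(nM^3)$. The tests pin the two routes to each other at
matched parameter values (likelihood, BLUPs, gradients, AI matrices) and
at their optima on a well-conditioned instance.

Model comparison uses $AIC = -2\log L + 2k$ with $k$ counting **only**
(co)variance parameters, $M(M+1)/2$ plus the number of residual classes;
whether fixed effects are counted differs between REML implementations,
and since all candidate models here share one fixed design the choice
cannot change a ranking. Non-converged fits are listed but excluded from
ranking.

## Genetic parameters on the time scale

With $\mathbf T$ the basis covariate matrix on the evaluation grid
(default: every integer DAP in range, 57 days),

* genetic covariance $\Sigma = \mathbf T \mathbf G_0 \mathbf T'$;
* heritability $h^2(j) = \Sigma_{jj} / (\Sigma_{jj} + \sigma^2_e(j))$,
  where under heterogeneous residuals $\sigma^2_e(j)$ is the variance of
  the class containing day $j$ — the displayed formula in the source shows
  a single $\sigma^2_e$ but states that it "depends on" the classes;
* genetic correlation $r(j,j') = \Sigma_{jj'} /
  \sqrt{\Sigma_{jj}\Sigma_{j'j'}}$. The source displays the denominator as
  $\sqrt{\sigma^2_{a_j} + \sigma^2_{a_{j'}}}$ (a sum); only the product
  form yields $r(j,j) = 1$, so the sum is treated as a typo and the
  product form implemented;
* breeding-value trajectories $\widehat{GEBV}_i = \mathbf T \hat g_i$,
  an exact matrix product with no smoothing beyond the basis.

## Cross-validated genomic prediction

`cvPredict()` partitions lines into $k$ equal-sized folds (sizes differ by
at most one). Validation lines lose their phenotypes but remain in the
whole-panel $\mathbf G$ — that is what makes prediction of unphenotyped
lines possible in GBLUP. Variance components are re-estimated on each
training set by default (a `reuseVarcomps` flag reuses the full-data
components for speed). Validation-line coefficient BLUPs come from the
training BLUPs by the relationship projection $\hat g_{val} =
(\mathbf G_{vt}\mathbf G_{tt}^{-1} \otimes \mathbf I)\hat g_{trn}$, which
is exactly the joint-MME solution for lines without records. Accuracy per
DAP is the Pearson correlation between full-data and reduced-data GEBV
over validation lines; bias is the slope of regressing full-data GEBV on
reduced-data GEBV. Whether such statistics should average folds or pool
validation lines is not fully determined by the description "repeated five
times"; per-fold averaging is the default and pooling is available behind
`pool = TRUE`.

A property of this accuracy definition worth knowing: full-data and
reduced-data GEBV of the same validation lines share the information in
the training records, so their correlation does **not** vanish when the
trait has no genetic variance. In a zero-heritability simulation the
package's tests observe correlations near 0.8 — structurally, not by
error. A null-calibrated accuracy would need a comparator independent of
the training data (for instance validation phenotypes); with the
full-vs-reduced definition, reported accuracies should be read as
agreement between two predictors, not as calibrated signal detection.
The variance components themselves are null-calibrated: with zero true
genetic variance the estimated per-day genetic variance stays below 5% of
the residual variance in at least 90% of seeded replicates.

## Longitudinal GWAS

SNP effects are back-solved from breeding values per coefficient,
$\hat u_m = \mathbf D\mathbf Z'(\mathbf Z\mathbf D\mathbf Z')^{-1}\hat
g_m$ with $\mathbf D = \mathbf I$ (a weights hook exists but is off by
default), using the identity $\mathbf Z\mathbf Z' = k\,\mathbf G$ and a
spectral pseudo-inverse when singular. Per-SNP trajectories are
$\widehat{SNP}_s = \mathbf T\hat u_s$. Significance is **rank-based**: the
top-$k$ SNPs by absolute effect per day (default 10), ties broken by
(smaller chromosome, smaller position); no p-values are computed, exactly
as in the motivating analysis. "Presence" of a SNP on a day means
membership in that day's top-$k$ set. Duration classes over the
presence-day set: more than one maximal consecutive run is
*intermittent*; a single run is *long* above 30 days, *short* below 10,
and *mid* from 10 to 30 — runs of exactly 10 or exactly 30 days are left
undefined by the printed rules and are assigned to *mid* here. Candidate
windows are closed 1-based intervals $[pos - w, pos + w]$ (default
$w = 25$ kb) intersected with user annotation (BED/GFF3 via rtracklayer);
SNPs inside a feature are flagged.

## The synthetic data generator

Because the motivating study's raw data are unreleased, `simulateRilGenotypes()`
and `simulatePhenotypes()` generate a panel with full ground truth:

* **Genotypes**: each family is a biparental cross of two simulated inbred
  founders; a fully inbred line is a founder mosaic along each chromosome
  (first-order Markov chain over markers, per-interval recombination
  probability from a 1.2 Morgan genetic length), doubled into 0/2 dosages
  with a small residual-heterozygosity rate (0.002). Defaults emulate the
  SoyNAM-like structure: 32 families, ~12 lines each, positions uniform
  per chromosome.
* **Phenotypes**: coefficients $a_i$ are drawn with covariance
  $\mathbf G \otimes \mathbf G_0$ through a Cholesky (or lifted eigen)
  square root of the panel's own VanRaden matrix, then records follow the
  RRM equation exactly, with class-wise residual noise, by default one
  record per line, environment–replication (3 × 2) and integer DAP.
  Unequal replication can be emulated with per-env_rep dropout rates.
* Either a known $\mathbf G_0$ is supplied, or a **target heritability
  profile** is requested and `g0ForH2Profile()` solves for a PSD
  $\mathbf G_0$ whose implied $\mathrm{diag}(\mathbf T\mathbf G_0\mathbf
  T')$ matches it (alternating least squares with PSD projection); the
  realized profile implied by the fitted $\mathbf G_0$ is stored as the
  truth.
* The trait is deliberately **unit-agnostic**: the study's trait is an
  imagery-predicted biomass whose per-day variance scale is not reported
  (only a seasonal range of roughly 10–940 g/m² in passing), and the
  upstream imagery model is out of scope, so the simulator's scale is
  arbitrary (population curve of amplitude 10, residual variances of
  order 1) and all downstream quantities shown to be scale-invariant are
  tested as such.

What the generator does **not** emulate: linkage disequilibrium beyond the
family Markov structure, selection, genotyping error, and the residual
autocorrelation an interpolated phenotype would carry. Passing
parameter-recovery tests on this generator therefore demonstrates
correctness of the estimation machinery under the model's own assumptions,
not robustness to real-data violations of them.

Missing dosages in real input are imputed to twice the allele frequency
after QC (the source data arrive pre-imputed from founders, so the
handling of residual missingness is this package's choice, and frequencies
are estimated from the analyzed panel — the scale of $\mathbf G$ affects
the scale of $\mathbf G_0$, never heritability ratios).

## Problem sizes used by the checks

The package's validation suite runs at deliberately desk-sized versions of
the study conditions: parameter recovery at 500 lines × 1,000 SNPs with 20
seeded replicates (observed mean absolute error of the recovered $h^2$
profile well under 0.05); null calibration at 200 lines × 50 replicates;
model recovery (AIC) at 300 lines × 20 replicates; and the acceptance
script at the full panel structure, 32 × 12 = 384 lines × 5,000 SNPs, on
all 57 days × 6 environment–replications (~131,000 records). These sizes
were chosen as the smallest at which the Monte-Carlo bands in the checks
are meaningful.

## Known limitations

* Single-step (pedigree + genomic) evaluation, dominance/epistasis, and
  Bayesian alternatives are out of scope, as are free-knot optimization,
  LD pruning and formal association testing.
* Standard errors of heritability (from the AI information matrix) are not
  reported.
* The full-vs-reduced accuracy caveat above.
* With heterogeneous residuals the AIC comparison across residual
  structures assumes the same record set; the package does not prevent
  comparing fits on different data, and `aicCompare()` should only be
  given fits of the same phenotype table.
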