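#' @import methods
NULL

#' Covariance-function time basis
#'
#' A basis over the day-after-planting (DAP) axis used to expand random and
#' fixed regressions in a random regression model. Two kinds are supported:
#' normalized Legendre orthogonal polynomials on time standardized to
#' \eqn{[-1, 1]}, and clamped B-splines of degree 1 or 2 with user-supplied
#' interior knots.
#'
#' @slot kind character, `"legendre"` or `"bspline"`.
#' @slot order integer, highest polynomial order for the Legendre kind
#'   (`order + 1` coefficients); ignored for B-splines.
#' @slot degree integer, B-spline degree (1 = linear, 2 = quadratic);
#'   ignored for Legendre.
#' @slot knots numeric, strictly increasing interior knots inside
#'   `(dapMin, dapMax)`; B-splines only.
#' @slot dapMin,dapMax numeric, the modeled DAP range.
#' @export
setClass("TimeBasis",
  representation(kind = "character", order = "integer", degree = "integer",
                 knots = "numeric", dapMin = "numeric", dapMax = "numeric"))

setValidity("TimeBasis", function(object) {
  msg <- NULL
  if (!object@kind %in% c("legendre", "bspline"))
    msg <- c(msg, "kind must be 'legendre' or 'bspline'")
  if (object@dapMin >= object@dapMax)
    msg <- c(msg, "dapMin must be < dapMax")
  if (object@kind == "legendre") {
    if (length(object@order) != 1L || object@order < 0L)
      msg <- c(msg, "Legendre order must be a single integer >= 0")
  } else {
    if (!object@degree %in% c(1L, 2L))
      msg <- c(msg, "B-spline degree must be 1 or 2")
    k <- object@knots
    if (length(k)) {
      if (is.unsorted(k, strictly = TRUE))
        msg <- c(msg, "interior knots must be strictly increasing")
      if (any(k <= object@dapMin) || any(k >= object@dapMax))
        msg <- c(msg, "interior knots must lie strictly inside (dapMin, dapMax)")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Panel of genotyped inbred lines
#'
#' SNP dosages (counts of the alternate allele, 0/1/2, `NA` = missing) for a
#' panel of lines, with per-SNP chromosome and 1-based physical position.
#' After QC imputation ([qcFilter()]) dosages may be fractional in `[0, 2]`
#' and the `imputed` flag is set.
#'
#' @slot dosages numeric matrix, lines x SNPs; rownames are line ids,
#'   colnames SNP ids.
#' @slot snpInfo data.frame with columns `snp_id`, `chrom`, `pos`.
#' @slot imputed logical, `TRUE` once missing dosages have been imputed.
#' @export
setClass("GenotypePanel",
  representation(dosages = "matrix", snpInfo = "data.frame",
                 imputed = "logical"),
  prototype(imputed = FALSE))

setValidity("GenotypePanel", function(object) {
  msg <- NULL
  d <- object@dosages
  si <- object@snpInfo
  if (!all(c("snp_id", "chrom", "pos") %in% names(si)))
    msg <- c(msg, "snpInfo must have columns snp_id, chrom, pos")
  if (nrow(si) != ncol(d))
    msg <- c(msg, "snpInfo rows must match dosage columns")
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    msg <- c(msg, "line ids (dosage rownames) must be present and unique")
  v <- d[!is.na(d)]
  if (length(v)) {
    if (min(v) < 0 || max(v) > 2)
      msg <- c(msg, "dosages must lie in [0, 2]")
    if (!object@imputed && any(v != round(v)))
      msg <- c(msg, "non-imputed dosages must be integers 0/1/2")
  }
  if (nrow(si) && any(si$pos < 1))
    msg <- c(msg, "positions must be >= 1 (1-based)")
  if (is.null(msg)) TRUE else msg
})

#' Genomic relationship matrix result
#'
#' VanRaden (method 1) genomic relationship matrix together with the centered
#' dosage matrix and the frequencies that produced it:
#' \eqn{G = Z Z' / (2 \sum_j p_j (1 - p_j))} with \eqn{Z = M - 2p}.
#'
#' @slot G n x n relationship matrix.
#' @slot Zc n x s column-centered dosage matrix.
#' @slot pFreq per-SNP alternate-allele frequency.
#' @slot kScale the scaling constant \eqn{2 \sum p (1 - p)}.
#' @slot snpInfo data.frame (`snp_id`, `chrom`, `pos`) for the kept SNPs.
#' @export
setClass("GRMResult",
  representation(G = "matrix", Zc = "matrix", pFreq = "numeric",
                 kScale = "numeric", snpInfo = "data.frame"))

setValidity("GRMResult", function(object) {
  msg <- NULL
  if (nrow(object@G) != ncol(object@G)) msg <- c(msg, "G must be square")
  if (max(abs(object@G - t(object@G))) > 1e-8 * (1 + max(abs(object@G))))
    msg <- c(msg, "G must be symmetric")
  if (object@kScale <= 0) msg <- c(msg, "kScale must be > 0")
  if (ncol(object@Zc) != length(object@pFreq))
    msg <- c(msg, "Zc columns must match pFreq length")
  if (is.null(msg)) TRUE else msg
})

#' Residual-variance class map
#'
#' An ordered set of disjoint DAP intervals partitioning `[dapMin, dapMax]`,
#' each carrying its own residual variance in a heterogeneous-residual fit.
#' The default map ([defaultResidualClasses()]) ships the 19 printed
#' intervals used for the soybean biomass grid 27--83 DAP (the source
#' describes them as 18 classes; the printed list has 19 intervals and is
#' retained as printed).
#'
#' @slot from,to integer vectors, closed interval bounds per class.
#' @export
setClass("ResidualClassMap",
  representation(from = "integer", to = "integer"))

setValidity("ResidualClassMap", function(object) {
  msg <- NULL
  f <- object@from; t <- object@to
  if (length(f) != length(t) || !length(f))
    msg <- c(msg, "from/to must be equal-length, non-empty")
  else {
    if (any(f > t)) msg <- c(msg, "each interval needs from <= to")
    if (length(f) > 1 && any(f[-1] != t[-length(t)] + 1L))
      msg <- c(msg, "intervals must be contiguous and ordered (partition)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Fitted random regression model
#'
#' REML estimates for the RRM
#' \eqn{y_{ijk} = Env_k + \sum_m b_m \phi_m(t) + \sum_m a_{im} \phi_m(t) + e_{ijk}}
#' with \eqn{var(a) = G \otimes G_0} (line-major ordering) and residual
#' variance homogeneous or per DAP class.
#'
#' @slot basis the [TimeBasis-class] used for both fixed and random regressions.
#' @slot residualMap the [ResidualClassMap-class] actually used (after merging
#'   empty/underfilled classes); a single interval for homogeneous fits.
#' @slot G0 m x m coefficient covariance estimate.
#' @slot sigma2e residual variance per class.
#' @slot beta fixed-effect solutions (population curve coefficients, then
#'   env_rep contrasts), named.
#' @slot ghat n x m matrix of per-line coefficient BLUPs, rownames line ids.
#' @slot logLik REML log-likelihood at the estimates.
#' @slot AIC Akaike information criterion,
#'   \eqn{-2 \log L + 2 \cdot} `nVarcompParams`.
#' @slot nVarcompParams number of (co)variance parameters,
#'   \eqn{m(m+1)/2 +} number of residual classes.
#' @slot converged logical convergence flag (the last iterate is returned
#'   either way).
#' @slot nIterations iterations used.
#' @slot history data.frame of per-iteration log-likelihoods and step kinds.
#' @export
setClass("RRMFit",
  representation(basis = "TimeBasis", residualMap = "ResidualClassMap",
                 G0 = "matrix", sigma2e = "numeric", beta = "numeric",
                 ghat = "matrix", logLik = "numeric", AIC = "numeric",
                 nVarcompParams = "numeric", converged = "logical",
                 nIterations = "integer", history = "data.frame"))

setValidity("RRMFit", function(object) {
  msg <- NULL
  m <- nrow(object@G0)
  if (ncol(object@G0) != m) msg <- c(msg, "G0 must be square")
  if (m && max(abs(object@G0 - t(object@G0))) > 1e-8 * (1 + max(abs(object@G0))))
    msg <- c(msg, "G0 must be symmetric")
  if (any(object@sigma2e <= 0)) msg <- c(msg, "residual variances must be > 0")
  if (ncol(object@ghat) != m) msg <- c(msg, "ghat must have m columns")
  if (is.null(msg)) TRUE else msg
})

#' Time-scale genetic parameters
#'
#' Per-DAP additive genetic variance (diagonal of
#' \eqn{\Sigma = T G_0 T'}), narrow-sense heritability and the DAP x DAP
#' genetic correlation matrix.
#'
#' @slot Sigma DAP x DAP genetic covariance matrix.
#' @slot h2 per-DAP heritability (may contain `NA` before
#'   [heritability()] is applied).
#' @slot genCorr DAP x DAP genetic correlation matrix (may be empty before
#'   [geneticCorrelation()] is applied).
#' @slot dapGrid the evaluation grid (days).
#' @export
setClass("GeneticParams",
  representation(Sigma = "matrix", h2 = "numeric", genCorr = "matrix",
                 dapGrid = "numeric"))

#' Cross-validated genomic prediction result
#'
#' @slot accuracy per-DAP Pearson correlation between full-data and
#'   reduced-data GEBV over validation lines, averaged over folds.
#' @slot bias per-DAP slope of regressing full-data GEBV on reduced-data
#'   GEBV, averaged over folds.
#' @slot perFold long data.frame: fold, dap, r, b1, nValidation.
#' @slot folds named integer vector, fold assignment per line.
#' @slot dapGrid evaluation grid.
#' @slot seed the seed that produced the folds.
#' @export
setClass("CVResult",
  representation(accuracy = "numeric", bias = "numeric",
                 perFold = "data.frame", folds = "integer",
                 dapGrid = "numeric", seed = "numeric"))

#' Time-dependent SNP effects
#'
#' Per-coefficient SNP effects back-solved from breeding values,
#' \eqn{\hat u_m = Z'(Z Z')^{-1} \hat g_m}, and their projection on the DAP
#' grid, \eqn{\widehat{SNP}_s = T \hat u_s}.
#'
#' @slot uHat SNPs x m per-coefficient effects.
#' @slot effectsByDap SNPs x DAP effect matrix.
#' @slot snpInfo data.frame `snp_id`, `chrom`, `pos` aligned with rows.
#' @slot dapGrid evaluation grid.
#' @export
setClass("SnpEffects",
  representation(uHat = "matrix", effectsByDap = "matrix",
                 snpInfo = "data.frame", dapGrid = "numeric"))

#' Ground truth retained by the phenotype simulator
#'
#' @slot G0 true coefficient covariance.
#' @slot sigma2e true residual variance per class.
#' @slot residualMap the class map used.
#' @slot beta true fixed population-curve coefficients.
#' @slot envEffects true env_rep effects, named.
#' @slot coef n x m true per-line random regression coefficients.
#' @slot basis the generating [TimeBasis-class].
#' @slot family family label per line.
#' @slot dapGrid grid on which `h2` is tabulated.
#' @slot h2 realized per-DAP heritability implied by `G0`, `sigma2e`.
#' @export
setClass("SyntheticTruth",
  representation(G0 = "matrix", sigma2e = "numeric",
                 residualMap = "ResidualClassMap", beta = "numeric",
                 envEffects = "numeric", coef = "matrix",
                 basis = "TimeBasis", family = "character",
                 dapGrid = "numeric", h2 = "numeric"))
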