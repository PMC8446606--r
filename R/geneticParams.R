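#' Genetic covariance over the time grid
#'
#' Projects the coefficient covariance onto the DAP scale,
#' \eqn{\Sigma = T G_0 T'}, where \eqn{T} is the basis covariate matrix on
#' the requested grid.
#'
#' @param fit an [RRMFit-class] (a non-converged fit is accepted with a
#'   warning unless `acceptNonConverged = FALSE`).
#' @param dapGrid evaluation days; default every integer DAP in the basis
#'   range.
#' @param acceptNonConverged set `FALSE` to error on non-converged fits.
#' @return a [GeneticParams-class] with `Sigma` filled (heritability and
#'   correlations are added by [heritability()] / [geneticCorrelation()]).
#' @export
geneticCovariance <- function(fit, dapGrid = NULL, acceptNonConverged = TRUE) {
  stopifnot(is(fit, "RRMFit"))
  if (!fit@converged) {
    if (!acceptNonConverged) stop("fit did not converge")
    warning("using estimates from a non-converged fit", call. = FALSE)
  }
  basis <- fit@basis
  if (is.null(dapGrid)) dapGrid <- seq(basis@dapMin, basis@dapMax)
  Tm <- basisMatrix(basis, dapGrid)
  Sigma <- Tm %*% fit@G0 %*% t(Tm)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(dapGrid, dapGrid)
  new("GeneticParams", Sigma = Sigma,
      h2 = rep(NA_real_, length(dapGrid)),
      genCorr = matrix(numeric(0), 0, 0), dapGrid = as.numeric(dapGrid))
}

#' Per-DAP narrow-sense heritability
#'
#' \eqn{h^2(j) = \sigma^2_a(j) / (\sigma^2_a(j) + \sigma^2_e(j))} with
#' \eqn{\sigma^2_a(j) = \Sigma(j, j)}; under heterogeneous residuals
#' \eqn{\sigma^2_e(j)} is the variance of the residual class containing
#' day \eqn{j}.
#'
#' @param params a [GeneticParams-class] from [geneticCovariance()].
#' @param fit the [RRMFit-class] providing residual variances and class map.
#' @return `params` with the `h2` slot filled.
#' @export
heritability <- function(params, fit) {
  stopifnot(is(params, "GeneticParams"), is(fit, "RRMFit"))
  cls <- classOfDap(fit@residualMap, params@dapGrid)
  s2e <- fit@sigma2e[cls]
  sa <- diag(params@Sigma)
  tot <- sa + s2e
  if (any(tot <= 0))
    stop("zero total variance at DAP ",
         paste(params@dapGrid[tot <= 0], collapse = ", "), ": h2 undefined")
  params@h2 <- as.numeric(sa / tot)
  params
}

#' Genetic correlations between days
#'
#' \eqn{r(j, j') = \Sigma(j, j') / \sqrt{\Sigma(j, j)\,\Sigma(j', j')}}
#' (product form in the denominator, the only form with \eqn{r(j,j) = 1}).
#' Days with zero additive variance give `NA` rows/columns with a warning.
#'
#' @param params a [GeneticParams-class] with `Sigma` filled.
#' @return `params` with the `genCorr` slot filled.
#' @export
geneticCorrelation <- function(params) {
  stopifnot(is(params, "GeneticParams"))
  sa <- diag(params@Sigma)
  bad <- sa <= 0
  if (any(bad))
    warning("zero additive variance at DAP ",
            paste(params@dapGrid[bad], collapse = ", "),
            ": correlations undefined there", call. = FALSE)
  s <- sqrt(ifelse(bad, NA_real_, sa))
  R <- params@Sigma / tcrossprod(s)
  over <- !is.na(R) & abs(R) > 1           # clip rounding overshoot
  R[over] <- sign(R[over])
  diag(R)[!bad] <- 1
  dimnames(R) <- dimnames(params@Sigma)
  params@genCorr <- R
  params
}

#' Genomic breeding-value trajectories
#'
#' \eqn{\widehat{GEBV}_i = T \hat g_i}: the exact matrix product of the
#' basis covariates with each line's coefficient BLUPs, no smoothing beyond
#' the basis.
#'
#' @param fit an [RRMFit-class].
#' @param dapGrid evaluation days (default: all integer DAP in range).
#' @return lines x DAP matrix of genomic estimated breeding values.
#' @export
gebvTrajectories <- function(fit, dapGrid = NULL) {
  stopifnot(is(fit, "RRMFit"))
  basis <- fit@basis
  if (is.null(dapGrid)) dapGrid <- seq(basis@dapMin, basis@dapMax)
  Tm <- basisMatrix(basis, dapGrid)
  out <- fit@ghat %*% t(Tm)
  colnames(out) <- as.character(dapGrid)
  out
}
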