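#' Estimate RRM variance components by AI-REML
#'
#' Maximizes the restricted likelihood of the random regression model over
#' the coefficient covariance \eqn{G_0} and the residual variances (one per
#' class, or a single one) using average-information updates with step
#' halving and an expectation-maximization fallback whenever an AI step
#' leaves the parameter space or decreases the objective. The likelihood is
#' evaluated through the mixed-model-equation factorization (log-determinant
#' identity), never by inverting the record-level covariance. Designs in
#' which every phenotyped line shares one (env_rep, DAP) record pattern are
#' detected and solved through an eigendecomposition of G that
#' block-diagonalizes the equations (identical results, much faster).
#'
#' Convergence requires both the maximum relative parameter change and the
#' scaled gradient norm to fall below `tol` and `gradTol`; on reaching
#' `maxIter` the last iterate is returned with `converged = FALSE` rather
#' than raising.
#'
#' @param phenotypes data.frame with `line`, `env_rep`, `dap`, `value`.
#' @param basis a [TimeBasis-class] used for both the fixed population curve
#'   and the random regressions.
#' @param grm a [GRMResult-class] (or a relationship matrix with line-id
#'   dimnames) covering all phenotyped lines.
#' @param residualMap a [ResidualClassMap-class]; classes with fewer than 2
#'   records are merged rightward with a warning.
#' @param residualMode `"heterogeneous"` (class-wise residual variances) or
#'   `"homogeneous"`.
#' @param init optional list with starting `G0` and `sigma2e`; the default
#'   is \eqn{G_0 = (var(y) / 2m) I} and half the per-class phenotypic
#'   variance.
#' @param maxIter,tol,gradTol,logLTol iteration controls: iterations stop
#'   when parameter changes and the scaled gradient stabilize
#'   (`tol`, `gradTol`) or the relative objective change drops below
#'   `logLTol` (which also catches boundary optima, where the unconstrained
#'   gradient need not vanish).
#' @param method `"auto"` picks the balanced eigendecomposition route when
#'   the design allows it; `"dense"`/`"balanced"` force a route.
#' @param verbose print per-iteration log-likelihoods.
#' @return an [RRMFit-class].
#' @export
remlEstimate <- function(phenotypes, basis, grm,
                         residualMap = defaultResidualClasses(),
                         residualMode = c("heterogeneous", "homogeneous"),
                         init = NULL, maxIter = 100L, tol = 1e-6,
                         gradTol = 1e-3, logLTol = 1e-8,
                         method = c("auto", "balanced", "dense"),
                         verbose = FALSE) {
  residualMode <- match.arg(residualMode)
  method <- match.arg(method)
  md <- rrmModelData(phenotypes, basis, grm, residualMap, residualMode)
  engine <- pickEngine(md, method)
  m <- md$m; nC <- md$nClass
  varY <- stats::var(md$y)
  if (is.null(init)) {
    G0 <- diag(varY / (2 * m), m)
    cv <- tapply(md$y, md$ci, stats::var)
    s2 <- as.vector(cv)[seq_len(nC)] / 2
    s2[!is.finite(s2) | s2 <= 0] <- varY / 2
  } else {
    G0 <- init$G0
    s2 <- rep(init$sigma2e, length.out = nC)
  }

  ev <- engine$eval(G0, s2, deriv = TRUE)
  if (!is.finite(ev$logL))
    stop("non-finite REML likelihood at initialization")
  hist <- data.frame(iter = 0L, logL = ev$logL, step = "init",
                     stringsAsFactors = FALSE)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    th <- packTheta(G0, s2)
    G0inv <- chol2inv(chol(G0))
    grad <- remlGradient(ev, md, G0inv, s2)
    AI <- engine$aiMatrix(ev, G0inv, s2)
    step <- tryCatch(
      solve(AI + diag(1e-8 * max(diag(AI)), nrow(AI)), grad),
      error = function(e) NULL)
    cand <- NULL; evn <- NULL; kind <- "AI"
    if (!is.null(step) && all(is.finite(step))) {
      for (h in 0:8) {
        thn <- th + step / 2^h
        cn <- unpackTheta(thn, m, nC, varY)
        if (is.null(cn)) next
        e2 <- engine$eval(cn$G0, cn$s2, deriv = FALSE)
        if (is.finite(e2$logL) &&
            e2$logL >= ev$logL - 1e-9 * (1 + abs(ev$logL))) {
          cand <- cn; evn <- e2
          if (h > 0) kind <- sprintf("AI/2^%d", h)
          break
        }
      }
    }
    if (is.null(cand)) {                       # EM fallback (uphill)
      kind <- "EM"
      cand <- list(G0 = projectPSD(ev$emG0, floor = 1e-8 * max(varY, 1e-8)),
                   s2 = pmax(ev$emS2, 1e-8 * varY))
      e2 <- engine$eval(cand$G0, cand$s2, deriv = FALSE)
      if (!is.finite(e2$logL) ||
          e2$logL < ev$logL - 1e-9 * (1 + abs(ev$logL))) {
        ## neither AI nor EM can improve: stalled at a (boundary) optimum
        hist <- rbind(hist, data.frame(iter = it, logL = ev$logL,
                                       step = "stall", stringsAsFactors = FALSE))
        converged <- max(abs(grad * (abs(th) + 1e-4 * varY))) /
          max(1, length(md$y)) < gradTol
        break
      }
    }
    relch <- max(abs(packTheta(cand$G0, cand$s2) - th) /
                   (abs(th) + 1e-4 * varY))
    logLprev <- ev$logL
    G0 <- cand$G0; s2 <- cand$s2
    ev <- engine$eval(G0, s2, deriv = TRUE)
    hist <- rbind(hist, data.frame(iter = it, logL = ev$logL, step = kind,
                                   stringsAsFactors = FALSE))
    if (verbose)
      rrmMessage("iter %d (%s): logL = %.6f, max rel change = %.2e",
                 it, kind, ev$logL, relch)
    G0inv <- chol2inv(chol(G0))
    gnow <- remlGradient(ev, md, G0inv, s2)
    gscaled <- max(abs(gnow * (abs(packTheta(G0, s2)) + 1e-4 * varY))) /
      max(1, length(md$y))
    ## the objective-change stop only applies to (quadratic) AI steps: an
    ## EM fallback can crawl with tiny gains while still far from optimum
    if ((relch < tol && gscaled < gradTol) ||
        (kind != "EM" &&
         abs(ev$logL - logLprev) < logLTol * (1 + abs(ev$logL)))) {
      converged <- TRUE
      break
    }
  }

  nVar <- m * (m + 1) / 2 + nC
  names(s2) <- sprintf("%d-%d", md$map@from, md$map@to)
  beta <- ev$beta; names(beta) <- md$fixedNames
  new("RRMFit", basis = basis, residualMap = md$map, G0 = G0, sigma2e = s2,
      beta = beta, ghat = ev$ghat, logLik = ev$logL,
      AIC = -2 * ev$logL + 2 * nVar, nVarcompParams = nVar,
      converged = converged, nIterations = it, history = hist)
}

pickEngine <- function(md, method = "auto") {
  if (method == "balanced" || (method == "auto" && md$balanced))
    makeFastEngine(md) else makeDenseEngine(md)
}

#' Assemble the mixed-model equations
#'
#' Builds the dense MME coefficient matrix and right-hand side for given
#' variance components: fixed part = env_rep contrasts + population-curve
#' covariates (same basis as the random part); random part = per-line basis
#' blocks with prior precision \eqn{(G \otimes G_0)^{-1}} in line-major
#' ordering; residual precision diagonal with the class variance of each
#' record's DAP.
#'
#' @inheritParams remlEstimate
#' @param G0 m x m coefficient covariance.
#' @param sigma2e residual variance per class (recycled).
#' @return list with `C`, `rhs`, `nFixed`, `fixedNames`, `lines`, `m`,
#'   `map`, and the model-data object.
#' @export
buildMME <- function(phenotypes, basis, grm, G0, sigma2e,
                     residualMap = defaultResidualClasses(),
                     residualMode = c("heterogeneous", "homogeneous")) {
  md <- rrmModelData(phenotypes, basis, grm, residualMap,
                     match.arg(residualMode))
  s2 <- rep(sigma2e, length.out = md$nClass)
  w <- (1 / s2)[md$ci]
  N <- length(md$y)
  Zs <- Matrix::sparseMatrix(
    i = rep(seq_len(N), md$m),
    j = as.vector(vapply(seq_len(md$m),
                         function(k) (md$li - 1L) * md$m + k, integer(N))),
    x = as.vector(md$Trec), dims = c(N, md$n * md$m))
  W <- Matrix::cbind2(Matrix::Matrix(md$Xrec, sparse = TRUE), Zs)
  C <- as.matrix(Matrix::crossprod(W, W * w))
  ridx <- md$p + seq_len(md$n * md$m)
  C[ridx, ridx] <- C[ridx, ridx] + md$Ginv %x% chol2inv(chol(G0))
  rhs <- as.vector(Matrix::crossprod(W, w * md$y))
  list(C = C, rhs = rhs, nFixed = md$p, fixedNames = md$fixedNames,
       lines = md$lines, m = md$m, map = md$map, md = md)
}

#' Solve the mixed-model equations for fixed effects and coefficient BLUPs
#'
#' @param mme a system from [buildMME()].
#' @return list with `beta` (named fixed-effect solutions) and `ghat`
#'   (n x m matrix of line coefficient BLUPs).
#' @export
solveMME <- function(mme) {
  sol <- solve(mme$C, mme$rhs)
  beta <- sol[seq_len(mme$nFixed)]
  names(beta) <- mme$fixedNames
  ghat <- t(matrix(sol[-seq_len(mme$nFixed)], mme$m))
  rownames(ghat) <- mme$lines
  list(beta = beta, ghat = ghat)
}

## BLUP at fixed variance components through the engine route (used by CV
## when variance components are reused rather than re-estimated)
blupSolve <- function(phenotypes, basis, grm, G0, sigma2e,
                      residualMap = defaultResidualClasses(),
                      residualMode = "heterogeneous") {
  md <- rrmModelData(phenotypes, basis, grm, residualMap, residualMode)
  engine <- pickEngine(md)
  s2 <- rep(sigma2e, length.out = md$nClass)
  ev <- engine$eval(G0, s2, deriv = FALSE)
  list(beta = ev$beta, ghat = ev$ghat)
}

#' Rank fitted models by AIC
#'
#' Sorts fits by ascending \eqn{AIC = -2 \log L + 2 k}, where \eqn{k}
#' counts only (co)variance parameters, \eqn{m(m+1)/2} plus the number of
#' residual classes. Non-converged fits are listed but excluded from the
#' ranking.
#'
#' @param fits a (optionally named) list of [RRMFit-class] objects.
#' @return data.frame with model, m, residual classes, parameters, logL,
#'   AIC, convergence and rank (NA for non-converged fits).
#' @export
aicCompare <- function(fits) {
  stopifnot(length(fits) > 0, all(vapply(fits, is, TRUE, "RRMFit")))
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  df <- data.frame(
    model = nm,
    m = vapply(fits, function(f) nrow(f@G0), 0),
    nResidClasses = vapply(fits, function(f) length(f@sigma2e), 0),
    nVarcompParams = vapply(fits, function(f) f@nVarcompParams, 0),
    logL = vapply(fits, function(f) f@logLik, 0),
    AIC = vapply(fits, function(f) f@AIC, 0),
    converged = vapply(fits, function(f) f@converged, TRUE),
    stringsAsFactors = FALSE)
  if (!any(df$converged))
    warning("no converged fit to rank", call. = FALSE)
  df$rank <- NA_integer_
  df$rank[df$converged] <- rank(df$AIC[df$converged], ties.method = "first")
  df[order(!df$converged, df$AIC), , drop = FALSE]
}
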