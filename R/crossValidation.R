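#' Random k-fold partition of lines
#'
#' Uniform random partition into `k` folds whose sizes differ by at most
#' one; reproducible under the seed (drawn from the `"cv"` module stream).
#'
#' @param lineIds character vector of line identifiers.
#' @param k number of folds (>= 2, <= number of lines).
#' @param seed integer seed.
#' @return named integer vector: fold index per line.
#' @export
makeFolds <- function(lineIds, k = 5L, seed = 1L) {
  n <- length(lineIds)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must be <= number of lines")
  set.seed(moduleSeed(seed, "cv"))
  fold <- rep(seq_len(k), length.out = n)[sample.int(n)]
  names(fold) <- lineIds
  fold
}

#' Cross-validated genomic prediction of GEBV trajectories
#'
#' For each fold, validation lines lose their phenotypes (but keep their
#' genotypes through the whole-panel G); the model is refit on the training
#' records and validation-line coefficient BLUPs are obtained from the
#' training BLUPs by the relationship-matrix projection
#' \eqn{\hat g_{val} = (G_{vt} G_{tt}^{-1} \otimes I_m) \hat g_{trn}}
#' (the BLUP of unphenotyped individuals). Per DAP, accuracy is the Pearson
#' correlation between full-data and reduced-data GEBV over validation
#' lines, and bias is the slope of regressing full-data GEBV on
#' reduced-data GEBV; both are averaged over folds (set `pool = TRUE` to
#' pool validation lines across folds instead).
#'
#' @inheritParams remlEstimate
#' @param grm a [GRMResult-class] covering all lines.
#' @param k number of folds.
#' @param seed seed for the fold partition.
#' @param dapGrid evaluation days (default: all integer DAP in range).
#' @param reuseVarcomps if `TRUE`, the full-data variance components are
#'   reused in each training fit instead of being re-estimated (faster;
#'   default `FALSE` re-estimates per fold).
#' @param pool pool validation lines across folds instead of averaging
#'   per-fold statistics.
#' @param fullFit optionally, an already computed full-data [RRMFit-class].
#' @param ... further arguments passed to [remlEstimate()].
#' @return a [CVResult-class].
#' @export
cvPredict <- function(phenotypes, basis, grm,
                      residualMap = defaultResidualClasses(),
                      residualMode = c("heterogeneous", "homogeneous"),
                      k = 5L, seed = 1L, dapGrid = NULL,
                      reuseVarcomps = FALSE, pool = FALSE, fullFit = NULL,
                      ...) {
  residualMode <- match.arg(residualMode)
  stopifnot(is(grm, "GRMResult"))
  if (is.null(dapGrid)) dapGrid <- seq(basis@dapMin, basis@dapMax)
  if (is.null(fullFit))
    fullFit <- remlEstimate(phenotypes, basis, grm, residualMap,
                            residualMode, ...)
  gebvFull <- gebvTrajectories(fullFit, dapGrid)
  lines <- rownames(gebvFull)
  folds <- makeFolds(lines, k, seed)
  G <- grm@G
  Tm <- basisMatrix(basis, dapGrid)
  perFold <- list()
  rMat <- bMat <- matrix(NA_real_, k, length(dapGrid))
  for (f in seq_len(k)) {
    val <- lines[folds == f]
    trn <- setdiff(lines, val)
    if (length(val) < 3) {
      warning(sprintf("fold %d has < 3 validation lines; skipped", f),
              call. = FALSE)
      next
    }
    phTrn <- phenotypes[phenotypes$line %in% trn, , drop = FALSE]
    if (reuseVarcomps) {
      sol <- blupSolve(phTrn, basis, grm, fullFit@G0, fullFit@sigma2e,
                       fullFit@residualMap, residualMode)
      ghTrn <- sol$ghat
    } else {
      fitTrn <- remlEstimate(phTrn, basis, grm, residualMap, residualMode, ...)
      ghTrn <- fitTrn@ghat
    }
    trnIn <- rownames(ghTrn)
    Gtt <- liftDiag(G[trnIn, trnIn, drop = FALSE])
    ghVal <- G[val, trnIn, drop = FALSE] %*% solve(Gtt, ghTrn)
    gebvRed <- ghVal %*% t(Tm)
    full <- gebvFull[val, , drop = FALSE]
    r <- vapply(seq_along(dapGrid), function(j)
      suppressWarnings(stats::cor(full[, j], gebvRed[, j])), 0)
    b1 <- vapply(seq_along(dapGrid), function(j) {
      vx <- stats::var(gebvRed[, j])
      if (!is.finite(vx) || vx == 0) return(NA_real_)
      stats::cov(full[, j], gebvRed[, j]) / vx
    }, 0)
    rMat[f, ] <- r; bMat[f, ] <- b1
    perFold[[f]] <- data.frame(fold = f, dap = dapGrid, r = r, b1 = b1,
                               nValidation = length(val))
    if (pool)
      perFold[[f]]$pooledRows <- I(list(cbind(full = full, red = gebvRed)))
  }
  if (!length(perFold)) stop("no usable folds")
  if (pool) {
    ## pool validation lines across folds, then one correlation per DAP
    acc <- bias <- numeric(length(dapGrid))
    fullAll <- do.call(rbind, lapply(perFold, function(d)
      d$pooledRows[[1]][, seq_along(dapGrid), drop = FALSE]))
    redAll <- do.call(rbind, lapply(perFold, function(d)
      d$pooledRows[[1]][, length(dapGrid) + seq_along(dapGrid), drop = FALSE]))
    for (j in seq_along(dapGrid)) {
      acc[j] <- stats::cor(fullAll[, j], redAll[, j])
      bias[j] <- stats::cov(fullAll[, j], redAll[, j]) / stats::var(redAll[, j])
    }
    perFold <- lapply(perFold, function(d) d[setdiff(names(d), "pooledRows")])
  } else {
    acc <- colMeans(rMat, na.rm = TRUE)
    bias <- colMeans(bMat, na.rm = TRUE)
  }
  new("CVResult", accuracy = acc, bias = bias,
      perFold = do.call(rbind, perFold), folds = folds,
      dapGrid = as.numeric(dapGrid), seed = as.numeric(seed))
}
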