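## a minimal fit object with chosen G0 / residuals, for transform tests
mkFit <- function(G0, s2 = 1, basis = NULL, map = NULL,
                  ghat = NULL, lines = NULL) {
  if (is.null(basis)) basis <- timeBasis("legendre", order = nrow(G0) - 1)
  if (is.null(map)) map <- homogeneousClasses(c(basis@dapMin, basis@dapMax))
  m <- nCoef(basis)
  if (is.null(ghat)) {
    if (is.null(lines)) lines <- sprintf("L%d", 1:4)
    ghat <- matrix(0, length(lines), m, dimnames = list(lines, NULL))
  }
  s2 <- rep(s2, length.out = length(map@from))
  new("RRMFit", basis = basis, residualMap = map, G0 = G0, sigma2e = s2,
      beta = numeric(m), ghat = ghat, logLik = 0, AIC = 0,
      nVarcompParams = m * (m + 1) / 2 + length(s2), converged = TRUE,
      nIterations = 1L, history = data.frame())
}

test_that("Sigma = T G0 T' matches a per-pair loop oracle", {
  set.seed(5)
  basis <- timeBasis("bspline", degree = 2, knots = c(44, 66))
  m <- nCoef(basis)
  A <- matrix(rnorm(m * m), m)
  G0 <- crossprod(A)                                 # random PSD (seeded)
  fit <- mkFit(G0, basis = basis)
  grid <- seq(27, 83, by = 2)
  par <- geneticCovariance(fit, grid)
  Tm <- basisMatrix(basis, grid)
  oracle <- matrix(0, length(grid), length(grid))
  for (i in seq_along(grid)) for (j in seq_along(grid))
    oracle[i, j] <- drop(Tm[i, ] %*% G0 %*% Tm[j, ])
  expect_equal(unname(par@Sigma), oracle, tolerance = 1e-12)

  ## identity G0 with a Legendre basis: Sigma(t, t) = sum of phi_m(t)^2
  lb <- timeBasis("legendre", order = 3)
  pI <- geneticCovariance(mkFit(diag(4), basis = lb), 27:83)
  expect_equal(diag(pI@Sigma), rowSums(basisMatrix(lb, 27:83)^2),
               ignore_attr = TRUE)
  ## zero G0 gives zero Sigma
  p0 <- geneticCovariance(mkFit(matrix(0, 4, 4), basis = lb), 27:83)
  expect_true(all(p0@Sigma == 0))
  expect_error(geneticCovariance(fit, 20:30), "range")
})

test_that("heritability combines Sigma with the class residual variance", {
  basis <- timeBasis("legendre", order = 0)
  ## constant basis: Sigma(t,t) = 0.5 * g0 for every day
  map <- residualClassMap(c(27, 56), c(55, 83))
  fit <- mkFit(matrix(2), s2 = c(1, 3), basis = basis, map = map)
  par <- heritability(geneticCovariance(fit, c(30, 60)), fit)
  expect_equal(par@h2, c(1 / (1 + 1), 1 / (1 + 3)))
  ## equal variances -> exactly 0.5
  fitEq <- mkFit(matrix(2), s2 = 1, basis = basis)
  expect_equal(heritability(geneticCovariance(fitEq, 40), fitEq)@h2, 0.5)
  ## zero genetic variance -> 0
  fit0 <- mkFit(matrix(0), s2 = 1, basis = basis)
  expect_equal(heritability(geneticCovariance(fit0, 40), fit0)@h2, 0)
  ## invariance to trait rescaling: c^2 on both scales
  fitC <- mkFit(matrix(2 * 9), s2 = c(9, 27), basis = basis, map = map)
  parC <- heritability(geneticCovariance(fitC, c(30, 60)), fitC)
  expect_equal(parC@h2, par@h2)
})

test_that("genetic correlations use the product-form denominator", {
  basis <- timeBasis("bspline", degree = 1, knots = c(44, 66))
  set.seed(8)
  A <- matrix(rnorm(16), 4)
  fit <- mkFit(crossprod(A), basis = basis)
  par <- geneticCorrelation(geneticCovariance(fit, seq(27, 83, by = 7)))
  R <- par@genCorr
  expect_equal(unname(diag(R)), rep(1, nrow(R)))
  expect_true(all(abs(R) <= 1 + 1e-8))
  ## the correlation matrix is itself PSD
  expect_gt(min(eigen(R, symmetric = TRUE)$values), -1e-8)
  ## rank-1 G0: one common factor, all |r| = 1
  v <- rnorm(4)
  fit1 <- mkFit(tcrossprod(v), basis = basis)
  R1 <- geneticCorrelation(geneticCovariance(fit1, c(30, 50, 70)))@genCorr
  expect_equal(abs(unname(R1)), matrix(1, 3, 3), tolerance = 1e-9)
})

test_that("GEBV trajectories are the exact basis product", {
  basis <- timeBasis("bspline", degree = 1, knots = c(44, 66))
  lines <- sprintf("L%d", 1:5)
  set.seed(9)
  gh <- matrix(rnorm(20), 5, dimnames = list(lines, NULL))
  fit <- mkFit(diag(4), basis = basis, ghat = gh)
  fine <- gebvTrajectories(fit, 27:83)
  expect_equal(unname(fine), unname(gh %*% t(basisMatrix(basis, 27:83))))
  ## coarse grid equals the fine grid subsampled
  coarse <- gebvTrajectories(fit, seq(27, 83, by = 7))
  expect_equal(coarse, fine[, as.character(seq(27, 83, by = 7))])
  ## zero coefficients give a flat zero trajectory
  fit0 <- mkFit(diag(4), basis = basis, ghat = 0 * gh)
  expect_true(all(gebvTrajectories(fit0) == 0))
  ## constant basis: trajectory constant at ghat * phi0
  fitC <- mkFit(matrix(1), ghat = matrix(2, 3, 1,
                dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(unname(gebvTrajectories(fitC, c(30, 60))),
               matrix(2 * sqrt(0.5), 3, 2))
})
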