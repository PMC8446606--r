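test_that("MME solutions match the closed-form BLUP on a ridge-like toy", {
  ## G = I, m = 1 (constant basis): y = X b + Z g + e with var(g) = s2a I
  set.seed(31)
  lines <- sprintf("L%d", 1:5)
  ph <- expand.grid(line = lines, env_rep = c("E1", "E2"),
                    dap = c(30, 50, 70), stringsAsFactors = FALSE)
  ph$value <- rnorm(nrow(ph), 5)
  G <- diag(5); dimnames(G) <- list(lines, lines)
  bs <- timeBasis("legendre", order = 0, dapMin = 27, dapMax = 83)
  s2a <- 0.7; s2e <- 1.3
  mme <- buildMME(ph, bs, G, G0 = matrix(s2a), sigma2e = s2e,
                  residualMode = "homogeneous")
  sol <- solveMME(mme)
  ## oracle: GLS fixed effects and direct BLUP from the marginal covariance
  li <- match(ph$line, lines)
  Z <- matrix(0, nrow(ph), 5); Z[cbind(seq_len(nrow(ph)), li)] <- sqrt(0.5)
  X <- cbind(sqrt(0.5), as.numeric(ph$env_rep == "E2"))
  V <- s2a * tcrossprod(Z) + s2e * diag(nrow(ph))
  Vi <- solve(V)
  bHat <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% ph$value))
  gHat <- s2a * crossprod(Z, Vi %*% (ph$value - X %*% bHat))
  expect_equal(unname(sol$beta), drop(bHat), tolerance = 1e-9)
  expect_equal(unname(drop(sol$ghat)), drop(gHat), tolerance = 1e-9)
})

test_that("constant phenotypes give zero BLUPs and the constant as intercept", {
  lines <- sprintf("L%d", 1:6)
  ph <- expand.grid(line = lines, env_rep = "E1", dap = c(30, 55, 80),
                    stringsAsFactors = FALSE)
  ph$value <- 4.2
  G <- diag(6); dimnames(G) <- list(lines, lines)
  bs <- timeBasis("legendre", order = 0, dapMin = 27, dapMax = 83)
  sol <- solveMME(buildMME(ph, bs, G, G0 = matrix(0.5), sigma2e = 1,
                           residualMode = "homogeneous"))
  expect_equal(max(abs(sol$ghat)), 0, tolerance = 1e-10)
  expect_equal(unname(sol$beta[1]) * sqrt(0.5), 4.2, tolerance = 1e-10)
})

test_that("the balanced and dense engines are algebraically identical", {
  ## likelihood, BLUPs, gradient summaries and AI matrix must match at any
  ## parameter point, including with the (always singular) internal-p G
  fx <- simFixture(nFam = 5, lpf = 5, nSnps = 200, seed = 51)
  md <- suppressWarnings(GenomicRRM:::rrmModelData(
    fx$ph, fx$basis, fx$grm, residualMode = "heterogeneous"))
  ef <- GenomicRRM:::makeFastEngine(md)
  ed <- GenomicRRM:::makeDenseEngine(md)
  G0 <- matrix(0.05, 4, 4) + diag(0.3, 4)
  for (s2 in list(rep(1.2, md$nClass), seq(0.5, 2, length.out = md$nClass))) {
    vf <- ef$eval(G0, s2); vd <- ed$eval(G0, s2)
    relmax <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-12)
    expect_equal(vf$logL, vd$logL, tolerance = 1e-8)
    expect_lt(relmax(vf$beta, vd$beta), 1e-7)
    expect_lt(relmax(vf$ghat, vd$ghat), 1e-6)
    expect_lt(relmax(vf$TT, vd$TT), 1e-6)
    expect_lt(relmax(vf$trwc, vd$trwc), 1e-6)
    G0i <- chol2inv(chol(G0))
    expect_lt(relmax(ef$aiMatrix(vf, G0i, s2), ed$aiMatrix(vd, G0i, s2)),
              1e-6)
    expect_lt(relmax(GenomicRRM:::remlGradient(vf, md, G0i, s2),
                     GenomicRRM:::remlGradient(vd, md, G0i, s2)), 1e-5)
  }
})

test_that("the analytic REML gradient matches finite differences", {
  fx <- simFixture(nFam = 4, lpf = 5, nSnps = 150, seed = 53)
  md <- suppressWarnings(GenomicRRM:::rrmModelData(
    fx$ph, fx$basis, fx$grm, residualMode = "heterogeneous"))
  ef <- GenomicRRM:::makeFastEngine(md)
  G0 <- matrix(0.05, 4, 4) + diag(0.25, 4)
  s2 <- seq(0.8, 1.5, length.out = md$nClass)
  ev <- ef$eval(G0, s2)
  gr <- GenomicRRM:::remlGradient(ev, md, chol2inv(chol(G0)), s2)
  th <- GenomicRRM:::packTheta(G0, s2)
  h <- 1e-5
  num <- vapply(seq_along(th), function(k) {
    up <- GenomicRRM:::unpackTheta(replace(th, k, th[k] + h), 4, md$nClass, 1)
    dn <- GenomicRRM:::unpackTheta(replace(th, k, th[k] - h), 4, md$nClass, 1)
    (ef$eval(up$G0, up$s2, deriv = FALSE)$logL -
       ef$eval(dn$G0, dn$s2, deriv = FALSE)$logL) / (2 * h)
  }, 0)
  expect_equal(gr, num, tolerance = 1e-4)
})

test_that("the balanced and dense REML routes find the same optimum", {
  ## a well-conditioned relationship matrix so both trajectories converge
  fx <- simFixture(nFam = 5, lpf = 5, nSnps = 200, seed = 51)
  G <- 0.9 * grmMatrix(fx$grm) + 0.1 * diag(nrow(grmMatrix(fx$grm)))
  dimnames(G) <- dimnames(grmMatrix(fx$grm))
  for (mode in c("homogeneous", "heterogeneous")) {
    f1 <- suppressWarnings(remlEstimate(fx$ph, fx$basis, G,
                                        residualMode = mode,
                                        method = "balanced"))
    f2 <- suppressWarnings(remlEstimate(fx$ph, fx$basis, G,
                                        residualMode = mode,
                                        method = "dense"))
    ## two independently stopped optimizers: same optimum, small residual
    ## drift along flat directions is expected
    expect_equal(f1@logLik, f2@logLik, tolerance = 1e-6)
    expect_lt(max(abs(f1@G0 - f2@G0)), 5e-3 * max(abs(f2@G0)))
    expect_lt(max(abs(f1@sigma2e - f2@sigma2e)), 5e-3 * max(f2@sigma2e))
    expect_lt(max(abs(f1@ghat - f2@ghat)), 1e-2 * max(abs(f2@ghat)))
  }
})

test_that("REML matches brute-force likelihood maximization (m = 1, n = 30)", {
  set.seed(61)
  lines <- sprintf("L%02d", 1:30)
  ph <- expand.grid(line = lines, env_rep = "E1", dap = c(30, 45, 60, 75),
                    stringsAsFactors = FALSE)
  G <- diag(30); dimnames(G) <- list(lines, lines)
  bs <- timeBasis("legendre", order = 0, dapMin = 27, dapMax = 83)
  li <- match(ph$line, lines)
  g <- rnorm(30, 0, sqrt(0.8))
  ph$value <- 3 + sqrt(0.5) * g[li] + rnorm(nrow(ph), 0, 1)
  fit <- remlEstimate(ph, bs, G, residualMode = "homogeneous", tol = 1e-8)
  expect_true(fit@converged)
  ## oracle: 2-parameter maximization of the explicit V-based REML logL
  Z <- matrix(0, nrow(ph), 30); Z[cbind(seq_len(nrow(ph)), li)] <- sqrt(0.5)
  X <- matrix(sqrt(0.5), nrow(ph), 1)
  obj <- function(lp) -vBasedRemlLogL(ph$value, X,
    exp(lp[1]) * tcrossprod(Z) + exp(lp[2]) * diag(nrow(ph)))
  grid <- expand.grid(a = log(c(0.2, 0.5, 1, 2)), e = log(c(0.3, 1, 3)))
  vals <- apply(grid, 1, obj)
  best <- optim(as.numeric(grid[which.min(vals), ]), obj)$par
  expect_equal(drop(fit@G0), exp(best[1]), tolerance = 1e-3)
  expect_equal(unname(fit@sigma2e), exp(best[2]), tolerance = 1e-3)
  expect_equal(fit@logLik, -obj(best), tolerance = 1e-6)
})

test_that("the REML objective never decreases across accepted iterations", {
  fx <- simFixture(nFam = 6, lpf = 5, nSnps = 200, seed = 71,
                   sigma2e = c(0.5, 1, 2))
  fit <- suppressWarnings(remlEstimate(fx$ph, fx$basis, fx$grm,
                                       residualMode = "heterogeneous"))
  expect_true(all(diff(fit@history$logL) > -1e-6 * (1 + abs(fit@logLik))))
})

test_that("permuting line order permutes BLUPs and leaves estimates alone", {
  fx <- simFixture(nFam = 4, lpf = 5, nSnps = 150, seed = 81)
  fit1 <- suppressWarnings(remlEstimate(fx$ph, fx$basis, fx$grm,
                                        residualMode = "homogeneous"))
  perm <- rev(lineIds(fx$grm))
  G2 <- grmMatrix(fx$grm)[perm, perm]
  set.seed(4)
  ph2 <- fx$ph[sample(nrow(fx$ph)), ]
  fit2 <- suppressWarnings(remlEstimate(ph2, fx$basis, G2,
                                        residualMode = "homogeneous"))
  expect_equal(fit1@logLik, fit2@logLik, tolerance = 1e-6)
  expect_equal(fit1@G0, fit2@G0, tolerance = 1e-5)
  expect_equal(fit1@ghat[perm, ], fit2@ghat, tolerance = 1e-5)
})

test_that("tied heterogeneous classes reproduce the homogeneous likelihood", {
  fx <- simFixture(nFam = 4, lpf = 5, nSnps = 150, seed = 91)
  G0 <- diag(0.4, 4); s2 <- 1.1
  md1 <- suppressWarnings(GenomicRRM:::rrmModelData(
    fx$ph, fx$basis, fx$grm, residualMode = "heterogeneous"))
  md2 <- GenomicRRM:::rrmModelData(fx$ph, fx$basis, fx$grm,
                                   residualMode = "homogeneous")
  e1 <- GenomicRRM:::makeFastEngine(md1)$eval(G0, rep(s2, md1$nClass))
  e2 <- GenomicRRM:::makeFastEngine(md2)$eval(G0, s2)
  expect_equal(e1$logL, e2$logL, tolerance = 1e-6)
  expect_equal(e1$ghat, e2$ghat, tolerance = 1e-8)
})

test_that("AIC ranking sorts converged fits and counts parameters", {
  fx <- simFixture(nFam = 4, lpf = 5, nSnps = 150, seed = 95,
                   daps = seq(27, 83, by = 4))
  fit <- suppressWarnings(remlEstimate(fx$ph, fx$basis, fx$grm,
                                       residualMode = "heterogeneous"))
  ## m(m+1)/2 + number of residual classes actually used
  expect_equal(fit@nVarcompParams, 10 + length(fit@sigma2e))
  expect_equal(fit@AIC, -2 * fit@logLik + 2 * fit@nVarcompParams)
  mk <- function(aic, conv) {
    f <- fit; f@AIC <- aic; f@converged <- conv; f
  }
  tab <- aicCompare(list(a = mk(120, TRUE), b = mk(100, TRUE),
                         c = mk(50, FALSE)))
  expect_equal(tab$model[tab$rank == 1 & !is.na(tab$rank)], "b")
  expect_true(is.na(tab$rank[tab$model == "c"]))
})
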