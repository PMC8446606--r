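## Internal preprocessing shared by the MME/REML engines.
##
## Turns (phenotypes, basis, grm, residual map) into record-level arrays:
## covariate rows for the fixed design (population curve + env_rep treatment
## contrasts) and the random design (per-line basis rows), residual class
## indices (after merging underfilled classes), and the eigendecomposition
## of the phenotyped-line relationship matrix. Kronecker ordering is
## line-major throughout: line i's m coefficients are contiguous and
## var(a) = G (x) G0.

rrmModelData <- function(phenotypes, basis, grm,
                         residualMap = defaultResidualClasses(),
                         residualMode = c("heterogeneous", "homogeneous")) {
  residualMode <- match.arg(residualMode)
  stopifnot(is(basis, "TimeBasis"), is(residualMap, "ResidualClassMap"))
  G <- if (is(grm, "GRMResult")) grm@G else as.matrix(grm)
  ph <- phenotypes
  need <- c("line", "env_rep", "dap", "value")
  stopifnot(all(need %in% names(ph)))
  unknown <- setdiff(unique(ph$line), rownames(G))
  if (length(unknown))
    stop("phenotyped line(s) without a G row: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  lines <- rownames(G)[rownames(G) %in% unique(ph$line)]
  G <- G[lines, lines, drop = FALSE]
  n <- length(lines)
  m <- nCoef(basis)
  if (n < m + 2) stop("need at least m + 2 phenotyped lines")

  if (residualMode == "homogeneous")
    residualMap <- homogeneousClasses(c(residualMap@from[1],
                                        residualMap@to[length(residualMap@to)]))
  mg <- mergeSparseClasses(residualMap, ph$dap, minRecords = 2L)

  daps <- sort(unique(ph$dap))
  Tgrid <- basisMatrix(basis, daps)
  di <- match(ph$dap, daps)
  Trec <- Tgrid[di, , drop = FALSE]
  li <- match(ph$line, lines)

  envLevels <- sort(unique(ph$env_rep))
  p <- m + max(0L, length(envLevels) - 1L)
  Xrec <- matrix(0, nrow(ph), p)
  Xrec[, seq_len(m)] <- Trec
  fixedNames <- colnames(Tgrid)
  if (length(envLevels) > 1) {
    for (k in seq_along(envLevels)[-1])
      Xrec[ph$env_rep == envLevels[k], m + k - 1L] <- 1
    fixedNames <- c(fixedNames, paste0("env_", envLevels[-1]))
  }
  colnames(Xrec) <- fixedNames
  qx <- qr(crossprod(Xrec))
  if (qx$rank < p)
    stop("rank-deficient fixed-effect design; confounded column(s): ",
         paste(fixedNames[qx$pivot[(qx$rank + 1):p]], collapse = ", "))

  eg <- eigen(G, symmetric = TRUE)
  d <- eg$values
  lift <- 1e-8 * mean(diag(G))
  if (min(d) < lift) {
    rrmMessage("G (near-)singular: lifting eigenvalues by %.2e", lift)
    d <- d + lift
  }
  Ginv <- eg$vectors %*% (t(eg$vectors) / d)

  key <- vapply(split(paste(ph$env_rep, ph$dap), ph$line),
                function(z) paste(sort(z), collapse = ";"), "")
  balanced <- length(unique(key)) == 1L

  list(y = ph$value, li = li, ci = mg$classIdx, dap = ph$dap,
       Trec = Trec, Xrec = Xrec, n = n, m = m, p = p,
       lines = lines, envLevels = envLevels, fixedNames = fixedNames,
       G = G, Ginv = Ginv, eigU = eg$vectors, eigD = d,
       logdetG = sum(log(d)), map = mg$map,
       nClass = length(mg$map@from), balanced = balanced, basis = basis)
}

## pack/unpack the variance parameter vector: vech(G0) then residual classes
packTheta <- function(G0, s2) c(G0[upper.tri(G0, diag = TRUE)], s2)

unpackTheta <- function(th, m, nClass, scale) {
  nv <- m * (m + 1) / 2
  G0 <- matrix(0, m, m)
  G0[upper.tri(G0, diag = TRUE)] <- th[seq_len(nv)]
  G0 <- G0 + t(G0) - diag(diag(G0), m)
  s2 <- th[nv + seq_len(nClass)]
  if (any(!is.finite(th))) return(NULL)
  if (any(s2 <= 1e-10 * scale)) return(NULL)
  eg <- eigen(G0, symmetric = TRUE)
  if (min(eg$values) < -0.5 * max(abs(eg$values), scale)) return(NULL)
  ## project onto the PSD cone with a floor that keeps the prior precision
  ## numerically tractable (the floor is far below any detectable variance)
  G0 <- projectPSD(G0, floor = 1e-8 * max(scale, 1e-8))
  list(G0 = G0, s2 = s2)
}

## shared gradient assembly from engine summaries (see engine contracts)
remlGradient <- function(ev, md, G0inv, s2) {
  m <- md$m
  TraceMat <- md$n * G0inv - G0inv %*% ev$TT %*% G0inv
  YMat <- G0inv %*% ev$Ydm %*% G0inv
  Gm <- -0.5 * (TraceMat - YMat)
  mult <- matrix(2, m, m); diag(mult) <- 1
  gG0 <- (Gm * mult)[upper.tri(Gm, diag = TRUE)]
  w <- 1 / s2
  gS2 <- -0.5 * (w * ev$Nc - w^2 * ev$trwc - w^2 * ev$esq)
  c(gG0, gS2)
}

## record-level AI matrix (used by the dense engine): columns of f are
## dV/dtheta_k P y; AI_kl = 0.5 * f_k' P f_l through the engine's MME solve.
aiMatrixGeneric <- function(engine, ev, md, G0inv, s2) {
  m <- md$m
  w <- (1 / s2)[md$ci]
  e <- ev$resid
  At <- ev$ghat %*% G0inv                       # n x m
  ut <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  nv <- nrow(ut)
  Fm <- matrix(0, length(md$y), nv + md$nClass)
  for (k in seq_len(nv)) {
    pq <- ut[k, ]
    f <- md$Trec[, pq[1]] * At[md$li, pq[2]]
    if (pq[1] != pq[2]) f <- f + md$Trec[, pq[2]] * At[md$li, pq[1]]
    Fm[, k] <- f
  }
  Fm[cbind(seq_along(md$y), nv + md$ci)] <- w * e
  Q <- engine$quadForm(Fm, w)
  0.5 * (crossprod(Fm, Fm * w) - Q)
}
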