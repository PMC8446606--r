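## Fast REML engine for line-balanced designs (every phenotyped line shares
## one (env_rep, DAP) record design). Rotating the random effects by the
## eigenvectors of G block-diagonalizes the random part of the mixed-model
## equations into n independent m x m blocks, so each REML iteration costs
## O(n m^3) instead of O((n m)^3). Exact: the rotation is orthogonal and all
## determinants and traces are preserved; equality with the dense engine is
## enforced by tests.

## batched products with the per-line m x m blocks V_j, stored as rows of
## an n x m^2 matrix (column-major vec per block)
bvMultVec <- function(Vm, X, m) {
  out <- matrix(0, nrow(Vm), m)
  for (pp in seq_len(m)) for (qq in seq_len(m))
    out[, pp] <- out[, pp] + Vm[, (qq - 1L) * m + pp] * X[, qq]
  out
}

## row-wise V_j %*% A for a fixed m x m matrix A
bvMultMat <- function(Vm, A, m) {
  out <- matrix(0, nrow(Vm), m * m)
  for (pp in seq_len(m)) for (ss in seq_len(m)) {
    col <- (ss - 1L) * m + pp
    for (qq in seq_len(m))
      out[, col] <- out[, col] + Vm[, (qq - 1L) * m + pp] * A[qq, ss]
  }
  out
}

## row-wise (B_j %*% V_j) where B_j rows of Bm
bvMultBlocks <- function(Bm, Vm, m) {
  out <- matrix(0, nrow(Vm), m * m)
  for (pp in seq_len(m)) for (ss in seq_len(m)) {
    col <- (ss - 1L) * m + pp
    for (qq in seq_len(m))
      out[, col] <- out[, col] + Bm[, (qq - 1L) * m + pp] * Vm[, (ss - 1L) * m + qq]
  }
  out
}

makeFastEngine <- function(md) {
  stopifnot(md$balanced)
  N <- length(md$y); m <- md$m; n <- md$n; p <- md$p
  nC <- md$nClass
  lif <- factor(md$li, levels = seq_len(n))
  ## per-class, per-line design summaries (identical across lines)
  Sx <- array(0, c(p, p, nC)); Sc <- array(0, c(m, m, nC))
  Bc <- array(0, c(p, m, nC)); xy <- matrix(0, p, nC)
  yy <- numeric(nC); NcT <- numeric(nC)
  ric <- vector("list", nC)
  for (c in seq_len(nC)) {
    ix <- md$ci == c
    Xc <- md$Xrec[ix, , drop = FALSE]; Tc <- md$Trec[ix, , drop = FALSE]
    Sx[, , c] <- crossprod(Xc) / n
    Sc[, , c] <- crossprod(Tc) / n
    Bc[, , c] <- crossprod(Xc, Tc) / n
    xy[, c] <- colSums(Xc * md$y[ix])
    yy[c] <- sum(md$y[ix]^2)
    NcT[c] <- sum(ix)
    r <- rowsum(Tc * md$y[ix], lif[ix])
    r[is.na(r)] <- 0
    ric[[c]] <- r
  }
  U <- md$eigU; dvec <- md$eigD; u <- colSums(U)
  cache <- new.env(parent = emptyenv())

  evalFun <- function(G0, s2, deriv = TRUE) {
    wc <- 1 / s2
    S <- matrix(0, m, m); Bw <- matrix(0, p, m); Cxx <- matrix(0, p, p)
    rx <- numeric(p); Rw <- matrix(0, n, m)
    for (c in seq_len(nC)) {
      S <- S + wc[c] * Sc[, , c]; Bw <- Bw + wc[c] * Bc[, , c]
      Cxx <- Cxx + wc[c] * n * Sx[, , c]; rx <- rx + wc[c] * xy[, c]
      Rw <- Rw + wc[c] * ric[[c]]
    }
    chG0 <- tryCatch(chol(G0), error = function(e) NULL)
    if (is.null(chG0)) return(list(logL = -Inf))
    G0inv <- chol2inv(chG0)
    Rt <- crossprod(U, Rw)
    Vm <- matrix(0, n, m * m)
    logdetK <- 0
    ok <- TRUE
    for (j in seq_len(n)) {
      K <- S + G0inv / dvec[j]
      chK <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(chK)) { ok <- FALSE; break }
      logdetK <- logdetK + 2 * sum(log(diag(chK)))
      Vm[j, ] <- chol2inv(chK)
    }
    if (!ok) return(list(logL = -Inf))
    Vsum <- matrix(colSums(Vm), m, m)
    Vsum2 <- matrix(colSums(Vm * u^2), m, m)
    vr <- colSums(u * bvMultVec(Vm, Rt, m))
    Mx <- Cxx - Bw %*% Vsum2 %*% t(Bw)
    chMx <- tryCatch(chol(Mx), error = function(e) NULL)
    if (is.null(chMx)) return(list(logL = -Inf))
    Fx <- chol2inv(chMx)
    beta <- drop(Fx %*% (rx - Bw %*% vr))
    Bb <- drop(crossprod(Bw, beta))
    Atil <- bvMultVec(Vm, Rt - outer(u, Bb), m)
    ghat <- U %*% Atil
    rownames(ghat) <- md$lines
    logdetC <- logdetK + 2 * sum(log(diag(chMx)))
    yPy <- sum(wc * yy) - sum(beta * rx) - sum(Atil * Rt)
    logL <- -0.5 * ((N - p) * log(2 * pi) + sum(NcT * log(s2)) +
                    m * md$logdetG + n * 2 * sum(log(diag(chG0))) +
                    logdetC + yPy)
    e <- md$y - as.vector(md$Xrec %*% beta) -
      rowSums(md$Trec * ghat[md$li, , drop = FALSE])
    ev <- list(logL = logL, beta = beta, ghat = ghat, resid = e, Nc = NcT)
    cache$Vm <- Vm; cache$Fx <- Fx; cache$Bw <- Bw; cache$S <- S
    if (deriv) {
      W0 <- crossprod(Bw, Fx %*% Bw)                     # m x m
      VW <- bvMultMat(Vm, W0, m)                         # V_j W0
      VWV <- bvMultBlocks(VW, Vm, m)                     # V_j W0 V_j
      Qsum2 <- matrix(colSums(VWV * u^2), m, m)
      TT <- matrix(colSums((Vm + VWV * u^2) / dvec), m, m)
      ev$TT <- (TT + t(TT)) / 2
      ev$Ydm <- crossprod(Atil, Atil / dvec)
      FBV <- Fx %*% Bw %*% Vsum2
      VQ <- Vsum + Qsum2
      trwc <- numeric(nC)
      for (c in seq_len(nC))
        trwc[c] <- n * sum(Fx * Sx[, , c]) - 2 * sum(FBV * Bc[, , c]) +
          sum(VQ * Sc[, , c])
      ev$trwc <- trwc
      ev$esq <- as.vector(rowsum(e^2, factor(md$ci, levels = seq_len(nC))))
      ev$esq[is.na(ev$esq)] <- 0
      ev$emG0 <- (ev$Ydm + ev$TT) / n
      ev$emS2 <- ifelse(NcT > 0, (ev$esq + trwc) / NcT, s2)
    }
    ev
  }

  ## AI matrix from closed-form aggregates: under balance every inner
  ## product f_k' R^-1 f_l and every MME right-hand side reduces to small
  ## per-line / per-class summaries, so no record-level matrix is formed.
  aiMatrix <- function(ev, G0inv, s2) {
    wc <- 1 / s2
    Vm <- cache$Vm; Fx <- cache$Fx; Bw <- cache$Bw; Sw <- cache$S
    At <- ev$ghat %*% G0inv                    # n x m, line space
    e <- ev$resid
    ut <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
    nv <- nrow(ut)
    np <- nv + nC
    pairs <- lapply(seq_len(nv), function(k) {
      pq <- ut[k, ]
      if (pq[1] == pq[2]) list(pq) else list(pq, rev(pq))
    })
    CA <- crossprod(At)
    sA <- colSums(At)
    grp <- md$li + n * (md$ci - 1L)
    Epc <- array(rowsum(md$Trec * e, grp), c(n, nC, m))
    XE <- rowsum(md$Xrec * e, md$ci)           # nC x p
    AI0 <- matrix(0, np, np)
    for (k in seq_len(nv)) for (l in k:nv) {
      v <- 0
      for (ab in pairs[[k]]) for (ab2 in pairs[[l]])
        v <- v + Sw[ab[1], ab2[1]] * CA[ab[2], ab2[2]]
      AI0[k, l] <- AI0[l, k] <- v
    }
    EA <- array(0, c(m, m, nC))
    for (c in seq_len(nC))
      EA[, , c] <- crossprod(Epc[, c, ], At)
    for (k in seq_len(nv)) for (c in seq_len(nC)) {
      v <- 0
      for (ab in pairs[[k]]) v <- v + EA[ab[1], ab[2], c]
      AI0[k, nv + c] <- AI0[nv + c, k] <- wc[c]^2 * v
    }
    diag(AI0)[nv + seq_len(nC)] <- wc^3 * ev$esq
    ## quadratic correction rhs' C^-1 rhs in transformed coordinates
    UtA <- crossprod(U, At)
    UtE <- array(crossprod(U, matrix(Epc, n, nC * m)), c(n, nC, m))
    rhsX <- matrix(0, p, np)
    RztM <- matrix(0, n * m, np)
    for (k in seq_len(nv)) {
      rz <- matrix(0, n, m)
      for (ab in pairs[[k]]) {
        rhsX[, k] <- rhsX[, k] + Bw[, ab[1]] * sA[ab[2]]
        rz <- rz + outer(UtA[, ab[2]], Sw[, ab[1]])
      }
      RztM[, k] <- rz
    }
    for (c in seq_len(nC)) {
      rhsX[, nv + c] <- wc[c]^2 * XE[c, ]
      RztM[, nv + c] <- wc[c]^2 * UtE[, c, ]
    }
    bsol <- matrix(0, p, np); AsolM <- matrix(0, n * m, np)
    for (k in seq_len(np)) {
      Rz <- matrix(RztM[, k], n, m)
      vr <- colSums(u * bvMultVec(Vm, Rz, m))
      bl <- drop(Fx %*% (rhsX[, k] - Bw %*% vr))
      bsol[, k] <- bl
      AsolM[, k] <- bvMultVec(Vm, Rz - outer(u, drop(crossprod(Bw, bl))), m)
    }
    Q <- crossprod(rhsX, bsol) + crossprod(RztM, AsolM)
    0.5 * (AI0 - (Q + t(Q)) / 2)
  }

  list(eval = evalFun, aiMatrix = aiMatrix, kind = "balanced")
}
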