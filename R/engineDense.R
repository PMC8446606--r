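## General dense-MME REML engine. Valid for any record design; cost is
## dominated by Cholesky/inversion of the (p + n m)-dimensional coefficient
## matrix, so it is the reference route and the fallback for unbalanced
## designs, while balanced designs use the eigendecomposition engine.

makeDenseEngine <- function(md) {
  N <- length(md$y); m <- md$m; n <- md$n; p <- md$p
  ridx <- p + seq_len(n * m)
  Zs <- Matrix::sparseMatrix(
    i = rep(seq_len(N), m),
    j = as.vector(vapply(seq_len(m), function(k) (md$li - 1L) * m + k,
                         integer(N))),
    x = as.vector(md$Trec), dims = c(N, n * m))
  W <- Matrix::cbind2(Matrix::Matrix(md$Xrec, sparse = TRUE), Zs)
  Nc <- tabulate(md$ci, md$nClass)
  cache <- new.env(parent = emptyenv())

  evalFun <- function(G0, s2, deriv = TRUE) {
    w <- (1 / s2)[md$ci]
    C <- as.matrix(Matrix::crossprod(W, W * w))
    G0inv <- tryCatch(chol2inv(chol(G0)), error = function(e) NULL)
    if (is.null(G0inv)) return(list(logL = -Inf))
    C[ridx, ridx] <- C[ridx, ridx] + md$Ginv %x% G0inv
    rhs <- as.vector(Matrix::crossprod(W, w * md$y))
    ## Jacobi scaling: a near-singular G makes the prior precision block
    ## dominate some rows by many orders of magnitude; equilibrating the
    ## diagonal keeps the factorization and the trace terms accurate
    ds <- 1 / sqrt(pmax(diag(C), .Machine$double.xmin))
    ch <- tryCatch(chol(C * tcrossprod(ds)), error = function(e) NULL)
    if (is.null(ch)) return(list(logL = -Inf))
    sol <- ds * backsolve(ch, backsolve(ch, ds * rhs, transpose = TRUE))
    yPy <- sum(w * md$y^2) - sum(sol * rhs)
    logdetC <- logDetChol(ch) - 2 * sum(log(ds))
    logL <- -0.5 * ((N - p) * log(2 * pi) + sum(Nc * log(s2)) +
                    m * md$logdetG + n * 2 * sum(log(diag(chol(G0)))) +
                    logdetC + yPy)
    beta <- sol[seq_len(p)]
    ghat <- t(matrix(sol[ridx], m, n))
    rownames(ghat) <- md$lines
    e <- md$y - as.vector(md$Xrec %*% beta) -
      rowSums(md$Trec * ghat[md$li, , drop = FALSE])
    ev <- list(logL = logL, beta = beta, ghat = ghat, resid = e, Nc = Nc)
    if (deriv) {
      Cinv <- chol2inv(ch) * tcrossprod(ds)
      cache$ch <- ch; cache$ds <- ds
      Caa <- Cinv[ridx, ridx]
      TT <- matrix(matrix(aperm(array(Caa, c(m, n, m, n)), c(1, 3, 2, 4)),
                          m * m, n * n) %*% as.vector(md$Ginv), m, m)
      ev$TT <- (TT + t(TT)) / 2
      ev$Ydm <- crossprod(ghat, md$Ginv %*% ghat)
      dw <- numeric(N)
      for (st in seq(1, N, by = 4000L)) {
        ix <- st:min(st + 3999L, N)
        B <- as.matrix(W[ix, , drop = FALSE] %*% Cinv)
        dw[ix] <- rowSums(B * as.matrix(W[ix, , drop = FALSE]))
      }
      ev$trwc <- as.vector(rowsum(dw, factor(md$ci, levels = seq_len(md$nClass))))
      ev$esq <- as.vector(rowsum(e^2, factor(md$ci, levels = seq_len(md$nClass))))
      ev$trwc[is.na(ev$trwc)] <- 0; ev$esq[is.na(ev$esq)] <- 0
      ## EM updates (guaranteed-uphill fallback)
      ev$emG0 <- (ev$Ydm + ev$TT) / n
      ev$emS2 <- ifelse(Nc > 0, (ev$esq + ev$trwc) / Nc, s2)
    }
    ev
  }

  quadForm <- function(Fm, w) {
    R <- as.matrix(Matrix::crossprod(W, Fm * w))
    Rs <- R * cache$ds
    S <- backsolve(cache$ch, backsolve(cache$ch, Rs, transpose = TRUE))
    crossprod(Rs, S)
  }

  engine <- list(eval = evalFun, quadForm = quadForm, kind = "dense")
  engine$aiMatrix <- function(ev, G0inv, s2)
    aiMatrixGeneric(engine, ev, md, G0inv, s2)
  engine
}
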