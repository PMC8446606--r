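#' Derive a module-specific seed from the run seed
#'
#' All randomness in the package flows from a single run seed; each module
#' draws from its own stream obtained by hashing the module name into a
#' 31-bit offset. Keeps derived seeds valid 32-bit integers.
#'
#' @param seed integer run seed.
#' @param module character module label, e.g. `"cv"`, `"genotypes"`.
#' @return an integer seed.
#' @export
moduleSeed <- function(seed, module) {
  h <- 0
  for (ch in utf8ToInt(module)) h <- (h * 31 + ch) %% 1048573
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h) %% 2147483647L)
}

## symmetric pseudo-inverse with relative eigenvalue tolerance
pinvSym <- function(A, tol = 1e-10) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- eg$values > tol * max(abs(eg$values), .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  V <- eg$vectors[, keep, drop = FALSE]
  V %*% (t(V) / eg$values[keep])
}

## project a symmetric matrix onto the PSD cone (eigenvalue clipping)
projectPSD <- function(A, floor = 0) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  v <- pmax(eg$values, floor)
  out <- eg$vectors %*% (t(eg$vectors) * v)
  (out + t(out)) / 2
}

## log-determinant via Cholesky; stops with a clear message if not PD
logDetChol <- function(ch) 2 * sum(log(diag(ch)))

## small diagonal lift used before inverting relationship matrices
liftDiag <- function(A, eps = 1e-8) {
  A + diag(eps * mean(diag(A)), nrow(A))
}

rrmMessage <- function(...) message("[GenomicRRM] ", sprintf(...))
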