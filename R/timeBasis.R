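#' Construct a covariance-function time basis
#'
#' @param kind `"legendre"` or `"bspline"`.
#' @param order highest Legendre polynomial order; the basis then has
#'   `order + 1` coefficients (order 0 is the constant). Legendre only.
#' @param degree B-spline degree, 1 (linear) or 2 (quadratic). B-spline only.
#' @param knots numeric vector of interior knots, strictly increasing and
#'   strictly inside `(dapMin, dapMax)`. B-spline only; may be empty.
#' @param dapMin,dapMax the DAP range the basis is defined on.
#' @return a [TimeBasis-class] object.
#' @examples
#' timeBasis("legendre", order = 3, dapMin = 27, dapMax = 83)
#' timeBasis("bspline", degree = 1, knots = c(44, 66), dapMin = 27, dapMax = 83)
#' @export
timeBasis <- function(kind = c("legendre", "bspline"), order = 2L,
                      degree = 1L, knots = numeric(0),
                      dapMin = 27, dapMax = 83) {
  kind <- match.arg(kind)
  new("TimeBasis", kind = kind, order = as.integer(order),
      degree = as.integer(degree), knots = as.numeric(knots),
      dapMin = as.numeric(dapMin), dapMax = as.numeric(dapMax))
}

#' Standardize days after planting to [-1, 1]
#'
#' Affine map sending `dapMin` to -1 and `dapMax` to +1, as used for
#' Legendre polynomial covariance functions.
#'
#' @param dap numeric vector of days.
#' @param dapMin,dapMax range bounds (`dapMin < dapMax`).
#' @return numeric vector in `[-1, 1]`.
#' @examples
#' standardizeTime(c(27, 55, 83), 27, 83)  # -1, 0, 1
#' @export
standardizeTime <- function(dap, dapMin, dapMax) {
  if (dapMin >= dapMax) stop("dapMin must be < dapMax")
  if (any(dap < dapMin - 1e-9) || any(dap > dapMax + 1e-9))
    stop(sprintf("dap outside [%g, %g]", dapMin, dapMax))
  -1 + 2 * (dap - dapMin) / (dapMax - dapMin)
}

## raw Legendre polynomials P_0..P_k at standardized t (Bonnet recurrence)
legendreRaw <- function(t, kmax) {
  P <- matrix(0, length(t), kmax + 1L)
  P[, 1] <- 1
  if (kmax >= 1) P[, 2] <- t
  if (kmax >= 2) for (k in 2:kmax)
    P[, k + 1] <- ((2 * k - 1) * t * P[, k] - (k - 1) * P[, k - 1]) / k
  P
}

#' Evaluate a time basis as a covariate matrix
#'
#' Returns the matrix \eqn{T} whose row for day \eqn{t} holds
#' \eqn{\phi_1(t), \ldots, \phi_m(t)}. For the Legendre kind, column
#' \eqn{k+1} is the normalized polynomial
#' \eqn{\phi_k(t) = \sqrt{(2k+1)/2}\, P_k(t)} on time standardized to
#' \eqn{[-1,1]}. For B-splines, the Cox--de Boor recursion is used with
#' clamped boundary knots (multiplicity `degree + 1` at both ends), 0/0
#' ratios defined as 0, and the last basis function including the right
#' endpoint, so the basis partitions unity on the whole range.
#'
#' @param basis a [TimeBasis-class].
#' @param daps numeric vector of days within the basis range.
#' @return a `length(daps) x nCoef(basis)` matrix.
#' @examples
#' bs <- timeBasis("bspline", degree = 1, knots = c(44, 66), dapMin = 27, dapMax = 83)
#' rowSums(basisMatrix(bs, 27:83))  # all 1: partition of unity
#' @export
basisMatrix <- function(basis, daps) {
  stopifnot(is(basis, "TimeBasis"))
  if (!length(daps)) stop("empty dap vector")
  if (any(daps < basis@dapMin - 1e-9) || any(daps > basis@dapMax + 1e-9))
    stop(sprintf("dap outside basis range [%g, %g]", basis@dapMin, basis@dapMax))
  if (basis@kind == "legendre") {
    t <- standardizeTime(daps, basis@dapMin, basis@dapMax)
    k <- basis@order
    P <- legendreRaw(t, k)
    Tm <- sweep(P, 2, sqrt((2 * (0:k) + 1) / 2), `*`)
    colnames(Tm) <- paste0("leg", 0:k)
  } else {
    Tm <- bsplineMatrix(daps, basis@degree, basis@knots, basis@dapMin,
                        basis@dapMax)
    colnames(Tm) <- paste0("bs", seq_len(ncol(Tm)))
  }
  rownames(Tm) <- as.character(daps)
  Tm
}

## Cox-de Boor recursion on the clamped knot vector; 0/0 := 0; the last
## degree-0 indicator is closed on the right so T has no zero row at dapMax.
bsplineMatrix <- function(t, p, innerKnots, lo, hi) {
  kv <- c(rep(lo, p + 1), innerKnots, rep(hi, p + 1))
  nb0 <- length(kv) - 1L                      # degree-0 functions
  B <- matrix(0, length(t), nb0)
  lastNonDeg <- max(which(kv < hi))           # last interval with width > 0
  for (m in seq_len(nb0)) {
    if (kv[m + 1] > kv[m])
      B[, m] <- as.numeric(t >= kv[m] & (t < kv[m + 1] |
                  (m == lastNonDeg & t == hi)))
  }
  if (p > 0) for (d in seq_len(p)) {
    nb <- nb0 - d
    Bn <- matrix(0, length(t), nb)
    for (m in seq_len(nb)) {
      den1 <- kv[m + d] - kv[m]
      den2 <- kv[m + d + 1] - kv[m + 1]
      r1 <- if (den1 > 0) (t - kv[m]) / den1 * B[, m] else 0
      r2 <- if (den2 > 0) (kv[m + d + 1] - t) / den2 * B[, m + 1] else 0
      Bn[, m] <- r1 + r2
    }
    B <- Bn
  }
  B
}
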