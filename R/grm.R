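#' SNP quality control
#'
#' Removes SNPs with minor allele frequency below `mafMin` or per-SNP call
#' rate (fraction of non-missing lines) below `callRateMin`, then imputes
#' remaining missing dosages to twice the observed allele frequency
#' \eqn{2\hat p}. Frequencies are estimated from the analyzed panel.
#'
#' @param panel a [GenotypePanel-class].
#' @param mafMin minimum minor allele frequency, in `(0, 0.5]`.
#' @param callRateMin minimum call rate, in `(0, 1]`.
#' @return a QC'd, imputed [GenotypePanel-class].
#' @export
qcFilter <- function(panel, mafMin = 0.05, callRateMin = 0.90) {
  stopifnot(is(panel, "GenotypePanel"))
  if (mafMin <= 0 || mafMin > 0.5) stop("mafMin must be in (0, 0.5]")
  if (callRateMin <= 0 || callRateMin > 1) stop("callRateMin must be in (0, 1]")
  M <- panel@dosages
  callRate <- colMeans(!is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- callRate >= callRateMin & maf >= mafMin
  rrmMessage("QC: removed %d of %d SNPs (call rate < %g: %d; MAF < %g: %d)",
             sum(!keep), ncol(M), callRateMin, sum(callRate < callRateMin),
             mafMin, sum(maf < mafMin & callRate >= callRateMin))
  if (!any(keep)) stop("zero SNPs survive QC")
  M <- M[, keep, drop = FALSE]
  p <- p[keep]
  nmiss <- sum(is.na(M))
  if (nmiss) {
    miss <- which(is.na(M), arr.ind = TRUE)
    M[miss] <- 2 * p[miss[, 2]]
    rrmMessage("imputed %d missing dosage(s) to 2*p-hat", nmiss)
  }
  newGenotypePanel(M, panel@snpInfo[keep, , drop = FALSE], imputed = TRUE)
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: dosages are column-centered by twice the observed allele
#' frequency, \eqn{Z = M - 2p}, and
#' \eqn{G = Z Z' / (2 \sum_j p_j (1 - p_j))}.
#'
#' @param panel a QC'd [GenotypePanel-class] with no missing values (see
#'   [qcFilter()]).
#' @return a [GRMResult-class].
#' @export
vanRadenGRM <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  M <- panel@dosages
  if (anyNA(M)) stop("panel has missing dosages; run qcFilter() first")
  p <- colMeans(M) / 2
  k <- 2 * sum(p * (1 - p))
  if (k <= 0) stop("all SNPs fixed: zero VanRaden scale 2*sum(p(1-p))")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / k
  G <- (G + t(G)) / 2
  new("GRMResult", G = G, Zc = Z, pFreq = unname(p), kScale = k,
      snpInfo = panel@snpInfo)
}

#' Export / import a GRM as TSV
#'
#' Symmetric matrix with a line-id header column and row.
#'
#' @param grm a [GRMResult-class] (export) or file path (import).
#' @param path output path.
#' @return `exportGRM`: `path` invisibly; `importGRM`: a symmetric matrix
#'   with line-id dimnames.
#' @export
exportGRM <- function(grm, path) {
  stopifnot(is(grm, "GRMResult"))
  df <- data.frame(line = rownames(grm@G), grm@G, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportGRM
#' @export
importGRM <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df$line
  (G + t(G)) / 2
}
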