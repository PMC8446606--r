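## Independent oracles and fixture builders shared across tests.

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch: eigen of the
## Jacobi matrix). Exact for polynomials of degree <= 2n - 1.
gaussLegendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  eg <- eigen(J, symmetric = TRUE)
  list(nodes = eg$values, weights = 2 * eg$vectors[1, ]^2)
}

## explicit V-based REML log-likelihood (the identity the MME route must
## reproduce): -0.5 [ (N-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
vBasedRemlLogL <- function(y, X, V) {
  N <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XtVX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtVX, crossprod(X, Vi))
  -0.5 * ((N - p) * log(2 * pi) + as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtVX)$modulus) +
            drop(crossprod(y, P %*% y)))
}

## small deterministic dosage panel with given matrix (lines x SNPs)
panelFromMatrix <- function(M, chrom = NULL, pos = NULL) {
  if (is.null(rownames(M))) rownames(M) <- sprintf("L%02d", seq_len(nrow(M)))
  s <- ncol(M)
  if (is.null(chrom)) chrom <- rep("Chr01", s)
  if (is.null(pos)) pos <- seq_len(s) * 1000L
  colnames(M) <- paste0(chrom, "_", pos)
  GenomicRRM:::newGenotypePanel(
    M, data.frame(snp_id = colnames(M), chrom = chrom, pos = pos,
                  stringsAsFactors = FALSE))
}

## balanced longitudinal phenotypes + GRM fixture for solver tests
simFixture <- function(nFam = 6, lpf = 6, nSnps = 300, basis = NULL,
                       G0 = NULL, sigma2e = 1, daps = seq(27, 83, by = 7),
                       envReps = c("E1", "E2"), seed = 42, ...) {
  if (is.null(basis)) basis <- timeBasis("bspline", degree = 1, knots = c(44, 66))
  if (is.null(G0)) G0 <- diag(0.3, nCoef(basis))
  panel <- simulateRilGenotypes(nFam, lpf, nSnps, nChrom = 4, seed = seed)
  sim <- simulatePhenotypes(panel, basis, G0 = G0, sigma2e = sigma2e,
                            dapGrid = daps, envReps = envReps,
                            seed = seed + 1, ...)
  grm <- vanRadenGRM(panel)
  list(panel = panel, grm = grm, ph = sim$phenotypes, truth = sim$truth,
       basis = basis)
}

## a tiny VCF written from code (text only, biallelic unless stated)
writeTestVcf <- function(path, multiAllelicRow = TRUE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "L1", "L2", "L3", sep = "\t"))
  rows <- c(
    "Chr01\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "Chr01\t200\ts2\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0\t./1",
    if (multiAllelicRow)
      "Chr01\t300\ts3\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0",
    "Chr02\t100\ts4\tT\tA\t.\tPASS\t.\tGT\t./.\t0/0\t0/1",
    "Chr02\t250\ts5\tA\tC\t.\tPASS\t.\tGT\t1/1\t1/1\t0/0")
  writeLines(c(hdr, rows), path)
  path
}
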