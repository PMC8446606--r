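#' Simulate genotypes for a nested-association RIL panel
#'
#' Emulates a nested-association RIL panel: each family is a biparental
#' cross of two simulated inbred founders, followed by repeated selfing
#' approximated by sampling a fully inbred line genome as a founder mosaic
#' along each chromosome (first-order Markov chain over markers with
#' per-interval recombination probability). Dosages are 0/2 except for an optional
#' residual-heterozygosity rate; positions are drawn uniformly per
#' chromosome and sorted.
#'
#' @param nFamilies number of biparental families.
#' @param linesPerFamily inbred lines per family.
#' @param nSnps total SNPs (split as evenly as possible across chromosomes).
#' @param nChrom number of chromosomes.
#' @param seed integer seed.
#' @param chromLengthMorgan genetic length per chromosome; the per-interval
#'   recombination probability is `chromLengthMorgan / (snps per chrom - 1)`.
#' @param chromLengthBp physical length used to draw positions.
#' @param residualHet per-marker probability of a residual heterozygote
#'   (dosage 1).
#' @return a [GenotypePanel-class]; the family of each line is encoded in
#'   its id (`F01_L001`, ...).
#' @export
simulateRilGenotypes <- function(nFamilies = 32L, linesPerFamily = 12L,
                                 nSnps = 5000L, nChrom = 20L, seed = 1L,
                                 chromLengthMorgan = 1.2,
                                 chromLengthBp = 5e7, residualHet = 0.002) {
  if (nFamilies < 1 || linesPerFamily < 1 || nSnps < 1 || nChrom < 1)
    stop("all counts must be >= 1")
  if (nSnps < nChrom) stop("nSnps must be >= nChrom")
  set.seed(moduleSeed(seed, "genotypes"))
  perChrom <- diff(round(seq(0, nSnps, length.out = nChrom + 1)))
  n <- nFamilies * linesPerFamily
  fam <- rep(seq_len(nFamilies), each = linesPerFamily)
  ids <- sprintf("F%02d_L%03d", fam, seq_len(n))
  ## two independent inbred founders per family (alleles Bernoulli(0.5))
  fndA <- matrix(stats::rbinom(nSnps * nFamilies, 1, 0.5), nFamilies)
  fndB <- matrix(stats::rbinom(nSnps * nFamilies, 1, 0.5), nFamilies)
  M <- matrix(0, n, nSnps, dimnames = list(ids, NULL))
  info <- vector("list", nChrom)
  off <- 0L
  for (ch in seq_len(nChrom)) {
    s <- perChrom[ch]
    if (!s) next
    cols <- off + seq_len(s)
    r <- if (s > 1) min(0.5, chromLengthMorgan / (s - 1)) else 0
    for (f in seq_len(nFamilies)) {
      rows <- which(fam == f)
      nl <- length(rows)
      ## founder mosaic: 0 = hub, 1 = diverse; switch w.p. r per interval
      start <- stats::rbinom(nl, 1, 0.5)
      if (s > 1) {
        sw <- matrix(stats::rbinom(nl * (s - 1), 1, r), nl)
        mosaic <- (start + cbind(0, t(apply(sw, 1, cumsum)))) %% 2
      } else mosaic <- matrix(start, nl, 1)
      hap <- matrix(fndA[f, cols], nl, s, byrow = TRUE)
      dv <- matrix(fndB[f, cols], nl, s, byrow = TRUE)
      hap[mosaic == 1] <- dv[mosaic == 1]
      M[rows, cols] <- 2 * hap
    }
    pos <- sort(sample.int(chromLengthBp, s))
    info[[ch]] <- data.frame(chrom = sprintf("Chr%02d", ch), pos = pos)
    off <- off + s
  }
  info <- do.call(rbind, info)
  info <- data.frame(snp_id = paste0(sub("Chr0?", "", info$chrom), ":", info$pos),
                     chrom = info$chrom, pos = info$pos,
                     stringsAsFactors = FALSE)
  if (residualHet > 0) {
    het <- which(stats::runif(length(M)) < residualHet)
    M[het] <- 1
  }
  colnames(M) <- info$snp_id
  newGenotypePanel(M, info)
}

#' Solve for a coefficient covariance matching a heritability profile
#'
#' Finds a positive semi-definite \eqn{G_0} whose implied per-DAP additive
#' variance, \eqn{diag(T G_0 T')}, best matches the variance profile implied
#' by a requested heritability curve and residual variances
#' (\eqn{\sigma^2_a(t) = h^2(t) \sigma^2_e(t) / (1 - h^2(t))}), by
#' alternating linear least squares on the distinct entries of \eqn{G_0}
#' with projection onto the PSD cone.
#'
#' @param basis a [TimeBasis-class].
#' @param h2Profile per-day target heritability on `dapGrid`, in `[0, 1)`.
#' @param sigma2e residual variance per class of `residualMap`.
#' @param residualMap a [ResidualClassMap-class].
#' @param dapGrid days on which the profile is specified.
#' @return an m x m PSD matrix.
#' @export
g0ForH2Profile <- function(basis, h2Profile, sigma2e,
                           residualMap = defaultResidualClasses(),
                           dapGrid = seq(basis@dapMin, basis@dapMax)) {
  stopifnot(length(h2Profile) == length(dapGrid), all(h2Profile >= 0),
            all(h2Profile < 1))
  cls <- classOfDap(residualMap, dapGrid)
  s2e <- rep(sigma2e, length.out = length(residualMap@from))[cls]
  v <- h2Profile * s2e / (1 - h2Profile)
  Tm <- basisMatrix(basis, dapGrid)
  m <- ncol(Tm)
  ut <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  X <- Tm[, ut[, 1]] * Tm[, ut[, 2]]
  X[, ut[, 1] != ut[, 2]] <- 2 * X[, ut[, 1] != ut[, 2], drop = FALSE]
  G0 <- matrix(0, m, m)
  target <- v
  for (it in 1:25) {
    th <- stats::lm.fit(X, target)$coefficients
    th[is.na(th)] <- 0
    Gu <- matrix(0, m, m)
    Gu[upper.tri(Gu, diag = TRUE)] <- th
    Gu <- Gu + t(Gu) - diag(diag(Gu))
    G0 <- projectPSD(Gu)
    ## alternating projection: re-target residual of the PSD part
    target <- v - (rowSums((Tm %*% G0) * Tm) - X %*% th)
    if (max(abs(Gu - G0)) < 1e-10) break
  }
  G0
}

#' Simulate longitudinal phenotypes from the RRM generative model
#'
#' Draws per-line random regression coefficients with covariance
#' \eqn{G \otimes G_0} (G the VanRaden matrix of the panel, via a Cholesky
#' or eigen square root with a logged `1e-8` diagonal lift when needed) and
#' generates records
#' \eqn{y_{ijk} = Env_k + \sum_m b_m \phi_m(t) + \sum_m a_{im} \phi_m(t) + e_{ijk}}
#' with class-wise residual variance. The full ground truth is retained.
#'
#' Either supply `G0` (with `sigma2e`), or supply `h2Profile` and the
#' coefficient covariance is solved for with [g0ForH2Profile()].
#'
#' @param panel a [GenotypePanel-class] without missing dosages.
#' @param basis the generating [TimeBasis-class].
#' @param G0 m x m PSD coefficient covariance (coefficient scale).
#' @param sigma2e residual variance per class (recycled across classes).
#' @param h2Profile optional per-day target heritability (see above).
#' @param residualMap a [ResidualClassMap-class].
#' @param dapGrid observed days (default: every integer DAP in the basis range).
#' @param envReps env x replication labels; one record per line, env_rep and
#'   observed day.
#' @param beta fixed population-curve coefficients; default: least-squares
#'   basis fit of a logistic growth curve with amplitude 10 on the trait
#'   scale (the trait scale is arbitrary and unit-agnostic).
#' @param envEffects fixed effect per env_rep; default small draws
#'   `N(0, 0.25)` from the module seed.
#' @param missingRate optional per-env_rep record dropout rate(s), emulating
#'   unequal replication across environments.
#' @param seed integer seed.
#' @return `list(phenotypes = data.frame(line, env_rep, dap, value),
#'   truth = SyntheticTruth)`.
#' @export
simulatePhenotypes <- function(panel, basis, G0 = NULL, sigma2e = 1,
                               h2Profile = NULL,
                               residualMap = defaultResidualClasses(),
                               dapGrid = seq(basis@dapMin, basis@dapMax),
                               envReps = c("2017_A.R1", "2017_A.R2",
                                           "2018_A.R1", "2018_A.R2",
                                           "2018_R.R1", "2018_R.R2"),
                               beta = NULL, envEffects = NULL,
                               missingRate = 0, seed = 1L) {
  stopifnot(is(panel, "GenotypePanel"), is(basis, "TimeBasis"))
  nCls <- length(residualMap@from)
  sigma2e <- rep(sigma2e, length.out = nCls)
  if (is.null(G0)) {
    if (is.null(h2Profile)) stop("supply either G0 or h2Profile")
    ## the profile may be given on the full integer day grid even when
    ## observations are on a sparser dapGrid
    fullGrid <- seq(basis@dapMin, basis@dapMax)
    profGrid <- if (length(h2Profile) == length(fullGrid)) fullGrid else dapGrid
    G0 <- g0ForH2Profile(basis, h2Profile, sigma2e, residualMap, profGrid)
  }
  m <- nCoef(basis)
  stopifnot(nrow(G0) == m, ncol(G0) == m)
  eg <- eigen((G0 + t(G0)) / 2, symmetric = TRUE)
  tolPSD <- -1e-8 * max(abs(eg$values), 1)
  if (min(eg$values) < tolPSD)
    stop(sprintf("G0 is not PSD: eigenvalue %.3e < 0", min(eg$values)))
  L0 <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), m)
  G <- vanRadenGRM(panel)@G
  n <- nrow(G)
  LG <- tryCatch(t(chol(G)), error = function(e) {
    rrmMessage("G singular; using eigen square root of G + 1e-8 lift")
    egg <- eigen(liftDiag(G), symmetric = TRUE)
    egg$vectors %*% diag(sqrt(pmax(egg$values, 0)), n)
  })

  set.seed(moduleSeed(seed, "phenotypes"))
  A <- LG %*% matrix(stats::rnorm(n * m), n, m) %*% t(L0)  # var = G (x) G0
  rownames(A) <- rownames(G)
  Tm <- basisMatrix(basis, dapGrid)
  if (is.null(beta)) {
    curve <- 10 / (1 + exp(-(dapGrid - mean(dapGrid)) / 8))
    beta <- stats::lm.fit(Tm, curve)$coefficients
    beta[is.na(beta)] <- 0
  }
  if (is.null(envEffects)) {
    envEffects <- stats::rnorm(length(envReps), 0, 0.5)
  }
  names(envEffects) <- envReps

  cls <- classOfDap(residualMap, dapGrid)
  recs <- expand.grid(line = rownames(G), env_rep = envReps, dap = dapGrid,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  li <- match(recs$line, rownames(G))
  di <- match(recs$dap, dapGrid)
  gval <- rowSums(Tm[di, , drop = FALSE] * A[li, , drop = FALSE])
  fixed <- drop(Tm %*% beta)[di] + envEffects[recs$env_rep]
  e <- stats::rnorm(nrow(recs), 0, sqrt(sigma2e[cls[di]]))
  recs$value <- unname(fixed + gval + e)
  if (any(missingRate > 0)) {
    mr <- rep(missingRate, length.out = length(envReps))
    names(mr) <- envReps
    keep <- stats::runif(nrow(recs)) >= mr[recs$env_rep]
    recs <- recs[keep, , drop = FALSE]
    rownames(recs) <- NULL
  }
  sa <- rowSums((Tm %*% G0) * Tm)
  truth <- new("SyntheticTruth", G0 = G0, sigma2e = sigma2e,
               residualMap = residualMap, beta = unname(beta),
               envEffects = envEffects, coef = A, basis = basis,
               family = sub("_.*", "", rownames(G)),
               dapGrid = as.numeric(dapGrid),
               h2 = sa / (sa + sigma2e[cls]))
  list(phenotypes = recs, truth = truth)
}
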