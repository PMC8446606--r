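test_that("back-solved SNP effects match dense linear algebra on a toy", {
  ## 4 lines x 6 SNPs, frequencies external so ZZ' is nonsingular
  M <- rbind(c(0, 2, 2, 0, 2, 0), c(2, 2, 0, 0, 0, 2),
             c(0, 0, 2, 2, 2, 2), c(2, 0, 0, 2, 0, 0))
  rownames(M) <- sprintf("L%d", 1:4)
  p <- rep(0.4, 6)
  Z <- sweep(M, 2, 2 * p)
  k <- 2 * sum(p * (1 - p))
  grm <- new("GRMResult", G = tcrossprod(Z) / k, Zc = Z, pFreq = p,
             kScale = k,
             snpInfo = data.frame(snp_id = paste0("s", 1:6),
                                  chrom = rep(c("Chr01", "Chr02"), each = 3),
                                  pos = rep(c(100L, 200L, 300L), 2)))
  basis <- timeBasis("legendre", order = 1)
  set.seed(21)
  gh <- matrix(rnorm(8), 4, 2, dimnames = list(rownames(M), NULL))
  fit <- new("RRMFit", basis = basis,
             residualMap = homogeneousClasses(), G0 = diag(2),
             sigma2e = 1, beta = numeric(2), ghat = gh, logLik = 0, AIC = 0,
             nVarcompParams = 4, converged = TRUE, nIterations = 1L,
             history = data.frame())
  eff <- backsolveSnpEffects(fit, grm)
  oracle <- t(Z) %*% solve(tcrossprod(Z)) %*% gh   # u = Z'(ZZ')^-1 g
  expect_equal(unname(eff@uHat), unname(oracle), tolerance = 1e-9)
  ## projection identity on the full-rank instance
  expect_lt(max(abs(Z %*% eff@uHat - gh)), 1e-8)
  ## zero breeding values give zero effects
  fit0 <- fit; fit0@ghat <- 0 * gh
  expect_true(all(backsolveSnpEffects(fit0, grm)@uHat == 0))
  ## line-order mismatch is an error
  fitP <- fit; rownames(fitP@ghat) <- rev(rownames(gh))
  expect_error(backsolveSnpEffects(fitP, grm), "mismatch")
})

test_that("projection identity holds for a fitted panel (internal p)", {
  fx <- simFixture(nFam = 5, lpf = 5, nSnps = 120, seed = 131)
  fit <- suppressWarnings(remlEstimate(fx$ph, fx$basis, fx$grm,
                                       residualMode = "homogeneous"))
  eff <- backsolveSnpEffects(fit, fx$grm)
  ## ghat lies in col(G) = col(ZZ'), so Z u reproduces it exactly
  expect_lt(max(abs(fx$grm@Zc %*% eff@uHat - fit@ghat)), 1e-8)
})

test_that("time projection of SNP effects equals the per-SNP loop", {
  basis <- timeBasis("bspline", degree = 1, knots = c(44, 66))
  set.seed(31)
  u <- matrix(rnorm(24), 6, 4)
  eff <- new("SnpEffects", uHat = u, effectsByDap = matrix(numeric(0), 0, 0),
             snpInfo = data.frame(snp_id = paste0("s", 1:6), chrom = "Chr01",
                                  pos = 1:6 * 100L),
             dapGrid = numeric(0))
  eff <- effectsOverTime(eff, basis, seq(27, 83, by = 4))
  Tm <- basisMatrix(basis, seq(27, 83, by = 4))
  for (s in 1:6)
    expect_equal(unname(eff@effectsByDap[s, ]),
                 unname(drop(Tm %*% u[s, ])))
  ## zero coefficients give a zero trajectory
  eff0 <- effectsOverTime(new("SnpEffects", uHat = 0 * u,
                              effectsByDap = matrix(numeric(0), 0, 0),
                              snpInfo = eff@snpInfo, dapGrid = numeric(0)),
                          basis)
  expect_true(all(eff0@effectsByDap == 0))
})

test_that("top-k selection matches sort-based brute force with tie rules", {
  set.seed(41)
  nS <- 40
  si <- data.frame(snp_id = paste0("s", 1:nS),
                   chrom = sample(sprintf("Chr%02d", 1:5), nS, TRUE),
                   pos = sample.int(1e6, nS))
  eb <- matrix(rnorm(nS * 8), nS)
  eff <- new("SnpEffects", uHat = matrix(0, nS, 1), effectsByDap = eb,
             snpInfo = si, dapGrid = as.numeric(30:37))
  rownames(eff@effectsByDap) <- si$snp_id
  sel <- selectTopSnps(eff, k = 5)
  chromNum <- as.numeric(gsub("[^0-9]", "", si$chrom))
  for (j in 1:8) {
    o <- order(-abs(eb[, j]), chromNum, si$pos)[1:5]     # brute force
    expect_setequal(sel$perDap$snp_id[sel$perDap$dap == 29 + j],
                    si$snp_id[o])
  }
  expect_true(all(sel$union$nDays >= 1))

  ## exact tie at a day with k = 1: the lower (chrom, pos) SNP wins
  si2 <- data.frame(snp_id = c("a", "b"), chrom = c("Chr02", "Chr01"),
                    pos = c(10L, 500L))
  eb2 <- matrix(c(0.5, -0.5), 2, 1)
  eff2 <- new("SnpEffects", uHat = matrix(0, 2, 1), effectsByDap = eb2,
              snpInfo = si2, dapGrid = 30)
  rownames(eff2@effectsByDap) <- si2$snp_id
  expect_equal(selectTopSnps(eff2, k = 1)$perDap$snp_id, "b")

  ## one dominant SNP everywhere: union of size 1 present on all days
  eb3 <- matrix(c(rep(9, 8), rnorm(nS * 8 - 8, 0, 0.1)), nS, 8, byrow = TRUE)
  eb3[1, ] <- 9; eb3[-1, ] <- rnorm((nS - 1) * 8, 0, 0.1)
  eff3 <- eff; eff3@effectsByDap <- eb3
  sel3 <- selectTopSnps(eff3, k = 1)
  expect_equal(nrow(sel3$union), 1L)
  expect_equal(sel3$union$nDays, 8L)
})

test_that("duration classes follow the consecutive-day rules", {
  expect_equal(classifyDuration(27:60), "long")          # 34 days
  expect_equal(classifyDuration(40:47), "short")         # 8 days
  expect_equal(classifyDuration(c(30:35, 70:75)), "intermittent")
  ## boundary decisions: exactly 10 and exactly 30 consecutive days -> mid
  expect_equal(classifyDuration(41:50), "mid")
  expect_equal(classifyDuration(31:60), "mid")
  expect_equal(classifyDuration(31:61), "long")
  expect_equal(classifyDuration(42:50), "short")
  expect_equal(classifyDuration(55), "short")
  expect_error(classifyDuration(integer(0)), "empty")
  ## total and exclusive over random day sets
  set.seed(51)
  for (i in 1:50) {
    d <- sort(sample(27:83, sample(1:40, 1)))
    cls <- classifyDuration(d)
    expect_true(cls %in% c("long", "mid", "short", "intermittent"))
    runs <- split(d, cumsum(c(1, diff(d) > 1)))
    if (length(runs) > 1) expect_equal(cls, "intermittent")
  }
})

test_that("candidate windows are closed intervals matched against features", {
  ann <- GenomicRanges::GRanges(
    c("Chr01", "Chr01", "Chr02"),
    IRanges::IRanges(c(90000, 130000, 5000), c(95000, 140000, 6000)),
    Name = c("geneA", "geneB", "geneC"))
  snps <- data.frame(snp_id = c("s1", "s2", "s3"),
                     chrom = c("Chr01", "Chr01", "Chr03"),
                     pos = c(100000L, 120000L, 1000L))
  expect_warning(hits <- candidateWindows(snps, ann, 25000L), "Chr03")
  ## s1 window [75000,125000] catches geneA only; gene start exactly at
  ## pos + 25000 would still be caught (closed interval): check boundary
  expect_setequal(hits$feature[hits$snp_id == "s1"], "geneA")
  ## s2 window [95000,145000]: geneA ends exactly at the window start
  ## (closed interval, included) and geneB lies inside
  expect_setequal(hits$feature[hits$snp_id == "s2"], c("geneA", "geneB"))
  ## feature starting exactly at pos + 25000 is included (closed interval)
  bnd <- data.frame(snp_id = "b", chrom = "Chr01", pos = 105000L)
  expect_true("geneB" %in% candidateWindows(bnd, ann, 25000L)$feature)
  ## feature ending exactly at pos - 25000 is included too
  bnd2 <- data.frame(snp_id = "b2", chrom = "Chr01", pos = 120000L)
  expect_true("geneA" %in% candidateWindows(bnd2, ann, 25000L)$feature)
  ## one day beyond the closed boundary misses
  bnd3 <- data.frame(snp_id = "b3", chrom = "Chr01", pos = 120001L)
  expect_false("geneA" %in% candidateWindows(bnd3, ann, 25000L)$feature)
  ## within-gene flag
  inGene <- data.frame(snp_id = "g", chrom = "Chr01", pos = 92000L)
  h <- candidateWindows(inGene, ann, 25000L)
  expect_true(h$withinGene[h$feature == "geneA"])
})

test_that("window overlap matches a quadratic all-pairs scan", {
  set.seed(61)
  nF <- 60; nS <- 25
  chrom <- sample(c("Chr01", "Chr02"), nF, TRUE)
  st <- sample.int(5e5, nF)
  ann <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(st, st + sample.int(2e4, nF)),
                                Name = paste0("f", seq_len(nF)))
  snps <- data.frame(snp_id = paste0("s", 1:nS),
                     chrom = sample(c("Chr01", "Chr02"), nS, TRUE),
                     pos = sample.int(5e5, nS))
  hw <- 10000L
  hits <- candidateWindows(snps, ann, hw)
  got <- sort(paste(hits$snp_id, hits$feature))
  want <- character(0)
  for (i in 1:nS) for (j in 1:nF) {      # brute-force closed-interval scan
    if (snps$chrom[i] == chrom[j] &&
        max(1, snps$pos[i] - hw) <= st[j] + (GenomicRanges::width(ann)[j] - 1) &&
        snps$pos[i] + hw >= st[j])
      want <- c(want, paste(snps$snp_id[i], paste0("f", j)))
  }
  expect_identical(got, sort(want))
})

test_that("annotation files read through rtracklayer keep 1-based windows", {
  bed <- tempfile(fileext = ".bed")
  ## BED half-open zero-based: this feature is 1-based [101, 200]
  writeLines("Chr01\t100\t200\tgeneX", bed)
  ann <- readAnnotation(bed)
  expect_equal(GenomicRanges::start(ann), 101)
  expect_equal(GenomicRanges::end(ann), 200)
  snp <- data.frame(snp_id = "s", chrom = "Chr01", pos = 300L)
  expect_equal(candidateWindows(snp, ann, 100L)$feature, "geneX")
  expect_equal(nrow(candidateWindows(snp, ann, 99L)), 0L)
})
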