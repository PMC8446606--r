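#' Back-solve per-coefficient SNP effects from breeding values
#'
#' For each random regression coefficient \eqn{m},
#' \eqn{\hat u_m = D Z'(Z D Z')^{-1} \hat g_m} with the SNP weight matrix
#' \eqn{D} fixed to the identity (a weights hook exists but is off by
#' default), computed through the relationship-matrix identity
#' \eqn{Z Z' = k\,G} and a pseudo-inverse when \eqn{Z Z'} is singular.
#'
#' @param fit an [RRMFit-class].
#' @param grm the [GRMResult-class] whose centered dosages produced the fit.
#' @param weights optional per-SNP diagonal of \eqn{D}.
#' @return a [SnpEffects-class] with `uHat` filled and `effectsByDap` empty
#'   until [effectsOverTime()] is applied.
#' @export
backsolveSnpEffects <- function(fit, grm, weights = NULL) {
  stopifnot(is(fit, "RRMFit"), is(grm, "GRMResult"))
  gh <- fit@ghat
  if (!identical(rownames(gh), rownames(grm@G)))
    stop("line order mismatch between fit and GRM")
  Z <- grm@Zc
  if (is.null(weights)) {
    ## ZZ' = kScale * G exactly; pseudo-invert via the spectrum of G
    ZZtInv <- pinvSym(grm@G * grm@kScale)
    uHat <- crossprod(Z, ZZtInv %*% gh)
  } else {
    stopifnot(length(weights) == ncol(Z), all(weights >= 0))
    ZD <- sweep(Z, 2, weights, `*`)
    uHat <- weights * crossprod(Z, pinvSym(tcrossprod(ZD, Z)) %*% gh)
  }
  rownames(uHat) <- grm@snpInfo$snp_id
  colnames(uHat) <- colnames(gh)
  new("SnpEffects", uHat = uHat, effectsByDap = matrix(numeric(0), 0, 0),
      snpInfo = grm@snpInfo, dapGrid = numeric(0))
}

#' Project SNP coefficient effects onto the time grid
#'
#' Per-SNP effect trajectory \eqn{\widehat{SNP}_s = T \hat u_s}.
#'
#' @param effects a [SnpEffects-class] from [backsolveSnpEffects()].
#' @param basis the [TimeBasis-class] of the fit.
#' @param dapGrid evaluation days (default all integer DAP in range).
#' @return `effects` with `effectsByDap` (SNPs x DAP) and `dapGrid` filled.
#' @export
effectsOverTime <- function(effects, basis, dapGrid = NULL) {
  stopifnot(is(effects, "SnpEffects"), is(basis, "TimeBasis"))
  if (is.null(dapGrid)) dapGrid <- seq(basis@dapMin, basis@dapMax)
  Tm <- basisMatrix(basis, dapGrid)
  if (ncol(Tm) != ncol(effects@uHat)) stop("basis/coefficient mismatch")
  eb <- effects@uHat %*% t(Tm)
  colnames(eb) <- as.character(dapGrid)
  effects@effectsByDap <- eb
  effects@dapGrid <- as.numeric(dapGrid)
  effects
}

#' Select the top-k SNPs by effect magnitude per day
#'
#' Per DAP, the `k` SNPs with the largest absolute effect; ties are broken
#' deterministically by (smaller chromosome, smaller position). The union
#' across days is reported with each SNP's presence-day set.
#'
#' @param effects a [SnpEffects-class] with `effectsByDap` filled.
#' @param k SNPs kept per day.
#' @return list with `perDap` (data.frame dap, rank, snp_id, effect) and
#'   `union` (data.frame snp_id, chrom, pos, nDays, days as a
#'   comma-collapsed string, firstDap, lastDap).
#' @export
selectTopSnps <- function(effects, k = 10L) {
  stopifnot(is(effects, "SnpEffects"), k >= 1)
  eb <- effects@effectsByDap
  if (!length(eb)) stop("run effectsOverTime() first")
  si <- effects@snpInfo
  chromNum <- suppressWarnings(as.numeric(gsub("[^0-9]", "", si$chrom)))
  chromKey <- if (anyNA(chromNum)) rank(si$chrom, ties.method = "min")
              else chromNum
  k <- min(k, nrow(eb))
  perDap <- vector("list", ncol(eb))
  for (j in seq_len(ncol(eb))) {
    o <- order(-abs(eb[, j]), chromKey, si$pos)[seq_len(k)]
    perDap[[j]] <- data.frame(dap = effects@dapGrid[j], rank = seq_len(k),
                              snp_id = si$snp_id[o], effect = eb[o, j],
                              stringsAsFactors = FALSE)
  }
  perDap <- do.call(rbind, perDap)
  days <- split(perDap$dap, perDap$snp_id)
  ids <- names(days)
  ix <- match(ids, si$snp_id)
  un <- data.frame(snp_id = ids, chrom = si$chrom[ix], pos = si$pos[ix],
                   nDays = lengths(days),
                   days = vapply(days, function(d)
                     paste(sort(d), collapse = ","), ""),
                   firstDap = vapply(days, min, 0),
                   lastDap = vapply(days, max, 0),
                   stringsAsFactors = FALSE)
  un <- un[order(suppressWarnings(chromKey[ix]), un$pos), , drop = FALSE]
  rownames(un) <- NULL
  list(perDap = perDap, union = un)
}

#' Classify the duration of a SNP's presence in the top set
#'
#' Maximal runs of consecutive days are computed from the presence-day set:
#' more than one run is `"intermittent"`; a single run of more than 30
#' consecutive days is `"long"`, of less than 10 days `"short"`, and
#' anything from 10 to 30 days (boundaries included; the printed rules
#' leave exactly 10 and exactly 30 undefined, both are assigned here)
#' `"mid"`.
#'
#' @param presenceDays integer vector of days on which the SNP was in the
#'   top set (any order, non-empty).
#' @return one of `"long"`, `"mid"`, `"short"`, `"intermittent"`.
#' @examples
#' classifyDuration(27:60)               # 34 consecutive days: long
#' classifyDuration(40:47)               # 8 days: short
#' classifyDuration(c(30:35, 70:75))     # two runs: intermittent
#' @export
classifyDuration <- function(presenceDays) {
  d <- sort(unique(as.integer(presenceDays)))
  if (!length(d)) stop("empty presence-day set")
  runs <- cumsum(c(1L, diff(d) > 1L))
  if (max(runs) > 1L) return("intermittent")
  len <- length(d)
  if (len > 30) "long" else if (len < 10) "short" else "mid"
}

#' Candidate-window queries against annotation intervals
#'
#' For each selected SNP, reports annotation features overlapping the
#' closed 1-based window `[pos - halfWidth, pos + halfWidth]` (clamped at
#' 1), and flags SNPs lying inside a feature. Chromosomes absent from the
#' annotation produce a per-SNP warning and no hits.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (e.g. the `union`
#'   table of [selectTopSnps()]).
#' @param annotation a `GRanges` of features (see [readAnnotation()]).
#' @param halfWidth window half-width in bp.
#' @return data.frame: snp_id, chrom, pos, feature, featureStart,
#'   featureEnd, withinGene. SNPs with no candidates are absent.
#' @export
candidateWindows <- function(snps, annotation, halfWidth = 25000L) {
  stopifnot(is(annotation, "GRanges"),
            all(c("snp_id", "chrom", "pos") %in% names(snps)))
  missing <- setdiff(unique(snps$chrom),
                     GenomeInfoDb::seqlevels(annotation))
  if (length(missing))
    warning("chromosome(s) absent from annotation: ",
            paste(missing, collapse = ", "), call. = FALSE)
  keep <- snps$chrom %in% GenomeInfoDb::seqlevels(annotation)
  if (!any(keep)) return(emptyWindowHits())
  sn <- snps[keep, , drop = FALSE]
  win <- GenomicRanges::GRanges(
    sn$chrom,
    IRanges::IRanges(pmax(1L, sn$pos - halfWidth), sn$pos + halfWidth))
  ov <- GenomicRanges::findOverlaps(win, annotation)
  if (!length(ov)) return(emptyWindowHits())
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  feat <- annotation[si]
  fname <- featureLabel(feat)
  data.frame(
    snp_id = sn$snp_id[qi], chrom = sn$chrom[qi], pos = sn$pos[qi],
    feature = fname,
    featureStart = GenomicRanges::start(feat),
    featureEnd = GenomicRanges::end(feat),
    withinGene = sn$pos[qi] >= GenomicRanges::start(feat) &
      sn$pos[qi] <= GenomicRanges::end(feat),
    stringsAsFactors = FALSE)
}

emptyWindowHits <- function() {
  data.frame(snp_id = character(0), chrom = character(0), pos = integer(0),
             feature = character(0), featureStart = integer(0),
             featureEnd = integer(0), withinGene = logical(0),
             stringsAsFactors = FALSE)
}

featureLabel <- function(gr) {
  md <- S4Vectors::mcols(gr)
  for (f in c("Name", "name", "ID", "gene_id", "id"))
    if (f %in% names(md)) {
      v <- as.character(md[[f]])
      if (!all(is.na(v))) return(v)
    }
  paste0("feature_", seq_along(gr))
}
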