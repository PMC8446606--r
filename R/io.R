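#' Read a genotype panel from TSV matrix or VCF
#'
#' The TSV matrix layout is one row per SNP with columns `snp_id`, `chrom`,
#' `pos`, then one column of 0/1/2/NA dosages per line. VCF input keeps
#' biallelic records only (multi-allelic rows are skipped with a logged
#' count); the dosage is the count of ALT alleles, phase is ignored, and
#' half-missing genotypes are treated as missing.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`; guessed from the extension by default.
#' @return a [GenotypePanel-class], SNPs in file order.
#' @export
readGenotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") readGenotypesVcf(path) else readGenotypesTsv(path)
}

readGenotypesTsv <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = NA),
    error = function(e) stop("malformed genotype TSV '", path, "': ",
                             conditionMessage(e)))
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(df)[1:3]))
    stop("malformed header at line 1: first columns must be snp_id, chrom, pos")
  if (!nrow(df)) stop("zero SNPs in ", path)
  lines <- names(df)[-(1:3)]
  if (!length(lines)) stop("no line columns in ", path)
  M <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  storage.mode(M) <- "double"
  rownames(M) <- lines
  colnames(M) <- as.character(df$snp_id)
  newGenotypePanel(M, data.frame(snp_id = as.character(df$snp_id),
                                 chrom = as.character(df$chrom),
                                 pos = as.integer(df$pos),
                                 stringsAsFactors = FALSE))
}

readGenotypesVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi))
    rrmMessage("skipped %d non-biallelic VCF record(s)", sum(multi))
  if (all(multi)) stop("zero biallelic SNPs in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  ## ALT-allele count; any missing allele ('.') makes the genotype missing
  alleles <- gsub("\\|", "/", gt)
  dose <- matrix(NA_real_, nrow(gt), ncol(gt))
  a1 <- sub("/.*", "", alleles)
  a2 <- sub(".*/", "", alleles)
  ok <- !is.na(alleles) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dose[ok] <- as.numeric(a1[ok]) + as.numeric(a2[ok])
  M <- t(dose)
  rownames(M) <- colnames(gt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  colnames(M) <- ids
  newGenotypePanel(M, data.frame(snp_id = ids, chrom = as.character(fix[, "CHROM"]),
                                 pos = as.integer(fix[, "POS"]),
                                 stringsAsFactors = FALSE))
}

newGenotypePanel <- function(M, info, imputed = FALSE) {
  rownames(info) <- NULL
  new("GenotypePanel", dosages = M, snpInfo = info, imputed = imputed)
}

#' Write a genotype panel as a TSV matrix
#'
#' Inverse of [readGenotypes()] for the TSV layout; round-trips dosages
#' exactly.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(panel, path) {
  stopifnot(is(panel, "GenotypePanel"))
  df <- cbind(panel@snpInfo,
              as.data.frame(t(panel@dosages), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' CSV with header columns `line`, `env_rep`, `dap`, `value`. Duplicate
#' `(line, env_rep, dap)` keys are an error; rows with `dap` outside
#' `dapRange` are dropped with a logged count.
#'
#' @param path CSV file path.
#' @param dapRange length-2 numeric, the modeled DAP window (default the
#'   27--83 day biomass window).
#' @return a data.frame with columns `line`, `env_rep`, `dap`, `value`.
#' @export
readPhenotypes <- function(path, dapRange = c(27, 83)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "env_rep", "dap", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  bad <- which(!is.na(df$value) & is.na(suppressWarnings(as.numeric(df$value))))
  if (length(bad)) stop("non-numeric phenotype value at data row ", bad[1],
                        " (file line ", bad[1] + 1L, ")")
  df$value <- as.numeric(df$value)
  df$dap <- as.numeric(df$dap)
  validatePhenotypes(df[, need], dapRange)
}

validatePhenotypes <- function(df, dapRange = c(27, 83)) {
  out <- df$dap < dapRange[1] | df$dap > dapRange[2]
  if (any(out)) {
    rrmMessage("dropped %d phenotype row(s) with DAP outside [%g, %g]",
               sum(out), dapRange[1], dapRange[2])
    df <- df[!out, , drop = FALSE]
  }
  key <- paste(df$line, df$env_rep, df$dap, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (line, env_rep, dap) key: ", key[duplicated(key)][1])
  rownames(df) <- NULL
  df
}

#' Read annotation intervals (BED or GFF3)
#'
#' Thin wrapper over `rtracklayer::import()`; BED coordinates are converted
#' to the 1-based closed convention of `GRanges`.
#'
#' @param path BED or GFF3 file path.
#' @return a `GRanges` of features.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rtracklayer::import(path)
}

#' Pipeline run configuration
#'
#' Bundles the knobs of a full run: basis specification, residual mode and
#' class map, DAP range, QC thresholds, cross-validation folds, GWAS top-k,
#' candidate window half-width, and the master seed.
#'
#' @param basis a [TimeBasis-class] (default: linear B-spline with knots at
#'   44 and 66 DAP, the model preferred for the soybean biomass data).
#' @param residualMode `"heterogeneous"` or `"homogeneous"`.
#' @param residualMap a [ResidualClassMap-class]; default the shipped map.
#' @param dapRange modeled DAP window.
#' @param mafMin,callRateMin genotype QC thresholds.
#' @param cvFolds number of cross-validation folds.
#' @param topK SNPs kept per DAP in the GWAS ranking.
#' @param windowHalfWidth candidate-window half-width in bp.
#' @param seed master run seed (all module seeds derive from it).
#' @return a validated `RunConfig` list (class `"RunConfig"`).
#' @export
rrmConfig <- function(basis = timeBasis("bspline", degree = 1,
                                        knots = c(44, 66),
                                        dapMin = 27, dapMax = 83),
                      residualMode = c("heterogeneous", "homogeneous"),
                      residualMap = defaultResidualClasses(),
                      dapRange = c(basis@dapMin, basis@dapMax),
                      mafMin = 0.05, callRateMin = 0.90,
                      cvFolds = 5L, topK = 10L,
                      windowHalfWidth = 25000L, seed = 1L) {
  residualMode <- match.arg(residualMode)
  stopifnot(is(basis, "TimeBasis"), is(residualMap, "ResidualClassMap"))
  validObject(basis); validObject(residualMap)
  if (topK < 1) stop("topK must be >= 1")
  if (cvFolds < 2) stop("cvFolds must be >= 2")
  if (!identical(as.numeric(dapRange), c(basis@dapMin, basis@dapMax)))
    stop("dapRange must match the basis range")
  if (residualMap@from[1] != dapRange[1] ||
      residualMap@to[length(residualMap@to)] != dapRange[2])
    stop("residual classes must partition the dap range")
  structure(list(basis = basis, residualMode = residualMode,
                 residualMap = residualMap, dapRange = as.numeric(dapRange),
                 mafMin = mafMin, callRateMin = callRateMin,
                 cvFolds = as.integer(cvFolds), topK = as.integer(topK),
                 windowHalfWidth = as.integer(windowHalfWidth),
                 seed = as.integer(seed)),
            class = "RunConfig")
}
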