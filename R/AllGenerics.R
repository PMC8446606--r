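#' @include AllClasses.R
NULL

#' Accessors for GenomicRRM objects
#'
#' Small accessor generics: `dosages()` returns the lines x SNPs dosage
#' matrix, `lineIds()` the line identifiers, `snpInfo()` the per-SNP
#' `snp_id`/`chrom`/`pos` table, `grmMatrix()` the genomic relationship
#' matrix, `nCoef()` the number of regression coefficients of a basis,
#' `dapRange()` the modeled DAP range, and `coefBlup()` the per-line
#' coefficient BLUPs of a fit.
#'
#' @param x an object of the documented classes.
#' @return the corresponding slot content (see Description).
#' @name accessors
#' @aliases dosages lineIds snpInfo grmMatrix nCoef dapRange coefBlup
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))
#' @rdname accessors
#' @export
setGeneric("nCoef", function(x) standardGeneric("nCoef"))
#' @rdname accessors
#' @export
setGeneric("dapRange", function(x) standardGeneric("dapRange"))
#' @rdname accessors
#' @export
setGeneric("coefBlup", function(x) standardGeneric("coefBlup"))

#' @rdname accessors
setMethod("dosages", "GenotypePanel", function(x) x@dosages)
#' @rdname accessors
setMethod("lineIds", "GenotypePanel", function(x) rownames(x@dosages))
#' @rdname accessors
setMethod("snpInfo", "GenotypePanel", function(x) x@snpInfo)
#' @rdname accessors
setMethod("lineIds", "GRMResult", function(x) rownames(x@G))
#' @rdname accessors
setMethod("snpInfo", "GRMResult", function(x) x@snpInfo)
#' @rdname accessors
setMethod("grmMatrix", "GRMResult", function(x) x@G)
#' @rdname accessors
setMethod("nCoef", "TimeBasis", function(x) {
  if (x@kind == "legendre") x@order + 1L else length(x@knots) + x@degree + 1L
})
#' @rdname accessors
setMethod("dapRange", "TimeBasis", function(x) c(x@dapMin, x@dapMax))
#' @rdname accessors
setMethod("coefBlup", "RRMFit", function(x) x@ghat)
#' @rdname accessors
setMethod("lineIds", "RRMFit", function(x) rownames(x@ghat))
#' @rdname accessors
setMethod("snpInfo", "SnpEffects", function(x) x@snpInfo)

setMethod("show", "TimeBasis", function(object) {
  if (object@kind == "legendre")
    cat(sprintf("TimeBasis: Legendre order %d (%d coefficients) on [%g, %g]\n",
                object@order, nCoef(object), object@dapMin, object@dapMax))
  else
    cat(sprintf(
      "TimeBasis: B-spline degree %d, interior knots {%s} (%d coefficients) on [%g, %g]\n",
      object@degree, paste(object@knots, collapse = ", "), nCoef(object),
      object@dapMin, object@dapMax))
})

setMethod("show", "GenotypePanel", function(object) {
  d <- object@dosages
  cat(sprintf("GenotypePanel: %d lines x %d SNPs (%d chromosomes)%s\n",
              nrow(d), ncol(d), length(unique(object@snpInfo$chrom)),
              if (object@imputed) ", imputed" else ""))
  nm <- sum(is.na(d))
  if (nm) cat(sprintf("  missing dosages: %d (%.2f%%)\n", nm, 100 * nm / length(d)))
})

setMethod("show", "GRMResult", function(object) {
  cat(sprintf("GRMResult: %d lines, %d SNPs, mean diag(G) = %.3f\n",
              nrow(object@G), length(object@pFreq), mean(diag(object@G))))
})

setMethod("show", "ResidualClassMap", function(object) {
  cat(sprintf("ResidualClassMap: %d classes on [%d, %d]\n",
              length(object@from), object@from[1], object@to[length(object@to)]))
  cat(" ", paste(sprintf("%d-%d", object@from, object@to), collapse = ", "), "\n")
})

setMethod("show", "RRMFit", function(object) {
  cat(sprintf("RRMFit: m = %d, %d residual class(es), %s in %d iterations\n",
              nrow(object@G0), length(object@sigma2e),
              if (object@converged) "converged" else "NOT converged",
              object@nIterations))
  cat(sprintf("  logL(REML) = %.4f, AIC = %.4f (%d varcomp parameters)\n",
              object@logLik, object@AIC, as.integer(object@nVarcompParams)))
})

setMethod("show", "GeneticParams", function(object) {
  cat(sprintf("GeneticParams on %d DAP (%g..%g)\n", length(object@dapGrid),
              min(object@dapGrid), max(object@dapGrid)))
  if (!all(is.na(object@h2)))
    cat(sprintf("  h2 range: %.3f .. %.3f\n", min(object@h2), max(object@h2)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d folds, %d DAP\n", max(object@folds),
              length(object@dapGrid)))
  cat(sprintf("  mean accuracy r = %.3f, mean bias b1 = %.3f\n",
              mean(object@accuracy), mean(object@bias)))
})

setMethod("show", "SnpEffects", function(object) {
  cat(sprintf("SnpEffects: %d SNPs x %d coefficients, projected on %d DAP\n",
              nrow(object@uHat), ncol(object@uHat), length(object@dapGrid)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d lines, m = %d, %d residual class(es)\n",
              nrow(object@coef), nrow(object@G0), length(object@sigma2e)))
  cat(sprintf("  realized h2 range: %.3f .. %.3f\n", min(object@h2), max(object@h2)))
})
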