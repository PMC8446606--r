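#' Residual-variance class maps
#'
#' `residualClassMap()` builds a map from closed interval bounds;
#' `defaultResidualClasses()` returns the shipped 19-interval map for the
#' 27--83 DAP biomass grid (one class per phenotyped DAP neighbourhood);
#' `homogeneousClasses()` is the single-class map; `classOfDap()` maps days
#' to class indices.
#'
#' @param from,to integer vectors of closed interval bounds; consecutive
#'   intervals must tile the range with no gaps.
#' @return `residualClassMap()`: a [ResidualClassMap-class].
#' @export
residualClassMap <- function(from, to) {
  new("ResidualClassMap", from = as.integer(from), to = as.integer(to))
}

#' @rdname residualClassMap
#' @export
defaultResidualClasses <- function() {
  residualClassMap(
    from = c(27, 34, 37, 38, 42, 44, 46, 47, 50, 54, 59, 62, 63, 66, 72, 75, 77, 81, 83),
    to   = c(33, 36, 37, 41, 43, 45, 46, 49, 53, 58, 61, 62, 65, 71, 74, 76, 80, 82, 83))
}

#' @rdname residualClassMap
#' @param dapRange length-2 range for the single class.
#' @export
homogeneousClasses <- function(dapRange = c(27, 83)) {
  residualClassMap(dapRange[1], dapRange[2])
}

#' @rdname residualClassMap
#' @param map a [ResidualClassMap-class].
#' @param dap numeric vector of days.
#' @return `classOfDap()`: integer class index per day.
#' @export
classOfDap <- function(map, dap) {
  stopifnot(is(map, "ResidualClassMap"))
  idx <- findInterval(dap, c(map@from, map@to[length(map@to)] + 1L))
  if (any(idx < 1L | idx > length(map@from)))
    stop("dap outside the residual class range")
  idx
}

## Merge classes with fewer than minRecords records into their right
## neighbour (last class merges leftward). Returns the merged map and the
## class index of each record.
mergeSparseClasses <- function(map, recordDap, minRecords = 2L) {
  from <- map@from; to <- map@to
  repeat {
    idx <- classOfDap(residualClassMap(from, to), recordDap)
    counts <- tabulate(idx, nbins = length(from))
    low <- which(counts < minRecords)
    if (!length(low) || length(from) == 1L) break
    j <- low[1]
    if (j < length(from)) {       # merge rightward
      to[j] <- to[j + 1]; from <- from[-(j + 1)]; to <- to[-(j + 1)]
    } else {                      # last class merges leftward
      to[j - 1] <- to[j]
      from <- from[-j]; to <- to[-j]
    }
    warning(sprintf("residual class %d had < %d records; merged", j, minRecords),
            call. = FALSE)
  }
  merged <- residualClassMap(from, to)
  list(map = merged, classIdx = classOfDap(merged, recordDap))
}
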