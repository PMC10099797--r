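#' @name accessors
#' @title Accessors for protocol and map objects
#' @description Small accessor generics: \code{trList} (TR values, ms),
#'   \code{averages} (per-TR averages), \code{echoTimes} (TE grid, ms),
#'   \code{matrixSize} (image matrix), \code{nominalFlip} (degrees),
#'   \code{signalArray} (the raw 5-D array), \code{qcFlags} (QC flag array),
#'   \code{labelMap} (phantom tissue labels).
#' @param x the object
#' @return the corresponding slot or derived quantity
NULL

#' @rdname accessors
#' @export
setGeneric("trList", function(x) standardGeneric("trList"))

#' @rdname accessors
#' @export
setGeneric("averages", function(x) standardGeneric("averages"))

#' @rdname accessors
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' @rdname accessors
#' @export
setGeneric("matrixSize", function(x) standardGeneric("matrixSize"))

#' @rdname accessors
#' @export
setGeneric("nominalFlip", function(x) standardGeneric("nominalFlip"))

#' @rdname accessors
#' @export
setGeneric("signalArray", function(x) standardGeneric("signalArray"))

#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' Convert relaxation rates to times
#'
#' Rates are stored in 1/s throughout the package; relaxation times are
#' reported in ms. \code{ratesToTimes} converts \code{R} (1/s) to
#' \code{T = 1000/R} (ms) and \code{timesToRates} is its exact inverse.
#' For \linkS4class{QuantMaps} the method returns a named list of T1 and
#' T2* arrays in ms (flagged voxels stay \code{NA}).
#'
#' @param x a positive numeric vector/array of rates (1/s), or a
#'   \linkS4class{QuantMaps} object
#' @return times in ms (numeric), or for \code{QuantMaps} a list with
#'   elements \code{T1} and \code{T2star} in ms
#' @examples
#' ratesToTimes(1000 / 510)   # 510 ms
#' timesToRates(ratesToTimes(3.2)) # round-trips exactly
#' @export
setGeneric("ratesToTimes", function(x) standardGeneric("ratesToTimes"))

#' @rdname ratesToTimes
#' @export
setGeneric("timesToRates", function(x) standardGeneric("timesToRates"))
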