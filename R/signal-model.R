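#' Spoiled gradient-echo (MEGE) forward signal model
#'
#' Closed-form steady-state signal of a spoiled gradient-echo acquisition,
#'
#' \deqn{S = A \sin\alpha \frac{1 - e^{-R_1 TR}}{1 - \cos\alpha\, e^{-R_1 TR}}
#'       e^{-R_2^* TE}}
#'
#' with flip angle \eqn{\alpha} in degrees (converted internally), rates in
#' 1/s and times in ms. \code{TR} and \code{TE} may be scalars or vectors;
#' when both are vectors the result is the outer grid of dimension
#' \code{length(TR) x length(TE)} — the same code path serves voxel-wise
#' and protocol-grid evaluation.
#'
#' @param A signal amplitude, arbitrary units, >= 0
#' @param flip flip angle in degrees, in [0, 180]
#' @param R1 longitudinal relaxation rate, 1/s, > 0
#' @param R2star effective transverse relaxation rate, 1/s, > 0
#' @param TR repetition time(s), ms, > 0
#' @param TE echo time(s), ms, >= 0
#' @return signal value(s); a scalar, a vector (one of TR/TE vector), or a
#'   \code{length(TR) x length(TE)} matrix
#' @examples
#' spgrSignal(A = 100, flip = 33, R1 = 1000 / 290, R2star = 1000 / 30,
#'            TR = 62, TE = 8.9)  # 24.14
#' @seealso \code{\link{satrecSignal}}, \code{\link{ernstAngle}}
#' @export
spgrSignal <- function(A, flip, R1, R2star, TR, TE) {
    .check_signal_params(A, flip, R1, TR, R2star = R2star, TE = TE)
    a <- flip * pi / 180
    E <- exp(-R1 * TR / 1000)
    sat <- A * sin(a) * (1 - E) / (1 - cos(a) * E)
    dec <- exp(-R2star * TE / 1000)
    if (length(TR) > 1L && length(TE) > 1L)
        outer(sat, dec)
    else
        sat * dec
}

#' Saturation-recovery signal (TE-summed MEGE model)
#'
#' The TE-independent factor of the spoiled gradient-echo signal,
#' \eqn{A' \sin\alpha (1-E) / (1 - \cos\alpha E)} with
#' \eqn{E = e^{-R_1 TR}}. This is the model fitted voxel-wise to
#' echo-summed data as a function of TR: the amplitude \code{A} absorbs
#' the (TR-independent) summed TE decay.
#'
#' @inheritParams spgrSignal
#' @param A effective amplitude (absorbs summed echo decay)
#' @return signal value(s), vectorised over \code{TR}
#' @export
satrecSignal <- function(A, flip, R1, TR) {
    .check_signal_params(A, flip, R1, TR)
    a <- flip * pi / 180
    E <- exp(-R1 * TR / 1000)
    A * sin(a) * (1 - E) / (1 - cos(a) * E)
}

#' Ernst angle
#'
#' The flip angle maximising the spoiled gradient-echo signal at fixed TR
#' and T1: \eqn{\alpha_E = \arccos(e^{-R_1 TR})}, returned in degrees.
#'
#' @param R1 longitudinal relaxation rate, 1/s, > 0
#' @param TR repetition time, ms, > 0
#' @return Ernst angle in degrees
#' @examples
#' ernstAngle(R1 = 1000 / 290, TR = 62)  # 36.15 deg
#' @export
ernstAngle <- function(R1, TR) {
    if (any(R1 <= 0) || any(TR <= 0))
        stop("R1 and TR must be positive")
    acos(exp(-R1 * TR / 1000)) * 180 / pi
}

setMethod("ratesToTimes", "numeric", function(x) {
    if (any(x <= 0, na.rm = TRUE))
        stop("rates must be positive")
    1000 / x
})

setMethod("timesToRates", "numeric", function(x) {
    if (any(x <= 0, na.rm = TRUE))
        stop("times must be positive")
    1000 / x
})

setMethod("ratesToTimes", "QuantMaps", function(x) {
    t1 <- x@R1
    t2 <- x@R2star
    ok1 <- !is.na(t1)
    ok2 <- !is.na(t2)
    if (any(t1[ok1] <= 0) || any(t2[ok2] <= 0))
        stop("rates must be positive at fitted voxels")
    t1[ok1] <- 1000 / t1[ok1]
    t2[ok2] <- 1000 / t2[ok2]
    list(T1 = t1, T2star = t2)
})

.check_signal_params <- function(A, flip, R1, TR, R2star = NULL, TE = NULL) {
    if (any(A < 0)) stop("amplitude must be >= 0")
    if (any(flip < 0 | flip > 180)) stop("flip angle must lie in [0, 180] degrees")
    if (any(R1 <= 0)) stop("R1 must be positive")
    if (any(TR <= 0)) stop("TR must be positive")
    if (!is.null(R2star) && any(R2star <= 0)) stop("R2star must be positive")
    if (!is.null(TE) && any(TE < 0)) stop("TE must be >= 0")
    invisible(TRUE)
}
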