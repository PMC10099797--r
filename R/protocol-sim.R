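#' Monte-Carlo precision of T1 estimation under a sampling scheme
#'
#' Repeatedly synthesizes a single voxel's noiseless TR/TE signal grid
#' for the given tissue, adds noise with SD \code{sigma / sqrt(averages)}
#' per TR, and re-runs the fitting chain. With
#' \code{estimator = "two_stage"} (default) each repetition mimics the
#' analysis pipeline: the flip angle is co-estimated from the TE-summed
#' saturation-recovery series and then held fixed in the dual R1/R2*
#' fit — this is the regime where extending the TR range pays off most,
#' because the long-TR point anchors the flip-angle/R1 degeneracy. With
#' \code{estimator = "fixed_alpha"} the true flip angle is supplied
#' (isolates the dual fit alone). Only cleanly converged repetitions
#' (QC flag 0) enter the reported SD and bias. The single-average noise
#' SD is referenced to GM signal: \code{sigma} is chosen so that the
#' echo/TR-summed GM-referenced signal has the requested SNR.
#'
#' @param tissue named numeric: \code{amplitude}, \code{flip} (deg),
#'   \code{T1} (ms), \code{T2star} (ms)
#' @param scheme a \linkS4class{MEGEProtocol} with >= 2 TRs
#' @param snr target SNR of the echo/TR-summed GM-referenced image
#' @param nReps Monte-Carlo repetitions (>= 50)
#' @param seed integer seed
#' @param noiseModel "gaussian" (default: matches the SSE fitting
#'   assumption) or "rician"
#' @param estimator "two_stage" or "fixed_alpha"
#' @param refTissue tissue the noise level is referenced to (default GM
#'   parameters from \code{\link{defaultTissueParams}})
#' @return a \linkS4class{SchemeReport}
#' @export
simulateT1Precision <- function(tissue, scheme, snr, nReps = 500L,
                                seed = 1L, noiseModel = "gaussian",
                                estimator = c("two_stage", "fixed_alpha"),
                                refTissue = NULL) {
    estimator <- match.arg(estimator)
    if (snr <= 0) stop("snr must be positive")
    if (length(trList(scheme)) < 2L)
        stop("T1 precision needs a scheme with >= 2 TR values")
    nReps <- as.integer(nReps)
    sigma <- .sigma_for_scheme(scheme, snr, refTissue)
    est <- .with_seed(seed, function() {
        .t1_mc(tissue, scheme, sigma, nReps, noiseModel, estimator)
    })
    new("SchemeReport", scheme = scheme,
        tissue = .tissue_vec(tissue), nReps = nReps,
        t1Sd = stats::sd(est[, 1]), t2starSd = stats::sd(est[, 2]),
        t1Bias = mean(est[, 1]) - tissue[["T1"]],
        t1Estimates = est[, 1], seed = as.integer(seed))
}

.tissue_vec <- function(tissue) {
    c(amplitude = tissue[["amplitude"]], flip = tissue[["flip"]],
      T1 = tissue[["T1"]], T2star = tissue[["T2star"]])
}

#' Tissue parameter sets for precision simulation
#'
#' Convenience constructor of the named tissue vector used by
#' \code{\link{simulateT1Precision}}, defaulting to the reference tissue
#' means and the relaxometry protocol's 60 degree flip.
#'
#' @param tissue "CSF", "GM" or "WM"
#' @param flip flip angle in degrees
#' @return named numeric vector (amplitude, flip, T1, T2star)
#' @export
tissueSignalParams <- function(tissue = c("CSF", "GM", "WM"), flip = 60) {
    tissue <- match.arg(tissue)
    tp <- defaultTissueParams()[tissue, ]
    c(amplitude = tp$amplitude, flip = flip, T1 = tp$t1_mean,
      T2star = tp$t2star_mean)
}

# Single-average noise sigma giving the echo/TR-summed reference-tissue
# signal the requested SNR (Gaussian background convention).
.sigma_for_scheme <- function(scheme, snr, refTissue = NULL) {
    if (any(averages(scheme) < 1))
        stop("simulation requires at least one average per TR")
    if (is.null(refTissue))
        refTissue <- tissueSignalParams("GM", flip = nominalFlip(scheme))
    s <- spgrSignal(refTissue[["amplitude"]], refTissue[["flip"]],
                    1000 / refTissue[["T1"]], 1000 / refTissue[["T2star"]],
                    TR = trList(scheme), TE = echoTimes(scheme))
    summed <- sum(s)
    k <- sum(scheme@nEchoes / averages(scheme))
    summed / (snr * sqrt(k))
}

# one repetition's estimate from a noisy nTE x nTR grid
.mc_estimate <- function(y, trs, tes, tissue, estimator, w) {
    if (estimator == "two_stage") {
        s1 <- .fit_satrec_voxel(colSums(y), trs, tissue[["flip"]],
                                weights = w)
        if (!s1$flag %in% c(0L, 2L)) return(NULL)
        fit <- .fit_relax_voxel(as.vector(y), trs, tes, s1$flip, s1$R1)
    } else {
        fit <- .fit_relax_voxel(as.vector(y), trs, tes, tissue[["flip"]],
                                1000 / tissue[["T1"]])
    }
    if (fit$flag != 0L) return(NULL)
    c(1000 / fit$R1, 1000 / fit$R2star)
}

# core Monte-Carlo loop; uses the ambient RNG stream
.t1_mc <- function(tissue, scheme, sigma, nReps, noiseModel, estimator) {
    trs <- trList(scheme)
    tes <- echoTimes(scheme)
    avg <- averages(scheme)
    w <- sqrt(avg)
    clean <- t(spgrSignal(tissue[["amplitude"]], tissue[["flip"]],
                          1000 / tissue[["T1"]], 1000 / tissue[["T2star"]],
                          TR = trs, TE = tes))   # nTE x nTR
    sds <- matrix(sigma / sqrt(rep(avg, each = length(tes))),
                  nrow = length(tes))
    est <- matrix(NA_real_, nReps, 2)
    for (r in seq_len(nReps)) {
        noise <- matrix(stats::rnorm(length(clean), 0, sds),
                        nrow = length(tes))
        y <- if (noiseModel == "rician") {
            im <- matrix(stats::rnorm(length(clean), 0, sds),
                         nrow = length(tes))
            sqrt((clean + noise)^2 + im^2)
        } else clean + noise
        e <- .mc_estimate(y, trs, tes, tissue, estimator, w)
        if (!is.null(e)) est[r, ] <- e
    }
    est[stats::complete.cases(est), , drop = FALSE]
}

setMethod("show", "SchemeReport", function(object) {
    cat(sprintf(paste0("SchemeReport: T1 = %g ms tissue, %d TRs, ",
                       "%d reps\n  T1 SD = %.1f ms, bias = %.1f ms; ",
                       "T2* SD = %.2f ms (seed %d)\n"),
                object@tissue[["T1"]], length(trList(object@scheme)),
                object@nReps, object@t1Sd, object@t1Bias,
                object@t2starSd, object@seed))
})

#' Compare the T1 precision of two sampling schemes
#'
#' Ratio of fitted-T1 SDs (extended / base) from paired Monte-Carlo runs
#' at a common noise level, optionally with common random numbers: the
#' noise draws of each repetition are generated for the extended scheme's
#' TR set and the base scheme re-uses the draws of its own TRs, so the
#' two estimates are positively correlated and the ratio is less noisy.
#' A ratio of ~0.5 means the extension halves the T1 SD.
#'
#' @param tissue as in \code{\link{simulateT1Precision}}
#' @param baseScheme,extendedScheme \linkS4class{MEGEProtocol}s sharing
#'   the echo structure; the base TRs must be a subset of the extended
#'   TRs for common random numbers
#' @param snr,nReps,seed,noiseModel,estimator as in
#'   \code{\link{simulateT1Precision}}
#' @param commonNoise use common random numbers (default TRUE)
#' @return list with elements \code{ratio} (extended/base T1 SD),
#'   \code{base} and \code{extended} (\linkS4class{SchemeReport}s)
#' @export
compareSchemes <- function(tissue, baseScheme, extendedScheme, snr,
                           nReps = 500L, seed = 1L,
                           noiseModel = "gaussian",
                           estimator = c("two_stage", "fixed_alpha"),
                           commonNoise = TRUE) {
    estimator <- match.arg(estimator)
    if (baseScheme@te1 != extendedScheme@te1 ||
        baseScheme@deltaTE != extendedScheme@deltaTE ||
        baseScheme@nEchoes != extendedScheme@nEchoes)
        stop("schemes must share the echo structure")
    sigma <- .sigma_for_scheme(baseScheme, snr)
    nReps <- as.integer(nReps)
    if (commonNoise) {
        if (!all(trList(baseScheme) %in% trList(extendedScheme)))
            stop("common random numbers require base TRs within extended TRs")
        res <- .with_seed(seed, function() {
            .t1_mc_paired(tissue, baseScheme, extendedScheme, sigma,
                          nReps, noiseModel, estimator)
        })
        base_est <- res$base; ext_est <- res$ext
    } else {
        base_est <- .with_seed(seed, function()
            .t1_mc(tissue, baseScheme, sigma, nReps, noiseModel, estimator))
        ext_est <- .with_seed(seed + 1L, function()
            .t1_mc(tissue, extendedScheme, sigma, nReps, noiseModel,
                   estimator))
    }
    mk <- function(est, scheme) new("SchemeReport", scheme = scheme,
        tissue = .tissue_vec(tissue), nReps = nReps,
        t1Sd = stats::sd(est[, 1]), t2starSd = stats::sd(est[, 2]),
        t1Bias = mean(est[, 1]) - tissue[["T1"]],
        t1Estimates = est[, 1], seed = as.integer(seed))
    base_rep <- mk(base_est, baseScheme)
    ext_rep <- mk(ext_est, extendedScheme)
    list(ratio = ext_rep@t1Sd / base_rep@t1Sd,
         base = base_rep, extended = ext_rep)
}

.t1_mc_paired <- function(tissue, base, ext, sigma, nReps, noiseModel,
                          estimator) {
    trs_e <- trList(ext); tes <- echoTimes(ext)
    trs_b <- trList(base)
    sel <- match(trs_b, trs_e)
    avg_e <- averages(ext)
    avg_b <- averages(base)
    clean_e <- t(spgrSignal(tissue[["amplitude"]], tissue[["flip"]],
                            1000 / tissue[["T1"]], 1000 / tissue[["T2star"]],
                            TR = trs_e, TE = tes))
    clean_b <- clean_e[, sel, drop = FALSE]
    est_b <- matrix(NA_real_, nReps, 2)
    est_e <- matrix(NA_real_, nReps, 2)
    nte <- length(tes)
    for (r in seq_len(nReps)) {
        z1 <- matrix(stats::rnorm(length(clean_e)), nrow = nte)
        z2 <- matrix(stats::rnorm(length(clean_e)), nrow = nte)
        noisy <- function(clean, cols, avg) {
            sds <- matrix(sigma / sqrt(rep(avg, each = nte)), nrow = nte)
            re <- clean + z1[, cols, drop = FALSE] * sds
            if (noiseModel == "rician")
                sqrt(re^2 + (z2[, cols, drop = FALSE] * sds)^2)
            else re
        }
        yb <- noisy(clean_b, sel, avg_b)
        ye <- noisy(clean_e, seq_along(trs_e), avg_e)
        eb <- .mc_estimate(yb, trs_b, tes, tissue, estimator, sqrt(avg_b))
        ee <- .mc_estimate(ye, trs_e, tes, tissue, estimator, sqrt(avg_e))
        if (!is.null(eb)) est_b[r, ] <- eb
        if (!is.null(ee)) est_e[r, ] <- ee
    }
    ok <- stats::complete.cases(est_b) & stats::complete.cases(est_e)
    list(base = est_b[ok, , drop = FALSE], ext = est_e[ok, , drop = FALSE])
}

#' Cramer-Rao lower bound on the T1 SD of a scheme
#'
#' Small-noise benchmark for the Monte-Carlo: numerical Fisher
#' information of the three-parameter (A, R1, R2*) model over the TR/TE
#' grid with per-point noise SD \code{sigma / sqrt(averages)}, inverted
#' and propagated to T1 = 1000/R1.
#'
#' @param tissue named numeric (amplitude, flip, T1, T2star)
#' @param scheme a \linkS4class{MEGEProtocol}
#' @param sigma single-average noise SD
#' @return the CRLB SD of T1 in ms
#' @export
crlbT1Sd <- function(tissue, scheme, sigma) {
    trs <- trList(scheme); tes <- echoTimes(scheme)
    avg <- averages(scheme)
    theta <- c(tissue[["amplitude"]], 1000 / tissue[["T1"]],
               1000 / tissue[["T2star"]])
    model <- function(p) as.vector(t(spgrSignal(p[1], tissue[["flip"]],
                                                p[2], p[3],
                                                TR = trs, TE = tes)))
    sds <- sigma / sqrt(rep(avg, each = length(tes)))
    J <- matrix(0, length(sds), 3)
    for (k in 1:3) {
        h <- theta[k] * 1e-5
        up <- theta; up[k] <- up[k] + h
        dn <- theta; dn[k] <- dn[k] - h
        J[, k] <- (model(up) - model(dn)) / (2 * h)
    }
    FI <- t(J / sds) %*% (J / sds)
    var_r1 <- solve(FI)[2, 2]
    sqrt(var_r1) * 1000 / theta[2]^2
}

#' Scan duration of a Cartesian MEGE protocol
#'
#' Pure phase-encode accounting: the sum over TRs of
#' \code{matrix_y x matrix_z x shutterFraction x averages x TR}. The
#' shutter fraction models vendor elliptical/partial acquisition; the
#' default 1.0 is full Cartesian encoding.
#'
#' @param scheme a \linkS4class{MEGEProtocol}
#' @param shutterFraction fraction of phase encodes acquired, in (0, 1]
#' @return total scan duration in seconds
#' @examples
#' scanDuration(loadingProtocol())  # 48 x 8 x 20 x 0.062 s = 476 s
#' @export
scanDuration <- function(scheme, shutterFraction = 1.0) {
    if (shutterFraction < 0 || shutterFraction > 1)
        stop("shutterFraction must lie in [0, 1]")
    m <- matrixSize(scheme)
    sum(m[2] * m[3] * shutterFraction * averages(scheme) *
        trList(scheme) / 1000)
}
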