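#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# Parameter bounds shared by all voxel fits (rates in 1/s, angles deg)
.R1_BOUNDS <- c(0.2, 20)
.R2_BOUNDS <- c(1, 500)
.FLIP_BOUNDS <- c(1, 120)

.new_quantmaps <- function(d) {
    na <- array(NA_real_, d)
    new("QuantMaps", flipAngle = na, R1 = na, R2star = na, amplitude = na,
        residualRMS = na, qcFlags = array(1L, d))
}

#' @rdname accessors
#' @export
setMethod("qcFlags", "QuantMaps", function(x) x@qcFlags)

setMethod("show", "QuantMaps", function(object) {
    n <- tabulate(object@qcFlags + 1L, 4L)
    cat(sprintf(paste0("QuantMaps: grid %s; %d fitted, %d skipped, ",
                       "%d bound-hit, %d non-converged\n"),
                paste(dim(object@qcFlags), collapse = "x"),
                n[1], n[2], n[3], n[4]))
})

# Voxels eligible for fitting: echo-summed signal (max across TR) at or
# above `frac` of its 99th percentile.
.threshold_mask <- function(summed_tr, frac) {
    v <- apply(summed_tr, 1:3, max)
    thr <- frac * stats::quantile(v, 0.99, names = FALSE)
    v >= thr
}

.at_bound <- function(x, bounds, tol = 1e-6) {
    x <= bounds[1] * (1 + tol) + tol | x >= bounds[2] * (1 - tol)
}

# Saturation-recovery fit of one voxel's TE-summed TR series.
# Multi-start (3 flip-angle starts, coarse R1 scan with analytic A).
# Residuals are inverse-variance weighted: the per-TR noise SD scales as
# 1/sqrt(averages), and equal weighting lets the noisy single-average
# long-TR points dominate and biases the recovered flip angle.
.fit_satrec_voxel <- function(y, trs, nominal_flip, weights = NULL) {
    if (is.null(weights)) weights <- rep(1, length(y))
    resid_fn <- function(p) {
        a <- p[2] * pi / 180
        E <- exp(-p[3] * trs / 1000)
        (p[1] * sin(a) * (1 - E) / (1 - cos(a) * E) - y) * weights
    }
    r1_grid <- exp(seq(log(0.3), log(15), length.out = 12))
    w2 <- weights^2
    best <- NULL
    # starts span the plausible B1 range of a birdcage head coil (~+/-15%
    # of nominal); wider spreads let noisy voxels lock onto spurious
    # high-flip ridge excursions and bias the neighbourhood mean
    for (fs in pmin(pmax(nominal_flip * c(0.85, 1, 1.15), 2), 119)) {
        a <- fs * pi / 180
        sse0 <- Inf; r1_0 <- 3; A0 <- max(y)
        for (r1 in r1_grid) {
            E <- exp(-r1 * trs / 1000)
            m <- sin(a) * (1 - E) / (1 - cos(a) * E)
            A <- max(sum(y * m * w2) / sum(m * m * w2), 0)
            sse <- sum(w2 * (A * m - y)^2)
            if (sse < sse0) { sse0 <- sse; r1_0 <- r1; A0 <- A }
        }
        fit <- tryCatch(suppressWarnings(
            nls.lm(par = c(A0, fs, r1_0), fn = resid_fn,
                   lower = c(0, .FLIP_BOUNDS[1], .R1_BOUNDS[1]),
                   upper = c(Inf, .FLIP_BOUNDS[2], .R1_BOUNDS[2]),
                   control = nls.lm.control(maxiter = 200))),
            error = function(e) NULL)
        if (is.null(fit)) next
        sse <- sum(fit$fvec^2)
        if (is.null(best) || sse < best$sse)
            best <- list(par = fit$par, sse = sse, info = fit$info)
    }
    if (is.null(best)) return(list(flag = 3L))
    p <- best$par
    # a parameter pinned at a bound marks a degenerate-but-informative fit
    # (flag 2) even when the optimizer exhausted its iterations there
    flag <- if (.at_bound(p[2], .FLIP_BOUNDS) || .at_bound(p[3], .R1_BOUNDS))
        2L else if (!best$info %in% 1:4) 3L else 0L
    if (flag == 3L) return(list(flag = 3L))
    list(A = p[1], flip = p[2], R1 = p[3],
         rms = sqrt(best$sse / length(y)), flag = flag)
}

#' Fit a flip-angle map from multi-TR echo-summed data
#'
#' First stage of the two-stage relaxometry fit: images are summed across
#' echoes at each TR and every above-threshold voxel's TR series is fitted
#' to the saturation-recovery model \code{\link{satrecSignal}} by bounded
#' nonlinear least squares, co-estimating flip angle, R1 and an effective
#' amplitude. Voxels below the signal threshold are flagged (code 1) and
#' skipped; voxels where a parameter lands on a bound carry code 2 and
#' non-converged voxels code 3.
#'
#' @param data a \linkS4class{MEGEDataset} with at least 3 TR values
#' @param signalThreshold fraction of the 99th-percentile echo-summed
#'   signal below which voxels are skipped (default 0.05)
#' @return a \linkS4class{QuantMaps} with flip-angle (deg), R1 (1/s) and
#'   amplitude maps populated
#' @seealso \code{\link{smoothFlipAngleMap}}, \code{\link{fitRelaxationMaps}}
#' @export
fitFlipAngleMap <- function(data, signalThreshold = 0.05) {
    p <- protocol(data)
    trs <- trList(p)
    if (length(trs) < 3L)
        stop("flip-angle fitting needs at least 3 TR values (3 unknowns)")
    sig <- signalArray(data)
    d <- dim(sig)[1:3]
    summed <- apply(sig, c(1, 2, 3, 5), sum)   # TE-summed, per TR
    fitmask <- .threshold_mask(summed, signalThreshold)
    maps <- .new_quantmaps(d)
    idx <- which(fitmask)
    smat <- matrix(summed, ncol = length(trs))
    w <- sqrt(averages(p))
    for (v in idx) {
        r <- .fit_satrec_voxel(smat[v, ], trs, nominalFlip(p), weights = w)
        maps@qcFlags[v] <- r$flag
        if (r$flag %in% c(0L, 2L)) {
            maps@flipAngle[v] <- r$flip
            maps@R1[v] <- r$R1
            maps@amplitude[v] <- r$A
            maps@residualRMS[v] <- r$rms
        }
    }
    maps
}

#' Smooth a flip-angle map over a 5x5x5 neighbourhood
#'
#' Each voxel is replaced by the mean of the valid (unflagged, in-volume)
#' voxels in its 5x5x5 neighbourhood; at the volume edge the neighbourhood
#' shrinks to the in-volume part. Voxels with no valid neighbour stay
#' \code{NA}.
#'
#' @param alphaMap 3-D flip-angle array, degrees
#' @param qcFlags integer flag array; \code{NULL} treats every
#'   non-\code{NA} voxel as valid
#' @param validFlags flag codes treated as valid (default 0 and 2: a
#'   single voxel's flip angle is noisy and often lands on a bound; the
#'   neighbourhood mean over all fitted voxels is what estimates the
#'   smooth B1 field without selection bias)
#' @return smoothed flip-angle array
#' @export
smoothFlipAngleMap <- function(alphaMap, qcFlags = NULL,
                               validFlags = c(0L, 2L)) {
    if (length(dim(alphaMap)) != 3L) stop("alphaMap must be a 3-D array")
    valid <- !is.na(alphaMap)
    if (!is.null(qcFlags)) valid <- valid & qcFlags %in% validFlags
    .box_mean_valid(alphaMap, valid, r = 2L)$mean
}

# Dual R1/R2* fit of one voxel's full TR x TE grid with alpha fixed.
.fit_relax_voxel <- function(y, trs, tes, flip, r1_init) {
    a <- flip * pi / 180
    ymat <- matrix(y, nrow = length(tes), ncol = length(trs))
    # log-linear R2* start from the TE decay at the longest TR
    ylast <- pmax(ymat[, length(trs)], max(ymat) * 1e-6)
    sl <- stats::coef(stats::lm(log(ylast) ~ tes))[2]
    r2_0 <- min(max(-sl * 1000, .R2_BOUNDS[1]), .R2_BOUNDS[2])
    resid_fn <- function(p) {
        E <- exp(-p[2] * trs / 1000)
        sat <- p[1] * sin(a) * (1 - E) / (1 - cos(a) * E)
        as.vector(outer(exp(-p[3] * tes / 1000), sat) - ymat)
    }
    starts <- list(c(r1_init, r2_0), c(r1_init * 3, r2_0),
                   c(r1_init / 3, r2_0))
    best <- NULL
    for (s in starts) {
        E <- exp(-s[1] * trs / 1000)
        m <- outer(exp(-s[2] * tes / 1000),
                   sin(a) * (1 - E) / (1 - cos(a) * E))
        A0 <- max(sum(ymat * m) / sum(m * m), 0)
        fit <- tryCatch(suppressWarnings(
            nls.lm(par = c(A0, s[1], s[2]), fn = resid_fn,
                   lower = c(0, .R1_BOUNDS[1], .R2_BOUNDS[1]),
                   upper = c(Inf, .R1_BOUNDS[2], .R2_BOUNDS[2]),
                   control = nls.lm.control(maxiter = 200))),
            error = function(e) NULL)
        if (is.null(fit)) next
        sse <- sum(fit$fvec^2)
        if (is.null(best) || sse < best$sse)
            best <- list(par = fit$par, sse = sse, info = fit$info)
    }
    if (is.null(best)) return(list(flag = 3L))
    p <- best$par
    flag <- if (.at_bound(p[2], .R1_BOUNDS) || .at_bound(p[3], .R2_BOUNDS))
        2L else if (!best$info %in% 1:4) 3L else 0L
    if (flag == 3L) return(list(flag = 3L))
    list(A = p[1], R1 = p[2], R2star = p[3],
         rms = sqrt(best$sse / length(y)), flag = flag)
}

#' Dual R1/R2* fit across the TR/TE grid with fixed flip angles
#'
#' Second stage of the relaxometry fit: with the (smoothed) flip-angle map
#' held fixed, each voxel's full signal grid S(TR_i, TE_j) is fitted for
#' amplitude, R1 and R2* by bounded nonlinear least squares on the sum of
#' squared residuals of the spoiled gradient-echo model. R2* is
#' initialised from a log-linear fit of the TE decay at the longest TR,
#' R1 from the first-stage estimate (or 1000/300 per s), and the amplitude
#' by linear back-projection.
#'
#' @param data a \linkS4class{MEGEDataset} with at least 2 TRs and 2 echoes
#' @param alphaMap flip-angle array in degrees, aligned with the data grid;
#'   must be non-\code{NA} at every voxel to be fitted
#' @param signalThreshold as in \code{\link{fitFlipAngleMap}}
#' @param r1Init optional R1 (1/s) array of starting values (e.g. the
#'   first-stage \code{QuantMaps} R1 slot)
#' @return a \linkS4class{QuantMaps} with R1, R2*, amplitude populated
#' @export
fitRelaxationMaps <- function(data, alphaMap, signalThreshold = 0.05,
                              r1Init = NULL) {
    p <- protocol(data)
    trs <- trList(p)
    tes <- echoTimes(p)
    if (length(trs) < 2L || length(tes) < 2L)
        stop("dual R1/R2* fitting needs >= 2 TRs and >= 2 echoes")
    sig <- signalArray(data)
    d <- dim(sig)[1:3]
    if (!identical(dim(alphaMap), d))
        stop("alphaMap is not aligned with the data grid")
    summed <- apply(sig, c(1, 2, 3, 5), sum)
    fitmask <- .threshold_mask(summed, signalThreshold)
    if (anyNA(alphaMap[fitmask]))
        stop("alphaMap has missing values at voxels selected for fitting")
    maps <- .new_quantmaps(d)
    idx <- which(fitmask)
    nvox <- prod(d)
    smat <- matrix(sig, nrow = nvox)  # columns ordered (echo, TR)
    for (v in idx) {
        r1_0 <- if (!is.null(r1Init) && !is.na(r1Init[v])) r1Init[v] else 1000 / 300
        r <- .fit_relax_voxel(smat[v, ], trs, tes, alphaMap[v], r1_0)
        maps@qcFlags[v] <- r$flag
        if (r$flag %in% c(0L, 2L)) {
            maps@flipAngle[v] <- alphaMap[v]
            maps@R1[v] <- r$R1
            maps@R2star[v] <- r$R2star
            maps@amplitude[v] <- r$A
            maps@residualRMS[v] <- r$rms
        }
    }
    maps
}

#' Mono-exponential T2* fit of single-TR multi-echo data
#'
#' Fits \code{S(TE) = S0 exp(-R2* TE)} voxel-wise by nonlinear least
#' squares with a log-linear start — the fit used for proton R2* maps
#' from a single-TR multi-echo acquisition.
#'
#' @param data a \linkS4class{MEGEDataset} with exactly one TR and >= 2
#'   echoes
#' @param signalThreshold as in \code{\link{fitFlipAngleMap}}
#' @return a \linkS4class{QuantMaps} with R2* and amplitude populated
#' @export
fitT2starMonoexp <- function(data, signalThreshold = 0.05) {
    p <- protocol(data)
    tes <- echoTimes(p)
    if (p@nEchoes < 2L)
        stop("mono-exponential T2* fitting needs at least 2 echoes")
    if (length(trList(p)) != 1L)
        stop("fitT2starMonoexp expects a single-TR dataset")
    sig <- signalArray(data)
    d <- dim(sig)[1:3]
    summed <- apply(sig, c(1, 2, 3, 5), sum)
    fitmask <- .threshold_mask(summed, signalThreshold)
    maps <- .new_quantmaps(d)
    idx <- which(fitmask)
    smat <- matrix(sig, nrow = prod(d))
    for (v in idx) {
        y <- smat[v, ]
        ypos <- pmax(y, max(y) * 1e-6)
        sl <- stats::coef(stats::lm(log(ypos) ~ tes))
        r2_0 <- min(max(-sl[2] * 1000, .R2_BOUNDS[1]), .R2_BOUNDS[2])
        A0 <- max(exp(sl[1]), 0)
        fit <- tryCatch(suppressWarnings(
            nls.lm(par = c(A0, r2_0),
                   fn = function(q) q[1] * exp(-q[2] * tes / 1000) - y,
                   lower = c(0, .R2_BOUNDS[1]), upper = c(Inf, .R2_BOUNDS[2]),
                   control = nls.lm.control(maxiter = 200))),
            error = function(e) NULL)
        at_bound <- !is.null(fit) && .at_bound(fit$par[2], .R2_BOUNDS)
        if (is.null(fit) || (!fit$info %in% 1:4 && !at_bound)) {
            maps@qcFlags[v] <- 3L
            next
        }
        flag <- if (at_bound) 2L else 0L
        maps@qcFlags[v] <- flag
        maps@R2star[v] <- fit$par[2]
        maps@amplitude[v] <- fit$par[1]
        maps@residualRMS[v] <- sqrt(sum(fit$fvec^2) / length(y))
    }
    maps
}
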