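#' Sum a MEGE dataset over echoes (and optionally TRs)
#'
#' Voxel-wise arithmetic sum along the echo axis, and optionally also the
#' TR axis — the summation images used both for display and as the input
#' of the saturation-recovery stage. Linear in the input.
#'
#' @param data a \linkS4class{MEGEDataset}
#' @param over "TE" (returns an x,y,z,TR array) or "TE_and_TR" (returns a
#'   3-D array)
#' @return numeric array of sums
#' @export
sumOverEchoes <- function(data, over = c("TE", "TE_and_TR")) {
    over <- match.arg(over)
    sig <- signalArray(data)
    if (over == "TE") apply(sig, c(1, 2, 3, 5), sum)
    else apply(sig, c(1, 2, 3), sum)
}

#' Resample an image or mask onto another voxel grid
#'
#' Pull-resampling through composed world transforms: each target voxel
#' index (0-based) is mapped to world mm by the target affine, then to a
#' source voxel index by the inverse source affine, and the source image
#' is sampled there. Masks should use \code{mode = "nearest"} (binary in,
#' binary out); images \code{"trilinear"}. Points falling outside the
#' source field of view map to 0.
#'
#' @param x 3-D numeric array in the source grid
#' @param affineSrc,affineDst 4x4 voxel-to-world (mm) affines, 0-based
#'   voxel indices, standard NIfTI semantics
#' @param targetShape integer length-3 target grid dimensions
#' @param mode "nearest" or "trilinear"
#' @return 3-D array of dimension \code{targetShape}
#' @export
resampleToGrid <- function(x, affineSrc, affineDst, targetShape,
                           mode = c("nearest", "trilinear")) {
    mode <- match.arg(mode)
    if (abs(det(affineSrc)) < 1e-12 || abs(det(affineDst)) < 1e-12)
        stop("affines must be invertible")
    d <- dim(x)
    ts <- as.integer(targetShape)
    # 0-based target voxel coordinates
    g <- as.matrix(expand.grid(i = 0:(ts[1] - 1), j = 0:(ts[2] - 1),
                               k = 0:(ts[3] - 1)))
    M <- solve(affineSrc) %*% affineDst   # target voxel -> source voxel
    src <- t(M %*% t(cbind(g, 1)))[, 1:3, drop = FALSE]
    out <- numeric(nrow(src))
    if (mode == "nearest") {
        si <- round(src) + 1   # to 1-based
        ok <- si[, 1] >= 1 & si[, 1] <= d[1] & si[, 2] >= 1 &
              si[, 2] <= d[2] & si[, 3] >= 1 & si[, 3] <= d[3]
        lin <- si[ok, 1] + (si[ok, 2] - 1) * d[1] +
               (si[ok, 3] - 1) * d[1] * d[2]
        out[ok] <- x[lin]
    } else {
        f <- floor(src)
        w <- src - f
        for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
            ci <- f + rep(c(dx, dy, dz), each = nrow(f))
            dim(ci) <- dim(f)
            wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
                  (if (dy == 1) w[, 2] else 1 - w[, 2]) *
                  (if (dz == 1) w[, 3] else 1 - w[, 3])
            si <- ci + 1
            ok <- si[, 1] >= 1 & si[, 1] <= d[1] & si[, 2] >= 1 &
                  si[, 2] <= d[2] & si[, 3] >= 1 & si[, 3] <= d[3]
            lin <- si[ok, 1] + (si[ok, 2] - 1) * d[1] +
                   (si[ok, 3] - 1) * d[1] * d[2]
            out[ok] <- out[ok] + wt[ok] * x[lin]
        }
    }
    array(out, ts)
}

#' Retain the largest interior components of a CSF mask
#'
#' Deterministic surrogate for manually pruning the outer regions of a
#' CSF mask so that it is dominated by the lateral ventricles: connected
#' components are labelled at 26-connectivity, components touching the
#' supplied exterior mask (e.g. the non-brain background — these are the
#' cortical-surface CSF) are discarded, and the \code{k} largest remaining
#' components are kept.
#'
#' @param mask 3-D binary CSF mask
#' @param k number of components to keep (default 2, the lateral
#'   ventricles)
#' @param exterior optional binary mask; components 26-adjacent to it are
#'   dropped before size ranking
#' @return pruned binary mask
#' @export
refineCSFMask <- function(mask, k = 2L, exterior = NULL) {
    if (!any(mask > 0)) {
        warning("empty CSF mask")
        return(array(FALSE, dim(mask)))
    }
    comp <- .label_components_3d(mask > 0)
    ids <- sort(unique(comp[comp > 0]))
    if (!is.null(exterior)) {
        keep <- vapply(ids, function(i) !any(.dilate1(comp == i) &
                                             (exterior > 0)), logical(1))
        ids <- ids[keep]
    }
    sizes <- vapply(ids, function(i) sum(comp == i), integer(1))
    kept <- ids[order(sizes, decreasing = TRUE)][seq_len(min(k, length(ids)))]
    array(comp %in% kept, dim(mask))
}

# Value-dependent rounding matching the printed precision of the in-vivo
# summary table: deuterium times >= 50 ms print to the nearest 10 ms,
# shorter deuterium times and all proton times to the nearest 1 ms.
.table1_round <- function(x, nucleus) {
    if (nucleus == "2H") ifelse(abs(x) >= 50, round(x / 10) * 10, round(x))
    else round(x)
}

#' ROI statistics of a relaxation-time map (or per-visit values)
#'
#' Mean and sample SD over the unflagged voxels of each named mask, or —
#' when \code{x} is a named list of numeric vectors — visit-level
#' summaries of per-visit scalars. \code{rounding = "table1"} applies the
#' value-dependent printed precision of the reference table (deuterium
#' times >= 50 ms to 10 ms, otherwise 1 ms; proton times to 1 ms).
#'
#' @param x 3-D map in ms, or a named list of numeric vectors
#' @param masks named list of binary arrays (ignored in list mode)
#' @param qc optional integer flag array; only voxels with flag 0 enter
#'   the statistics
#' @param rounding "none" or "table1"
#' @param nucleus "2H" or "1H" (selects the table1 rounding rule)
#' @return data.frame with columns \code{roi}, \code{mean}, \code{sd},
#'   \code{n}
#' @examples
#' v <- visitRelaxationTimes()
#' roiStatistics(list(CSF = v$csf_t1_2h), rounding = "table1") # mean 510
#' @export
roiStatistics <- function(x, masks = NULL, qc = NULL,
                          rounding = c("none", "table1"),
                          nucleus = c("2H", "1H")) {
    rounding <- match.arg(rounding)
    nucleus <- match.arg(nucleus)
    if (is.list(x)) {
        vals <- lapply(x, function(v) v[!is.na(v)])
    } else {
        if (is.null(masks)) stop("masks are required for map input")
        ok <- !is.na(x)
        if (!is.null(qc)) ok <- ok & qc == 0L
        vals <- lapply(masks, function(m) {
            if (!identical(dim(m), dim(x)))
                stop("mask not aligned with map")
            x[m > 0 & ok]
        })
    }
    n <- vapply(vals, length, integer(1))
    if (any(n == 0))
        stop("empty effective mask: ",
             paste(names(vals)[n == 0], collapse = ", "))
    mu <- vapply(vals, mean, numeric(1))
    sdv <- vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else 0,
                  numeric(1))
    if (rounding == "table1") {
        mu <- .table1_round(mu, nucleus)
        sdv <- .table1_round(sdv, nucleus)
    }
    data.frame(roi = names(vals), mean = unname(mu), sd = unname(sdv),
               n = unname(n), row.names = NULL)
}

#' Estimate image SNR from tissue and background ROIs
#'
#' Mean signal over the tissue mask divided by the SD of the signal over
#' the background mask. No Rayleigh/Rician correction is applied to the
#' background SD.
#'
#' @param image 3-D signal array (typically an echo-summed image)
#' @param tissueMask,backgroundMask disjoint non-empty binary arrays
#' @return the SNR (dimensionless)
#' @export
estimateSNR <- function(image, tissueMask, backgroundMask) {
    if (!any(tissueMask > 0) || !any(backgroundMask > 0))
        stop("tissue and background masks must be non-empty")
    if (any(tissueMask > 0 & backgroundMask > 0))
        stop("tissue and background masks must be disjoint")
    s <- stats::sd(image[backgroundMask > 0])
    if (s == 0) stop("zero background SD")
    mean(image[tissueMask > 0]) / s
}

#' Two-sample t-test
#'
#' Classic pooled-variance (default) or Welch two-sample t statistic with
#' a two-tailed p-value from the t distribution. With zero pooled
#' variance and equal means, p = 1 by convention.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2
#' @param variant "pooled" or "welch"
#' @return list with elements \code{t}, \code{df}, \code{p}
#' @examples
#' v <- visitRelaxationTimes()
#' twoSampleTTest(v$csf_t1_2h, v$gm_t1_2h)$p   # ~0.004
#' @export
twoSampleTTest <- function(groupA, groupB, variant = c("pooled", "welch")) {
    variant <- match.arg(variant)
    a <- groupA[!is.na(groupA)]; b <- groupB[!is.na(groupB)]
    na <- length(a); nb <- length(b)
    if (na < 2 || nb < 2) stop("each group needs at least 2 values")
    va <- stats::var(a); vb <- stats::var(b)
    dm <- mean(a) - mean(b)
    if (variant == "pooled") {
        sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
        df <- na + nb - 2
        se <- sqrt(sp2 * (1 / na + 1 / nb))
    } else {
        se <- sqrt(va / na + vb / nb)
        df <- (va / na + vb / nb)^2 /
            ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    if (se == 0) {
        if (dm == 0) return(list(t = 0, df = df, p = 1))
        return(list(t = sign(dm) * Inf, df = df, p = 0))
    }
    t <- dm / se
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
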