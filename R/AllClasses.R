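#' @import methods
NULL

#' MEGE acquisition protocol
#'
#' Describes a spoiled multi-echo gradient-echo (MEGE) acquisition: the
#' repetition-time list with per-TR averaging, the echo-time grid
#' (\code{TE_j = TE1 + (j-1) * deltaTE}), the nominal excitation flip angle
#' and the imaging geometry. The in-plane/through-plane matrix size is
#' derived from FOV and voxel size, which must divide exactly.
#'
#' @slot trList repetition times in ms, strictly increasing
#' @slot averages number of signal averages acquired at each TR
#' @slot te1 first echo time in ms
#' @slot deltaTE echo spacing in ms
#' @slot nEchoes number of echoes
#' @slot nominalFlip nominal flip angle in degrees
#' @slot fov field of view in mm (length 3)
#' @slot voxelSize voxel dimensions in mm (length 3)
#'
#' @export
setClass("MEGEProtocol",
    representation(
        trList = "numeric",
        averages = "numeric",
        te1 = "numeric",
        deltaTE = "numeric",
        nEchoes = "integer",
        nominalFlip = "numeric",
        fov = "numeric",
        voxelSize = "numeric"
    )
)

setValidity("MEGEProtocol", function(object) {
    msg <- character()
    if (length(object@trList) < 1L || any(object@trList <= 0))
        msg <- c(msg, "trList must contain positive repetition times")
    if (is.unsorted(object@trList, strictly = TRUE))
        msg <- c(msg, "trList must be strictly increasing")
    if (length(object@averages) != length(object@trList))
        msg <- c(msg, "averages must match trList in length")
    if (any(object@averages < 0))
        msg <- c(msg, "averages must be >= 0")
    if (object@te1 <= 0 || object@deltaTE <= 0)
        msg <- c(msg, "te1 and deltaTE must be positive")
    if (object@nEchoes < 1L)
        msg <- c(msg, "nEchoes must be >= 1")
    if (object@nominalFlip <= 0 || object@nominalFlip > 180)
        msg <- c(msg, "nominalFlip must lie in (0, 180] degrees")
    if (length(object@fov) != 3L || length(object@voxelSize) != 3L)
        msg <- c(msg, "fov and voxelSize must have length 3")
    else {
        if (any(object@fov <= 0) || any(object@voxelSize <= 0))
            msg <- c(msg, "fov and voxelSize must be positive")
        m <- object@fov / object@voxelSize
        if (any(abs(m - round(m)) > 1e-6))
            msg <- c(msg, "FOV must be an exact multiple of voxel size")
    }
    if (length(msg)) msg else TRUE
})

#' MEGE magnitude image dataset
#'
#' A 5-D magnitude image array indexed (x, y, z, echo, TR-index), bound to
#' the \linkS4class{MEGEProtocol} that produced it.
#'
#' @slot signal 5-D numeric array, dimensions matrix-x, matrix-y, matrix-z,
#'   nEchoes, nTR
#' @slot protocol the acquisition protocol
#'
#' @export
setClass("MEGEDataset",
    representation(signal = "array", protocol = "MEGEProtocol")
)

setValidity("MEGEDataset", function(object) {
    d <- dim(object@signal)
    if (length(d) != 5L)
        return("signal must be a 5-D array (x, y, z, echo, TR-index)")
    p <- object@protocol
    m <- round(p@fov / p@voxelSize)
    if (!all(d[1:3] == m))
        return(sprintf("spatial dimensions %s do not match protocol matrix %s",
                       paste(d[1:3], collapse = "x"), paste(m, collapse = "x")))
    if (d[4] != p@nEchoes)
        return("echo dimension does not match protocol nEchoes")
    if (d[5] != length(p@trList))
        return("TR dimension does not match protocol trList")
    TRUE
})

#' Voxel-wise quantitative parameter maps
#'
#' Holds the fitted flip-angle, R1, R2* and amplitude maps together with a
#' per-voxel residual RMS and quality-control flag. Unfitted voxels carry
#' \code{NA} in the parameter maps and a nonzero flag: 1 = below signal
#' threshold (skipped), 2 = parameter at a bound, 3 = optimizer did not
#' converge.
#'
#' @slot flipAngle flip-angle map in degrees
#' @slot R1 longitudinal relaxation rate map in 1/s
#' @slot R2star effective transverse relaxation rate map in 1/s
#' @slot amplitude signal amplitude map (arbitrary units)
#' @slot residualRMS per-voxel root-mean-square fit residual
#' @slot qcFlags integer flag array (0 ok, 1 skipped, 2 bound-hit,
#'   3 non-converged)
#'
#' @export
setClass("QuantMaps",
    representation(
        flipAngle = "array",
        R1 = "array",
        R2star = "array",
        amplitude = "array",
        residualRMS = "array",
        qcFlags = "array"
    )
)

setValidity("QuantMaps", function(object) {
    d <- dim(object@qcFlags)
    slots <- c("flipAngle", "R1", "R2star", "amplitude", "residualRMS")
    for (s in slots) {
        if (!identical(dim(slot(object, s)), d))
            return(sprintf("slot '%s' does not match qcFlags dimensions", s))
    }
    if (!all(object@qcFlags %in% 0:3))
        return("qcFlags must contain codes 0-3 only")
    TRUE
})

#' Ground truth for the synthetic digital brain phantom
#'
#' Three-tissue (CSF/GM/WM) nested-ellipsoid brain with per-voxel T1, T2*
#' and amplitude maps, a smooth multiplicative B1 (flip-angle scaling)
#' field, and the magnitude-noise specification used when synthesizing
#' acquisitions from it.
#'
#' @slot labelMap integer array: 0 background, 1 CSF, 2 GM, 3 WM
#' @slot t1Map per-voxel T1 in ms
#' @slot t2starMap per-voxel T2* in ms
#' @slot amplitudeMap per-voxel signal amplitude (water-fraction scale)
#' @slot b1Field multiplicative flip-angle field, actual alpha = b1 x nominal
#' @slot voxelSize voxel dimensions in mm
#' @slot noiseSigma magnitude noise SD per single-average image
#' @slot noiseModel "gaussian" or "rician"
#' @slot seed integer seed the phantom was built with
#'
#' @export
setClass("PhantomTruth",
    representation(
        labelMap = "array",
        t1Map = "array",
        t2starMap = "array",
        amplitudeMap = "array",
        b1Field = "array",
        voxelSize = "numeric",
        noiseSigma = "numeric",
        noiseModel = "character",
        seed = "integer"
    )
)

setValidity("PhantomTruth", function(object) {
    d <- dim(object@labelMap)
    for (s in c("t1Map", "t2starMap", "amplitudeMap", "b1Field"))
        if (!identical(dim(slot(object, s)), d))
            return(sprintf("slot '%s' does not match labelMap dimensions", s))
    if (!all(object@labelMap %in% 0:3))
        return("labelMap must contain labels 0-3 only")
    tissue <- object@labelMap > 0L
    if (any(object@t1Map[tissue] <= 0) || any(object@t2starMap[tissue] <= 0))
        return("tissue T1/T2* must be positive")
    if (any(object@b1Field < 0.5 - 1e-9) || any(object@b1Field > 1.5 + 1e-9))
        return("b1Field must lie in [0.5, 1.5]")
    if (object@noiseSigma < 0)
        return("noiseSigma must be >= 0")
    if (!object@noiseModel %in% c("gaussian", "rician"))
        return("noiseModel must be 'gaussian' or 'rician'")
    TRUE
})

#' Deuterium enrichment time series
#'
#' Enrichment (atom % deuterium) sampled at a sorted set of times, with a
#' provenance tag recording whether it came from a dose model, from
#' spectroscopy amplitudes, or from the synthetic generator.
#'
#' @slot times minutes since first dose
#' @slot enrichment atom percent deuterium
#' @slot provenance one of "from_dose", "from_spectra", "synthetic"
#'
#' @export
setClass("EnrichmentSeries",
    representation(times = "numeric", enrichment = "numeric",
                   provenance = "character")
)

setValidity("EnrichmentSeries", function(object) {
    if (length(object@times) != length(object@enrichment))
        return("times and enrichment must have equal length")
    if (is.unsorted(object@times))
        return("times must be sorted")
    if (any(object@enrichment < 0))
        return("enrichment must be >= 0")
    if (!object@provenance %in% c("from_dose", "from_spectra", "synthetic"))
        return("unknown provenance")
    TRUE
})

#' Monte-Carlo precision report for a sampling scheme
#'
#' Result of repeated synthesize-and-refit experiments for one tissue and
#' one TR/TE sampling scheme: the SD and bias of the fitted T1 (and the SD
#' of the fitted T2*), with the seed for reproducibility.
#'
#' @slot scheme the \linkS4class{MEGEProtocol} simulated
#' @slot tissue named numeric: amplitude, flip (deg), T1 (ms), T2star (ms)
#' @slot nReps number of Monte-Carlo repetitions
#' @slot t1Sd sample SD of fitted T1 in ms
#' @slot t2starSd sample SD of fitted T2* in ms
#' @slot t1Bias mean fitted T1 minus true T1, ms
#' @slot t1Estimates the raw fitted T1 values (ms)
#' @slot seed integer seed
#'
#' @export
setClass("SchemeReport",
    representation(
        scheme = "MEGEProtocol",
        tissue = "numeric",
        nReps = "integer",
        t1Sd = "numeric",
        t2starSd = "numeric",
        t1Bias = "numeric",
        t1Estimates = "numeric",
        seed = "integer"
    )
)

setValidity("SchemeReport", function(object) {
    if (object@nReps < 50L)
        return("nReps must be >= 50")
    if (object@t1Sd < 0 || object@t2starSd < 0)
        return("SDs must be >= 0")
    TRUE
})
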