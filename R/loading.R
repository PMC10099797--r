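#' Total body water volume
#'
#' The dilution space for ingested D2O. \code{method = "watson"} uses the
#' published Watson anthropometric equations (litres):
#' males \code{2.447 - 0.09156 age + 0.1074 height + 0.3362 mass},
#' females \code{-2.097 + 0.1069 height + 0.2466 mass}.
#' \code{method = "fraction"} uses a fixed fraction of body mass
#' (default 0.60, 1 kg ~ 1 L).
#'
#' @param sex "male" or "female"
#' @param age years
#' @param height cm
#' @param mass kg
#' @param method "watson" (default) or "fraction"
#' @param fraction water fraction of body mass for the fraction method
#' @return total body water in litres
#' @examples
#' totalBodyWater("male", 30, 175, 70)            # 42.0 L
#' totalBodyWater("male", 30, 175, 70, "fraction") # 42.0 L
#' @export
totalBodyWater <- function(sex, age, height, mass,
                           method = c("watson", "fraction"),
                           fraction = 0.60) {
    method <- match.arg(method)
    if (any(c(age, height, mass) <= 0))
        stop("anthropometrics must be positive")
    if (method == "fraction") {
        if (fraction <= 0) stop("fraction must be positive")
        return(fraction * mass)
    }
    sex <- match.arg(sex, c("male", "female"))
    if (sex == "male")
        2.447 - 0.09156 * age + 0.1074 * height + 0.3362 * mass
    else
        -2.097 + 0.1069 * height + 0.2466 * mass
}

#' Enrichment from a cumulative dose schedule
#'
#' Deuterium enrichment implied by the total imbibed D2O volume relative
#' to total body water: \code{100 * sum(volume * fraction) / (tbw * 1000)}
#' atom %, optionally adding the 0.015 atom % natural-abundance baseline.
#' With \code{cumulative = TRUE} a step series over the dose times is
#' returned instead of the final scalar.
#'
#' @param doses data.frame with columns \code{time_min}, \code{volume_ml},
#'   \code{d2o_fraction}; may have zero rows
#' @param tbw total body water, litres
#' @param includeBaseline add the 0.015 atom % natural abundance
#' @param cumulative return the running enrichment after each dose
#' @return atom % deuterium (scalar, or a data.frame \code{time_min},
#'   \code{enrichment} when cumulative)
#' @examples
#' sched <- standardDoseSchedule(nDoses = 18)  # 900 ml of 70% solution
#' enrichmentFromDoses(sched, tbw = 42)        # 1.5
#' @export
enrichmentFromDoses <- function(doses, tbw, includeBaseline = FALSE,
                                cumulative = FALSE) {
    if (tbw <= 0) stop("tbw must be positive")
    base <- if (includeBaseline) 0.015 else 0
    if (!nrow(doses)) {
        if (cumulative)
            return(data.frame(time_min = numeric(), enrichment = numeric()))
        return(base)
    }
    added <- 100 * doses$volume_ml * doses$d2o_fraction / (tbw * 1000)
    if (cumulative)
        data.frame(time_min = doses$time_min,
                   enrichment = base + cumsum(added))
    else
        base + sum(added)
}

#' Integrate the HDO resonance of a magnitude spectrum
#'
#' Discrete integral (sum x frequency spacing) of the magnitude spectrum
#' over a window centred on the HDO peak (taken as the spectrum maximum).
#' Linear in the spectrum amplitude.
#'
#' @param spectrum data.frame with columns \code{frequency_hz} and
#'   \code{magnitude}, on a uniform frequency grid
#' @param window half-width of the integration window, Hz; must lie
#'   within the spectral bandwidth
#' @return integrated amplitude (magnitude x Hz)
#' @export
integrateHDOSignal <- function(spectrum, window) {
    f <- spectrum$frequency_hz
    m <- spectrum$magnitude
    if (window <= 0) stop("window must be positive")
    if (window > (max(f) - min(f)) / 2)
        stop("window exceeds the spectral bandwidth")
    df <- stats::median(diff(f))
    if (all(m == 0)) return(0)
    centre <- f[which.max(m)]
    sel <- abs(f - centre) <= window
    sum(m[sel]) * df
}

#' Enrichment from a signal amplitude via natural-abundance scaling
#'
#' Scales a measured HDO signal by the pre-loading (natural-abundance)
#' signal: enrichment = natural abundance x signal / baseline signal, so
#' a 100-fold signal gives 1.5 atom % at the 0.015 % baseline.
#'
#' @param signal measured HDO amplitude (>= 0)
#' @param baselineSignal natural-abundance amplitude (> 0)
#' @param naturalAbundance atom % (default 0.015)
#' @return atom % deuterium
#' @examples
#' enrichmentFromSignal(100, 1)  # 1.5
#' @export
enrichmentFromSignal <- function(signal, baselineSignal,
                                 naturalAbundance = 0.015) {
    if (any(baselineSignal <= 0)) stop("baseline signal must be positive")
    if (any(signal < 0)) stop("signal must be >= 0")
    naturalAbundance * signal / baselineSignal
}

#' Normalize ROI time-courses to a reference ROI's final value
#'
#' Divides every series by the reference ROI's value at the final time
#' point (the late-time normalization used when pre-loading SNR is too
#' low for a natural-abundance baseline); the reference ROI then ends at
#' exactly 1.
#'
#' @param roiSeries data.frame with a \code{time_min} column and one
#'   numeric column per ROI
#' @param referenceROI name of the reference ROI column
#' @param referenceTime currently only \code{"last"}
#' @return data.frame of the same shape with scaled series
#' @export
normalizeTimecourse <- function(roiSeries, referenceROI,
                                referenceTime = "last") {
    referenceTime <- match.arg(referenceTime, "last")
    if (!referenceROI %in% names(roiSeries))
        stop("reference ROI '", referenceROI, "' not found")
    ref <- roiSeries[[referenceROI]][nrow(roiSeries)]
    if (is.na(ref) || ref <= 0) stop("reference value must be positive")
    out <- roiSeries
    cols <- setdiff(names(roiSeries), "time_min")
    out[cols] <- lapply(roiSeries[cols], function(v) v / ref)
    out
}
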