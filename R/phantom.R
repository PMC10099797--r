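#' Default tissue relaxation parameters at 7T
#'
#' Mean and SD of deuterium (HDO) T1 and T2* (ms) in CSF, GM and WM at 7T,
#' together with relative signal amplitudes (water-fraction scale: CSF 1.0,
#' GM 0.8, WM 0.7). The means/SDs are the across-visit summary values of
#' the in-vivo reference table (see \code{\link{visitRelaxationTimes}});
#' they are the defaults the phantom draws per-voxel parameters from.
#'
#' @param nucleus "2H" (default) or "1H" (proton T2* only; T1 values for
#'   protons are not part of the reference table and are set to NA)
#' @return data.frame with rows CSF, GM, WM and columns
#'   \code{t1_mean, t1_sd, t2star_mean, t2star_sd, amplitude}
#' @export
defaultTissueParams <- function(nucleus = c("2H", "1H")) {
    nucleus <- match.arg(nucleus)
    if (nucleus == "2H") {
        data.frame(
            row.names = c("CSF", "GM", "WM"),
            t1_mean = c(510, 320, 290),
            t1_sd = c(100, 50, 30),
            t2star_mean = c(90, 32, 30),
            t2star_sd = c(10, 1, 1),
            amplitude = c(1.0, 0.8, 0.7)
        )
    } else {
        data.frame(
            row.names = c("CSF", "GM", "WM"),
            t1_mean = c(NA_real_, NA_real_, NA_real_),
            t1_sd = c(NA_real_, NA_real_, NA_real_),
            t2star_mean = c(97, 24, 23),
            t2star_sd = c(5, 2, 2),
            amplitude = c(1.0, 0.8, 0.7)
        )
    }
}

#' Per-visit tissue relaxation times measured at 7T
#'
#' Reference per-visit mean relaxation times (ms) of deuterium (T1, T2*)
#' and proton (T2*) in CSF, GM and WM from six scanning visits of four
#' participants at 7T (proton values from four visits). These are the
#' per-visit values whose across-visit means define
#' \code{\link{defaultTissueParams}}; they are also the inputs for
#' tissue-comparison t-tests and visit-level summaries.
#'
#' @return data.frame with columns \code{subject}, \code{visit},
#'   \code{csf_t1_2h}, \code{csf_t2star_2h}, \code{gm_t1_2h},
#'   \code{gm_t2star_2h}, \code{wm_t1_2h}, \code{wm_t2star_2h},
#'   \code{csf_t2star_1h}, \code{gm_t2star_1h}, \code{wm_t2star_1h}
#' @export
visitRelaxationTimes <- function() {
    data.frame(
        subject = c("A", "B", "C", "C", "D", "D"),
        visit = c(1L, 1L, 1L, 2L, 1L, 2L),
        csf_t1_2h = c(450, 520, 460, 390, 720, 510),
        csf_t2star_2h = c(110, 83, 76, 82, 84, 110),
        gm_t1_2h = c(280, 300, 301, 295, 420, 320),
        gm_t2star_2h = c(32, 33, 31, 32, 31, 31),
        wm_t1_2h = c(260, 280, 290, 267, 350, 277),
        wm_t2star_2h = c(30, 32, 30, 32, 28, 28),
        csf_t2star_1h = c(106, 103, 93, 87, NA, NA),
        gm_t2star_1h = c(26, 25, 22, 23, NA, NA),
        wm_t2star_1h = c(27, 23, 21, 22, NA, NA)
    )
}

#' Build a synthetic three-tissue digital brain phantom
#'
#' Constructs a nested-ellipsoid brain: a thin cortical CSF rim, a GM
#' shell, a WM core, two interior ellipsoidal "lateral ventricles" and a
#' small interior "superior cistern" blob, the last three labelled CSF.
#' Per-voxel T1/T2* are drawn from each tissue's mean/SD (truncated
#' positive); the amplitude map is the tissue water-fraction scale. A
#' smooth multiplicative flip-angle (B1) field is generated as a low-order
#' polynomial plus a Gaussian bump, clipped to [0.5, 1.5]. Fully
#' deterministic for a fixed seed.
#'
#' @param gridShape integer length-3 grid dimensions, each >= 8
#' @param tissueParams per-tissue mean/SD table as from
#'   \code{\link{defaultTissueParams}} (rows CSF, GM, WM)
#' @param b1Spec list; either \code{list(type = "constant", value = 1)} or
#'   \code{list(type = "smooth", gradient = c(gx, gy), bump = -0.08,
#'   bump_width = 0.35)} (fractions of the grid)
#' @param noiseSigma magnitude noise SD for a single-average image
#' @param noiseModel "rician" (magnitude default) or "gaussian"
#' @param seed integer seed
#' @param voxelSize voxel dimensions in mm
#' @return a \linkS4class{PhantomTruth}
#' @examples
#' ph <- buildPhantom(gridShape = c(16, 16, 12), seed = 7)
#' table(labelMap(ph))
#' @export
buildPhantom <- function(gridShape = c(24, 24, 16),
                         tissueParams = defaultTissueParams(),
                         b1Spec = list(type = "smooth"),
                         noiseSigma = 0, noiseModel = "rician",
                         seed = 1L, voxelSize = c(6, 6, 10)) {
    d <- as.integer(gridShape)
    if (length(d) != 3L || any(d < 8L))
        stop("gridShape must be three integers >= 8")
    need <- c("CSF", "GM", "WM")
    if (!all(need %in% rownames(tissueParams)))
        stop("tissueParams must have rows CSF, GM, WM")
    tp <- tissueParams[need, ]
    if (any(c(tp$t1_sd, tp$t2star_sd) < 0, na.rm = TRUE))
        stop("tissue SDs must be >= 0")

    ctr <- (d + 1) / 2
    brain <- .ellipsoid_mask(d, ctr, 0.42 * d)
    inner <- .ellipsoid_mask(d, ctr, 0.36 * d)   # inside the CSF rim
    core <- .ellipsoid_mask(d, ctr, 0.24 * d)    # WM core
    ventL <- .ellipsoid_mask(d, ctr + c(-0.11 * d[1], 0, 0),
                             c(0.08, 0.065, 0.08) * d)
    ventR <- .ellipsoid_mask(d, ctr + c(+0.11 * d[1], 0, 0),
                             c(0.08, 0.065, 0.08) * d)
    cistern <- .ellipsoid_mask(d, ctr + c(0, -0.16 * d[2], -0.05 * d[3]),
                               c(0.055, 0.045, 0.055) * d)

    lab <- array(0L, d)
    lab[brain] <- 1L                 # cortical CSF rim
    lab[inner] <- 2L                 # GM shell
    lab[core] <- 3L                  # WM core
    lab[ventL | ventR] <- 1L         # lateral ventricles (CSF)
    lab[cistern & inner] <- 1L       # superior cistern, CSF-like

    maps <- .with_seed(seed, function() {
        t1 <- array(1000, d)   # background placeholder, never observed
        t2 <- array(50, d)
        amp <- array(0, d)
        for (k in 1:3) {
            v <- which(lab == k)
            if (!length(v)) next
            m <- tp[k, ]
            t1[v] <- pmax(stats::rnorm(length(v), m$t1_mean, m$t1_sd),
                          0.2 * m$t1_mean)
            t2[v] <- pmax(stats::rnorm(length(v), m$t2star_mean, m$t2star_sd),
                          0.2 * m$t2star_mean)
            amp[v] <- m$amplitude
        }
        list(t1 = t1, t2 = t2, amp = amp)
    })

    b1 <- .make_b1_field(d, b1Spec)

    new("PhantomTruth", labelMap = lab, t1Map = maps$t1, t2starMap = maps$t2,
        amplitudeMap = maps$amp, b1Field = b1,
        voxelSize = as.numeric(voxelSize),
        noiseSigma = as.numeric(noiseSigma),
        noiseModel = noiseModel, seed = as.integer(seed))
}

.make_b1_field <- function(d, spec) {
    type <- if (is.null(spec$type)) "smooth" else spec$type
    if (type == "constant") {
        val <- if (is.null(spec$value)) 1 else spec$value
        return(array(val, d))
    }
    if (type != "smooth") stop("unknown b1Spec type: ", type)
    grad <- if (is.null(spec$gradient)) c(0.08, 0.05) else spec$gradient
    bump <- if (is.null(spec$bump)) -0.08 else spec$bump
    bw <- if (is.null(spec$bump_width)) 0.35 else spec$bump_width
    ctr <- (d + 1) / 2
    ix <- (seq_len(d[1]) - ctr[1]) / d[1]
    iy <- (seq_len(d[2]) - ctr[2]) / d[2]
    iz <- (seq_len(d[3]) - ctr[3]) / d[3]
    lin <- outer(outer(grad[1] * ix, grad[2] * iy, "+"), rep(0, d[3]), "+")
    r2 <- outer(outer(ix^2, iy^2, "+"), iz^2, "+")
    field <- 1 + lin + bump * exp(-r2 / (2 * bw^2))
    pmin(pmax(field, 0.5), 1.5)
}

#' @rdname accessors
#' @export
setMethod("labelMap", "PhantomTruth", function(x) x@labelMap)

setMethod("show", "PhantomTruth", function(object) {
    d <- dim(object@labelMap)
    n <- tabulate(object@labelMap + 1L, 4L)
    cat(sprintf("PhantomTruth: grid %s (%d background, %d CSF, %d GM, %d WM)\n",
                paste(d, collapse = "x"), n[1], n[2], n[3], n[4]))
    cat(sprintf("  noise: %s, sigma = %g; seed = %d\n",
                object@noiseModel, object@noiseSigma, object@seed))
})

#' Tissue and ROI masks of a phantom
#'
#' Derives the named binary masks used by the ROI module from a phantom's
#' label map: CSF/GM/WM, whole brain, background, the two lateral-ventricle
#' components and the cistern blob (the two interior CSF structures are
#' separated by connected-component size and position).
#'
#' @param truth a \linkS4class{PhantomTruth}
#' @return named list of binary arrays: \code{CSF}, \code{GM}, \code{WM},
#'   \code{brain}, \code{background}, \code{ventricle}, \code{cistern}
#' @export
phantomMasks <- function(truth) {
    lab <- truth@labelMap
    csf <- lab == 1L
    brain <- lab > 0L
    comp <- .label_components_3d(csf)
    ids <- sort(unique(comp[comp > 0]))
    # component touching the background is the cortical rim
    bg <- !brain
    touches_bg <- vapply(ids, function(i) {
        any(.dilate1(comp == i) & bg)
    }, logical(1))
    interior <- ids[!touches_bg]
    sizes <- vapply(interior, function(i) sum(comp == i), integer(1))
    o <- order(sizes, decreasing = TRUE)
    vent_ids <- interior[o][seq_len(min(2L, length(interior)))]
    cist_ids <- setdiff(interior, vent_ids)
    list(
        CSF = csf, GM = lab == 2L, WM = lab == 3L,
        brain = brain, background = bg,
        ventricle = array(comp %in% vent_ids, dim(lab)),
        cistern = array(comp %in% cist_ids, dim(lab))
    )
}

# 26-connectivity dilation by one voxel
.dilate1 <- function(mask) {
    out <- array(FALSE, dim(mask))
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
        out <- out | .shift3d(mask, dx, dy, dz, fill = FALSE) > 0
    out
}

#' Add magnitude-image noise to a signal grid
#'
#' Gaussian noise adds \code{N(0, sigma)} to each value; Rician noise
#' models magnitude reconstruction of complex data,
#' \code{|v + N(0, sigma) + i N(0, sigma)|}. Deterministic per seed.
#'
#' @param volume numeric array of noiseless signal
#' @param sigma noise SD (>= 0); 0 returns the input unchanged
#' @param model "gaussian" or "rician"
#' @param seed integer seed (NULL uses the current RNG stream)
#' @return noisy array of the same shape
#' @export
addNoise <- function(volume, sigma, model = c("rician", "gaussian"),
                     seed = NULL) {
    model <- match.arg(model)
    if (sigma < 0) stop("sigma must be >= 0")
    if (sigma == 0) return(volume)
    n <- length(volume)
    .with_seed(seed, function() {
        if (model == "gaussian") {
            volume + array(stats::rnorm(n, 0, sigma), dim(volume))
        } else {
            re <- volume + array(stats::rnorm(n, 0, sigma), dim(volume))
            im <- array(stats::rnorm(n, 0, sigma), dim(volume))
            sqrt(re^2 + im^2)
        }
    })
}

#' Synthesize a MEGE acquisition from phantom truth
#'
#' Evaluates the spoiled gradient-echo forward model voxel-wise with the
#' actual flip angle \code{b1Field x nominalFlip}, then adds magnitude
#' noise with SD \code{noiseSigma / sqrt(averages)} at each TR. Background
#' voxels have zero amplitude and are exactly zero before noise.
#'
#' @param truth a \linkS4class{PhantomTruth}; its grid must equal the
#'   protocol matrix
#' @param protocol a \linkS4class{MEGEProtocol}
#' @param seed noise seed (default: the phantom's seed + 1)
#' @return a \linkS4class{MEGEDataset}
#' @export
synthesizeMEGE <- function(truth, protocol, seed = truth@seed + 1L) {
    d <- dim(truth@labelMap)
    m <- matrixSize(protocol)
    if (!all(d == m))
        stop(sprintf("phantom grid %s does not match protocol matrix %s",
                     paste(d, collapse = "x"), paste(m, collapse = "x")))
    if (any(averages(protocol) < 1))
        stop("synthesis requires at least one average per TR")
    alpha <- truth@b1Field * nominalFlip(protocol) * pi / 180
    R1 <- 1000 / truth@t1Map        # 1/s
    R2 <- 1000 / truth@t2starMap
    A <- truth@amplitudeMap
    trs <- trList(protocol)
    tes <- echoTimes(protocol)
    avg <- averages(protocol)
    sig <- array(0, c(d, length(tes), length(trs)))
    sina <- sin(alpha); cosa <- cos(alpha)
    for (i in seq_along(trs)) {
        E <- exp(-R1 * trs[i] / 1000)
        sat <- A * sina * (1 - E) / (1 - cosa * E)
        for (j in seq_along(tes))
            sig[, , , j, i] <- sat * exp(-R2 * tes[j] / 1000)
    }
    if (truth@noiseSigma > 0) {
        sig <- .with_seed(seed, function() {
            for (i in seq_along(trs)) {
                s_i <- truth@noiseSigma / sqrt(avg[i])
                sig[, , , , i] <- addNoise(sig[, , , , i, drop = FALSE],
                                           s_i, truth@noiseModel, seed = NULL)
            }
            sig
        })
    }
    MEGEDataset(sig, protocol)
}

#' Noise level targeting a given summed-image SNR
#'
#' Chooses the single-average noise SD sigma so that the echo/TR-summed
#' image of the phantom has brain-tissue mean over background SD equal to
#' \code{snr}. Summing nTE echoes at each of the TRs (noise scaled by
#' 1/sqrt(averages)) gives a background SD of
#' \code{sigma * f * sqrt(sum(nTE / averages))}, where f = 1 for Gaussian
#' noise and \code{sqrt(2 - pi/2)} for Rician background (Rayleigh SD).
#'
#' For Rician noise the expected magnitude exceeds the underlying signal
#' at low per-echo SNR, so the brain mean is computed from the analytic
#' Rician mean and sigma found by root solving; for Gaussian noise the
#' closed form applies directly.
#'
#' @param truth a \linkS4class{PhantomTruth}
#' @param protocol a \linkS4class{MEGEProtocol}
#' @param snr target SNR of the TE/TR-summed image (e.g. 16)
#' @return sigma, the single-average noise SD
#' @export
sigmaForSNR <- function(truth, protocol, snr) {
    if (snr <= 0) stop("snr must be positive")
    noiseless <- buildPhantomNoiseless(truth)
    data <- synthesizeMEGE(noiseless, protocol)
    sig <- signalArray(data)
    brain <- truth@labelMap > 0L
    k <- sum(protocol@nEchoes / averages(protocol))
    summed <- sumOverEchoes(data, over = "TE_and_TR")
    sigma0 <- mean(summed[brain]) / (snr * sqrt(k))
    if (truth@noiseModel == "gaussian") return(sigma0)
    # per-(echo, TR) noiseless brain values and their noise SDs
    avg <- averages(protocol)
    nte <- protocol@nEchoes
    vals <- matrix(sig[rep(brain, nte * length(avg))],
                   ncol = nte * length(avg))
    sd_scale <- rep(1 / sqrt(avg), each = nte)
    f <- sqrt(2 - pi / 2)
    snr_of <- function(sigma) {
        mu <- 0
        for (j in seq_len(ncol(vals)))
            mu <- mu + mean(.rician_mean(vals[, j], sigma * sd_scale[j]))
        mu / (sigma * f * sqrt(k)) - snr
    }
    stats::uniroot(snr_of, c(sigma0 / 2, sigma0 * 2), tol = sigma0 * 1e-6)$root
}

# E|S + complex N(0, sigma)| for real S >= 0 (Rician mean), numerically
# stable via exponentially-scaled Bessel functions.
.rician_mean <- function(s, sigma) {
    t <- s^2 / (2 * sigma^2)
    sigma * sqrt(pi / 2) *
        ((1 + t) * besselI(t / 2, 0, expon.scaled = TRUE) +
         t * besselI(t / 2, 1, expon.scaled = TRUE))
}

# copy of a phantom with noise switched off
buildPhantomNoiseless <- function(truth) {
    out <- truth
    out@noiseSigma <- 0
    out
}

#' Synthesize a heavy-water loading enrichment time-course
#'
#' Body-water deuterium enrichment during a dosing schedule: each dose of
#' volume v ml at fraction f D2O, taken at time t_k, contributes
#' \code{100 * v * f / (TBW * 1000)} atom percent, approached with a
#' single-exponential absorption of half-life ~12 min; natural abundance
#' (0.015 atom %) is the baseline. The series is monotone non-decreasing
#' and bounded by baseline + total dose / TBW.
#'
#' @param doses data.frame with columns \code{time_min}, \code{volume_ml},
#'   \code{d2o_fraction}, sorted by time; may have zero rows
#' @param body named list: \code{sex}, \code{age} (yr), \code{height} (cm),
#'   \code{mass} (kg) — passed to \code{\link{totalBodyWater}}
#' @param sampleTimes minutes since first dose, sorted
#' @param absorptionHalfLife minutes (default 12)
#' @param baseline natural-abundance enrichment, atom % (default 0.015)
#' @param tbwMethod "watson" or "fraction"
#' @return an \linkS4class{EnrichmentSeries} (provenance "synthetic")
#' @examples
#' sched <- standardDoseSchedule(nDoses = 18)
#' body <- list(sex = "male", age = 30, height = 175, mass = 70)
#' es <- synthesizeLoadingSeries(sched, body, sampleTimes = seq(0, 540, 30))
#' @export
synthesizeLoadingSeries <- function(doses, body, sampleTimes,
                                    absorptionHalfLife = 12,
                                    baseline = 0.015,
                                    tbwMethod = "watson") {
    if (is.unsorted(sampleTimes)) stop("sampleTimes must be sorted")
    tbw <- totalBodyWater(body$sex, body$age, body$height, body$mass,
                          method = tbwMethod)
    enr <- rep(baseline, length(sampleTimes))
    if (nrow(doses)) {
        if (is.unsorted(doses$time_min)) stop("doses must be sorted by time")
        if (any(doses$volume_ml <= 0)) stop("dose volumes must be positive")
        if (any(doses$d2o_fraction <= 0 | doses$d2o_fraction > 1))
            stop("d2o_fraction must lie in (0, 1]")
        for (k in seq_len(nrow(doses))) {
            contrib <- 100 * doses$volume_ml[k] * doses$d2o_fraction[k] /
                (tbw * 1000)
            dt <- sampleTimes - doses$time_min[k]
            on <- dt >= 0
            enr[on] <- enr[on] +
                contrib * (1 - 2^(-dt[on] / absorptionHalfLife))
        }
    }
    new("EnrichmentSeries", times = as.numeric(sampleTimes),
        enrichment = enr, provenance = "synthetic")
}

#' Standard initial-loading dose schedule
#'
#' The eight-hour initial loading regime: repeated ~50 ml doses of 70%
#' D2O / 30% H2O, one every ~30 minutes.
#'
#' @param nDoses number of doses (12-16 typical; default 18 brings a 42 L
#'   body-water pool to 1.5 atom %)
#' @param volume dose volume, ml
#' @param fraction D2O fraction of the solution
#' @param interval minutes between doses
#' @return data.frame with columns \code{time_min}, \code{volume_ml},
#'   \code{d2o_fraction}
#' @export
standardDoseSchedule <- function(nDoses = 18, volume = 50, fraction = 0.7,
                                 interval = 30) {
    data.frame(time_min = (seq_len(nDoses) - 1) * interval,
               volume_ml = rep(volume, nDoses),
               d2o_fraction = rep(fraction, nDoses))
}

setMethod("show", "EnrichmentSeries", function(object) {
    cat(sprintf("EnrichmentSeries (%s): %d time points, %.4g-%.4g atom %%\n",
                object@provenance, length(object@times),
                min(object@enrichment), max(object@enrichment)))
})
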