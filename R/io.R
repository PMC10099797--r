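#' @importFrom RNifti readNifti writeNifti asNifti pixdim "pixdim<-"
#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml write_yaml
#' @importFrom utils read.csv write.csv packageVersion
NULL

.protocol_to_list <- function(p) {
    list(trList = p@trList, averages = p@averages, te1 = p@te1,
         deltaTE = p@deltaTE, nEchoes = p@nEchoes,
         nominalFlip = p@nominalFlip, fov = p@fov,
         voxelSize = p@voxelSize)
}

.protocol_from_list <- function(x) {
    MEGEProtocol(trList = unlist(x$trList), averages = unlist(x$averages),
                 te1 = x$te1, deltaTE = x$deltaTE, nEchoes = x$nEchoes,
                 nominalFlip = x$nominalFlip, fov = unlist(x$fov),
                 voxelSize = unlist(x$voxelSize))
}

#' Write a MEGE dataset to NIfTI with a protocol sidecar
#'
#' The 5-D magnitude array (x, y, z, echo, TR-index) is written as a
#' single NIfTI volume; the protocol is written next to it as a YAML
#' sidecar (same path with extension \code{.yaml}).
#'
#' @param data a \linkS4class{MEGEDataset}
#' @param path output path ending in \code{.nii} or \code{.nii.gz}
#' @return \code{path}, invisibly
#' @export
writeMEGEDataset <- function(data, path) {
    p <- protocol(data)
    img <- asNifti(signalArray(data))
    pixdim(img) <- c(p@voxelSize, 1, 1)
    writeNifti(img, path)
    write_yaml(.protocol_to_list(p), .sidecar_path(path))
    invisible(path)
}

# plain numeric array from an RNifti image (drops the niftiImage class)
.nifti_array <- function(img) {
    a <- as.array(img)
    array(as.numeric(a), dim(a))
}

.sidecar_path <- function(path) {
    sub("\\.nii(\\.gz)?$", ".yaml", path)
}

#' Read a MEGE dataset from NIfTI volumes
#'
#' Two on-disk dialects are read: a single 5-D volume (with the protocol
#' from its YAML sidecar or the \code{protocol} argument), or a manifest
#' of per-echo/per-TR 3-D volumes. Manifest assembly is label-driven —
#' rows may appear in any order — and every file's grid must match the
#' protocol matrix; a mismatching file is reported by name.
#'
#' @param x path to a 5-D NIfTI file, or a data.frame manifest with
#'   columns \code{file}, \code{echo}, \code{tr} (1-based indices into
#'   the protocol's echo and TR grids)
#' @param protocol a \linkS4class{MEGEProtocol}; optional for the
#'   single-file dialect if a sidecar is present
#' @return a \linkS4class{MEGEDataset}
#' @export
readMEGEDataset <- function(x, protocol = NULL) {
    if (is.character(x)) {
        if (is.null(protocol)) {
            sc <- .sidecar_path(x)
            if (!file.exists(sc))
                stop("no protocol given and no sidecar found at ", sc)
            protocol <- .protocol_from_list(read_yaml(sc))
        }
        arr <- .nifti_array(readNifti(x))
        if (length(dim(arr)) != 5L)
            stop("expected a 5-D volume in ", x)
        return(MEGEDataset(arr, protocol))
    }
    if (!is.data.frame(x) || !all(c("file", "echo", "tr") %in% names(x)))
        stop("manifest must be a data.frame with columns file, echo, tr")
    if (is.null(protocol)) stop("the manifest dialect requires a protocol")
    m <- matrixSize(protocol)
    nte <- protocol@nEchoes
    ntr <- length(trList(protocol))
    if (nrow(x) != nte * ntr ||
        !setequal(paste(x$echo, x$tr), paste(rep(1:nte, ntr),
                                             rep(1:ntr, each = nte))))
        stop("manifest must cover every (echo, TR) pair exactly once")
    sig <- array(NA_real_, c(m, nte, ntr))
    for (r in seq_len(nrow(x))) {
        arr <- .nifti_array(readNifti(x$file[r]))
        if (!identical(as.integer(dim(arr)[1:3]), m))
            stop(sprintf("file '%s' has grid %s, expected %s", x$file[r],
                         paste(dim(arr)[1:3], collapse = "x"),
                         paste(m, collapse = "x")))
        sig[, , , x$echo[r], x$tr[r]] <- arr
    }
    MEGEDataset(sig, protocol)
}

#' Read or write a dose schedule CSV
#'
#' Dose schedules are stored as CSV with columns \code{time_min},
#' \code{volume_ml}, \code{d2o_fraction}.
#'
#' @param path CSV path
#' @param doses data.frame to write
#' @return \code{readDoseSchedule}: the data.frame, sorted by time
#' @export
readDoseSchedule <- function(path) {
    d <- read.csv(path)
    need <- c("time_min", "volume_ml", "d2o_fraction")
    if (!all(need %in% names(d)))
        stop("dose schedule must have columns ", paste(need, collapse = ", "))
    d[order(d$time_min), need]
}

#' @rdname readDoseSchedule
#' @export
writeDoseSchedule <- function(doses, path) {
    write.csv(doses, path, row.names = FALSE)
    invisible(path)
}

#' Write fitted parameter maps and a fit report
#'
#' One NIfTI volume per populated parameter (flip angle, R1, R2*,
#' amplitude, residual RMS, QC flags, and T1/T2* in ms) plus a JSON
#' report of bounds, threshold and per-flag voxel counts.
#'
#' @param maps a \linkS4class{QuantMaps}
#' @param dir output directory (created if needed)
#' @param voxelSize voxel dimensions in mm for the NIfTI headers
#' @param extra named list merged into the JSON report
#' @return the report path, invisibly
#' @export
writeQuantMaps <- function(maps, dir, voxelSize = c(6, 6, 10),
                           extra = list()) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(arr, name) {
        img <- asNifti(arr)
        pixdim(img) <- voxelSize
        writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
    }
    wr(maps@flipAngle, "flip_angle_deg")
    wr(maps@R1, "r1_per_s")
    wr(maps@R2star, "r2star_per_s")
    wr(maps@amplitude, "amplitude")
    wr(maps@residualRMS, "residual_rms")
    wr(maps@qcFlags + 0, "qc_flags")
    times <- ratesToTimes(maps)
    wr(times$T1, "t1_ms")
    wr(times$T2star, "t2star_ms")
    counts <- as.list(tabulate(maps@qcFlags + 1L, 4L))
    names(counts) <- c("fitted", "skipped_low_signal", "bound_hit",
                       "non_converged")
    report <- c(list(bounds = list(R1_per_s = .R1_BOUNDS,
                                   R2star_per_s = .R2_BOUNDS,
                                   flip_deg = .FLIP_BOUNDS),
                     qc_counts = counts), extra)
    rp <- file.path(dir, "fit_report.json")
    write_json(report, rp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(rp)
}

.config_hash <- function(config) {
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(config, tf, compress = FALSE)
    unname(tools::md5sum(tf))
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML file) with components
#' \code{input} (either \code{type = "phantom"} with \code{gridShape},
#' \code{snr}, \code{noiseModel}, or \code{type = "nifti"} with
#' \code{path} and named mask paths), an optional \code{protocol} list,
#' \code{fit} options (\code{signalThreshold}), \code{roi} options
#' (\code{rounding}) and a \code{seed}. Every stochastic stage receives
#' an explicit seed derived from it.
#'
#' @param config named list or path to a YAML file
#' @return the validated config list (with defaults filled in)
#' @export
validateRunConfig <- function(config) {
    if (is.character(config)) config <- read_yaml(config)
    if (is.null(config$input) || is.null(config$input$type))
        stop("config$input$type is required ('phantom' or 'nifti')")
    if (!config$input$type %in% c("phantom", "nifti"))
        stop("unknown input type: ", config$input$type)
    if (config$input$type == "nifti" && is.null(config$input$path))
        stop("config$input$path is required for NIfTI input")
    if (is.null(config$seed)) stop("config$seed is required")
    if (is.null(config$fit)) config$fit <- list()
    if (is.null(config$fit$signalThreshold)) config$fit$signalThreshold <- 0.05
    if (is.null(config$roi)) config$roi <- list()
    if (is.null(config$roi$rounding)) config$roi$rounding <- "none"
    if (config$input$type == "phantom") {
        if (is.null(config$input$gridShape)) config$input$gridShape <- c(24, 24, 16)
        if (is.null(config$input$snr)) config$input$snr <- 16
        if (is.null(config$input$noiseModel)) config$input$noiseModel <- "gaussian"
    }
    config
}

#' Run the full relaxometry pipeline
#'
#' Chains the analysis stages: flip-angle map fit on TE-summed data,
#' 5x5x5 smoothing, dual R1/R2* fit with fixed flip angles, conversion
#' to relaxation times, and tissue ROI statistics. Writes the parameter
#' maps, a \code{roi_summary.csv} and a JSON run log (config hash, seed,
#' stage decisions, QC counts) into \code{outputDir}. Deterministic for
#' fixed inputs and seed.
#'
#' @param config run configuration (list or YAML path); see
#'   \code{\link{validateRunConfig}}
#' @param outputDir output directory
#' @return invisibly, a list with the ROI summary data.frame, the
#'   \linkS4class{QuantMaps}, and the log list
#' @export
runPipeline <- function(config, outputDir) {
    config <- validateRunConfig(config)
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    log <- list(package = "DeutRelax",
                version = as.character(packageVersion("DeutRelax")),
                config_hash = .config_hash(config),
                seed = config$seed, stages = list())
    stage <- function(name, f) {
        res <- tryCatch(f(), error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
        log$stages[[name]] <<- res$log
        res$value
    }

    inp <- stage("input", function() {
        if (config$input$type == "phantom") {
            proto <- if (is.null(config$protocol)) {
                gs <- unlist(config$input$gridShape)
                relaxometryProtocol(fov = gs * c(6, 6, 10),
                                    voxelSize = c(6, 6, 10))
            } else .protocol_from_list(config$protocol)
            truth <- buildPhantom(gridShape = unlist(config$input$gridShape),
                                  noiseModel = config$input$noiseModel,
                                  seed = config$seed,
                                  voxelSize = proto@voxelSize)
            truth@noiseSigma <- sigmaForSNR(truth, proto, config$input$snr)
            data <- synthesizeMEGE(truth, proto, seed = config$seed + 1L)
            masks <- phantomMasks(truth)
            list(value = list(data = data, masks = masks),
                 log = list(type = "phantom", snr = config$input$snr,
                            sigma = truth@noiseSigma,
                            noise = config$input$noiseModel))
        } else {
            proto <- if (is.null(config$protocol)) NULL
                     else .protocol_from_list(config$protocol)
            data <- readMEGEDataset(config$input$path, proto)
            masks <- lapply(config$input$masks, function(pth)
                .nifti_array(readNifti(pth)) > 0)
            list(value = list(data = data, masks = masks),
                 log = list(type = "nifti", path = config$input$path))
        }
    })

    thr <- config$fit$signalThreshold
    b1 <- stage("fit_flip_angle", function() {
        m <- fitFlipAngleMap(inp$data, signalThreshold = thr)
        list(value = m, log = list(threshold = thr,
             qc_counts = as.list(tabulate(m@qcFlags + 1L, 4L))))
    })
    alpha_s <- stage("smooth_flip_angle", function()
        list(value = smoothFlipAngleMap(b1@flipAngle, b1@qcFlags),
             log = list(kernel = "5x5x5 valid-neighbour mean")))
    maps <- stage("fit_relaxation", function() {
        m <- fitRelaxationMaps(inp$data, alpha_s, signalThreshold = thr,
                               r1Init = b1@R1)
        list(value = m, log = list(
             qc_counts = as.list(tabulate(m@qcFlags + 1L, 4L))))
    })
    times <- ratesToTimes(maps)
    summary_df <- stage("roi_statistics", function() {
        keep <- intersect(c("CSF", "GM", "WM"), names(inp$masks))
        t1 <- roiStatistics(times$T1, inp$masks[keep], qc = maps@qcFlags,
                            rounding = config$roi$rounding)
        t2 <- roiStatistics(times$T2star, inp$masks[keep],
                            qc = maps@qcFlags,
                            rounding = config$roi$rounding)
        t1$metric <- "T1_ms"; t2$metric <- "T2star_ms"
        list(value = rbind(t1, t2), log = list(rois = keep))
    })

    voxels <- protocol(inp$data)@voxelSize
    writeQuantMaps(maps, outputDir, voxelSize = voxels,
                   extra = list(config_hash = log$config_hash))
    write.csv(summary_df, file.path(outputDir, "roi_summary.csv"),
              row.names = FALSE)
    log$timestamp <- format(Sys.time(), tz = "UTC")
    write_json(log, file.path(outputDir, "run_log.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(summary = summary_df, maps = maps, log = log))
}
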