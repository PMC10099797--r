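#' Construct a MEGE acquisition protocol
#'
#' @param trList repetition times in ms, strictly increasing
#' @param te1 first echo time, ms
#' @param deltaTE echo spacing, ms
#' @param nEchoes number of echoes
#' @param nominalFlip nominal flip angle, degrees
#' @param fov field of view, mm (length 3)
#' @param voxelSize voxel size, mm (length 3); FOV must divide exactly
#' @param averages signal averages per TR (default 1 each)
#' @return a \linkS4class{MEGEProtocol}
#' @examples
#' MEGEProtocol(trList = c(68, 136, 272, 544, 816),
#'              averages = c(8, 4, 2, 1, 1),
#'              te1 = 4.3, deltaTE = 8.4, nEchoes = 6, nominalFlip = 60,
#'              fov = c(288, 288, 240), voxelSize = c(6, 6, 10))
#' @export
MEGEProtocol <- function(trList, te1, deltaTE, nEchoes, nominalFlip,
                         fov, voxelSize, averages = rep(1, length(trList))) {
    new("MEGEProtocol", trList = as.numeric(trList),
        averages = as.numeric(averages), te1 = as.numeric(te1),
        deltaTE = as.numeric(deltaTE), nEchoes = as.integer(nEchoes),
        nominalFlip = as.numeric(nominalFlip), fov = as.numeric(fov),
        voxelSize = as.numeric(voxelSize))
}

#' @rdname accessors
#' @export
setMethod("trList", "MEGEProtocol", function(x) x@trList)

#' @rdname accessors
#' @export
setMethod("averages", "MEGEProtocol", function(x) x@averages)

#' @rdname accessors
#' @export
setMethod("echoTimes", "MEGEProtocol",
          function(x) x@te1 + (seq_len(x@nEchoes) - 1) * x@deltaTE)

#' @rdname accessors
#' @export
setMethod("matrixSize", "MEGEProtocol",
          function(x) as.integer(round(x@fov / x@voxelSize)))

#' @rdname accessors
#' @export
setMethod("nominalFlip", "MEGEProtocol", function(x) x@nominalFlip)

#' Voxel volume of a protocol
#'
#' @param protocol a \linkS4class{MEGEProtocol}
#' @return voxel volume in ml (1 ml = 1000 mm^3)
#' @examples
#' p <- relaxometryProtocol()
#' voxelVolume(p)  # 6 x 6 x 10 mm^3 = 0.36 ml
#' @export
voxelVolume <- function(protocol) prod(protocol@voxelSize) / 1000

setMethod("show", "MEGEProtocol", function(object) {
    m <- matrixSize(object)
    cat("MEGEProtocol\n")
    cat(sprintf("  TR (ms): %s  [averages %s]\n",
                paste(object@trList, collapse = ", "),
                paste(object@averages, collapse = ", ")))
    cat(sprintf("  TE (ms): %s\n",
                paste(format(echoTimes(object)), collapse = ", ")))
    cat(sprintf("  flip %g deg; FOV %s mm; voxel %s mm; matrix %s\n",
                object@nominalFlip, paste(object@fov, collapse = "x"),
                paste(object@voxelSize, collapse = "x"),
                paste(m, collapse = "x")))
})

#' Standard 7T deuterium protocols
#'
#' \code{relaxometryProtocol} is the steady-state multi-TR scheme used for
#' T1/T2* mapping (TR = 68/136/272/544/816 ms with 8/4/2/1/1 averages,
#' six echoes, TE1 = 4.3 ms, dTE = 8.4 ms, 60 deg flip).
#' \code{loadingProtocol} is the single-TR scheme used to follow signal
#' during heavy-water loading (TR = 62 ms, 20 averages, five echoes,
#' TE1 = 8.9 ms, 33 deg flip). Geometry defaults to the acquired FOV and
#' 6 x 6 x 10 mm voxels but can be overridden (e.g. for a small phantom
#' grid).
#'
#' @param fov field of view, mm
#' @param voxelSize voxel size, mm
#' @param nEchoes number of echoes (relaxometry default 6)
#' @return a \linkS4class{MEGEProtocol}
#' @export
relaxometryProtocol <- function(fov = c(288, 288, 240),
                                voxelSize = c(6, 6, 10), nEchoes = 6) {
    MEGEProtocol(trList = c(68, 136, 272, 544, 816),
                 averages = c(8, 4, 2, 1, 1),
                 te1 = 4.3, deltaTE = 8.4, nEchoes = nEchoes,
                 nominalFlip = 60, fov = fov, voxelSize = voxelSize)
}

#' @rdname relaxometryProtocol
#' @export
loadingProtocol <- function(fov = c(288, 288, 80),
                            voxelSize = c(6, 6, 10)) {
    MEGEProtocol(trList = 62, averages = 20, te1 = 8.9, deltaTE = 8.4,
                 nEchoes = 5, nominalFlip = 33, fov = fov,
                 voxelSize = voxelSize)
}

#' Extend a protocol with additional TR measurements
#'
#' Appends TR values (with their averages) to a scheme, keeping the echo
#' structure; used for protocol-precision comparisons such as adding a
#' TR = 1500 ms measurement.
#'
#' @param protocol base \linkS4class{MEGEProtocol}
#' @param tr TR values to add, ms
#' @param averages averages for each added TR
#' @return the extended \linkS4class{MEGEProtocol}
#' @export
extendProtocol <- function(protocol, tr, averages = rep(1, length(tr))) {
    trs <- c(protocol@trList, tr)
    avg <- c(protocol@averages, averages)
    o <- order(trs)
    MEGEProtocol(trList = trs[o], averages = avg[o], te1 = protocol@te1,
                 deltaTE = protocol@deltaTE, nEchoes = protocol@nEchoes,
                 nominalFlip = protocol@nominalFlip, fov = protocol@fov,
                 voxelSize = protocol@voxelSize)
}

#' Construct a MEGE dataset from an array and protocol
#'
#' @param signal 5-D magnitude array (x, y, z, echo, TR-index)
#' @param protocol the matching \linkS4class{MEGEProtocol}
#' @return a \linkS4class{MEGEDataset}
#' @export
MEGEDataset <- function(signal, protocol) {
    new("MEGEDataset", signal = signal, protocol = protocol)
}

#' @rdname accessors
#' @export
setMethod("signalArray", "MEGEDataset", function(x) x@signal)

#' Protocol of a dataset
#' @param x a \linkS4class{MEGEDataset}
#' @return the \linkS4class{MEGEProtocol}
#' @export
protocol <- function(x) x@protocol

setMethod("show", "MEGEDataset", function(object) {
    d <- dim(object@signal)
    cat(sprintf("MEGEDataset: %s voxels, %d echoes, %d TRs\n",
                paste(d[1:3], collapse = "x"), d[4], d[5]))
    show(object@protocol)
})
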