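# Shared fixtures: small phantoms and grid-matched protocols. Heavy
# objects are cached so several test files can reuse one fit.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
    if (!exists(key, envir = .fixture_cache))
        assign(key, builder(), envir = .fixture_cache)
    get(key, envir = .fixture_cache)
}

relax_proto_for <- function(gridShape)
    relaxometryProtocol(fov = gridShape * c(6, 6, 10))

loading_proto_for <- function(gridShape)
    loadingProtocol(fov = gridShape * c(6, 6, 10))

# noiseless phantom + two-stage fit (exact-recovery fixture)
noiseless_fit_fixture <- function() {
    .cached("noiseless_fit", function() {
        gs <- c(16, 16, 12)
        truth <- buildPhantom(gridShape = gs, seed = 11,
                              noiseModel = "gaussian")
        proto <- relax_proto_for(gs)
        data <- synthesizeMEGE(truth, proto)
        b1 <- fitFlipAngleMap(data)
        maps <- fitRelaxationMaps(data, b1@flipAngle, r1Init = b1@R1)
        list(truth = truth, proto = proto, data = data, b1 = b1,
             maps = maps, masks = phantomMasks(truth))
    })
}

# SNR-16 phantom (noise calibrated on the echo-summed loading acquisition,
# where the study's SNR figure is defined) + full pipeline fit
snr16_fit_fixture <- function() {
    .cached("snr16_fit", function() {
        gs <- c(24, 24, 16)
        truth <- buildPhantom(gridShape = gs, seed = 5,
                              noiseModel = "gaussian")
        truth@noiseSigma <- sigmaForSNR(truth, loading_proto_for(gs), 16)
        proto <- relax_proto_for(gs)
        data <- synthesizeMEGE(truth, proto, seed = 6L)
        b1 <- fitFlipAngleMap(data)
        alpha <- smoothFlipAngleMap(b1@flipAngle, b1@qcFlags)
        maps <- fitRelaxationMaps(data, alpha, r1Init = b1@R1)
        list(truth = truth, proto = proto, data = data, b1 = b1,
             alpha = alpha, maps = maps, masks = phantomMasks(truth))
    })
}

default_body <- function() list(sex = "male", age = 30, height = 175,
                                mass = 70)
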