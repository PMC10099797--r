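test_that("phantom generation is deterministic and respects tissue means", {
    a <- buildPhantom(gridShape = c(12, 12, 10), seed = 3)
    b <- buildPhantom(gridShape = c(12, 12, 10), seed = 3)
    expect_identical(a@t1Map, b@t1Map)
    expect_identical(a@labelMap, b@labelMap)

    # zero SDs and a constant unit B1 give piecewise-constant truth at the
    # 7T reference means (CSF 510, GM 320, WM 290 ms)
    tp <- defaultTissueParams()
    tp$t1_sd <- 0; tp$t2star_sd <- 0
    ph <- buildPhantom(gridShape = c(12, 12, 10), tissueParams = tp,
                       b1Spec = list(type = "constant", value = 1), seed = 1)
    expect_true(all(ph@b1Field == 1))
    for (k in 1:3) {
        v <- ph@labelMap == k
        expect_equal(unique(ph@t1Map[v]), c(510, 320, 290)[k])
        expect_equal(unique(ph@t2starMap[v]), c(90, 32, 30)[k])
        expect_equal(unique(ph@amplitudeMap[v]), c(1.0, 0.8, 0.7)[k])
    }
})

test_that("phantom geometry provides all named ROI masks", {
    ph <- buildPhantom(gridShape = c(16, 16, 12), seed = 7)
    mk <- phantomMasks(ph)
    expect_setequal(names(mk), c("CSF", "GM", "WM", "brain", "background",
                                 "ventricle", "cistern"))
    # tissue masks partition the brain
    expect_false(any(mk$CSF & mk$GM) || any(mk$CSF & mk$WM) ||
                 any(mk$GM & mk$WM))
    expect_true(all((mk$CSF | mk$GM | mk$WM) == mk$brain))
    expect_false(any(mk$brain & mk$background))
    # ventricles and cistern are interior CSF structures
    expect_true(all(mk$ventricle <= mk$CSF))
    expect_true(all(mk$cistern <= mk$CSF))
    expect_gt(sum(mk$ventricle), 0)
    expect_gt(sum(mk$cistern), 0)
    expect_gt(sum(mk$ventricle), sum(mk$cistern))
    expect_true(all(ph@b1Field >= 0.5 & ph@b1Field <= 1.5))
})

test_that("invalid phantom specifications are rejected", {
    expect_error(buildPhantom(gridShape = c(4, 4, 4)), ">= 8")
    tp <- defaultTissueParams(); tp$t1_sd[1] <- -1
    expect_error(buildPhantom(tissueParams = tp), "SD")
    tp <- defaultTissueParams()[c("GM", "WM"), ]
    expect_error(buildPhantom(tissueParams = tp), "CSF")
})

test_that("noiseless synthesis equals the forward model voxel-wise", {
    gs <- c(12, 12, 10)
    ph <- buildPhantom(gridShape = gs, seed = 9)
    proto <- relax_proto_for(gs)
    d <- synthesizeMEGE(ph, proto)
    sig <- signalArray(d)
    # background is exactly zero
    bg <- which(ph@labelMap == 0L)
    expect_true(all(sig[bg] == 0))
    # spot-check tissue voxels against spgrSignal
    set.seed(1)
    for (v in sample(which(ph@labelMap > 0L), 10)) {
        idx <- arrayInd(v, gs)
        expected <- spgrSignal(ph@amplitudeMap[v], ph@b1Field[v] * 60,
                               1000 / ph@t1Map[v], 1000 / ph@t2starMap[v],
                               TR = trList(proto), TE = echoTimes(proto))
        expect_equal(sig[idx[1], idx[2], idx[3], , ], t(expected),
                     tolerance = 1e-12)
    }
    # a CSF voxel's signal increases down the TR axis, decreases along TE
    v <- which(ph@labelMap == 1L)[1]
    idx <- arrayInd(v, gs)
    s <- sig[idx[1], idx[2], idx[3], , ]
    expect_true(all(apply(s, 1, diff) > 0))   # over TR at each echo
    expect_true(all(apply(s, 2, diff) < 0))   # over TE at each TR
    expect_error(synthesizeMEGE(ph, relax_proto_for(c(16, 16, 12))),
                 "does not match")
})

test_that("magnitude noise model behaves as specified", {
    x <- array(runif(64), c(4, 4, 4))
    expect_identical(addNoise(x, 0, "rician", seed = 1), x)
    # Rician noise on a zero signal is Rayleigh with mean sigma*sqrt(pi/2)
    z <- addNoise(array(0, c(50, 50, 40)), 2, "rician", seed = 4)
    expect_equal(mean(z), 2 * sqrt(pi / 2), tolerance = 0.02)
    # Gaussian noise is unbiased
    g <- addNoise(array(16, c(50, 50, 40)), 1, "gaussian", seed = 5)
    expect_equal(mean(g), 16, tolerance = 0.002)
    # deterministic per seed
    expect_identical(addNoise(x, 1, "rician", seed = 9),
                     addNoise(x, 1, "rician", seed = 9))
    expect_error(addNoise(x, -1, "gaussian"), "sigma")
})

test_that("noise calibration hits the target summed-image SNR", {
    gs <- c(16, 16, 12)
    for (model in c("rician", "gaussian")) {
        ph <- buildPhantom(gridShape = gs, seed = 2, noiseModel = model)
        lp <- loading_proto_for(gs)
        ph@noiseSigma <- sigmaForSNR(ph, lp, 16)
        d <- synthesizeMEGE(ph, lp, seed = 8)
        mk <- phantomMasks(ph)
        snr <- estimateSNR(sumOverEchoes(d, "TE_and_TR"), mk$brain,
                           mk$background)
        expect_equal(snr, 16, tolerance = 0.10)
    }
})

test_that("loading series follows dose kinetics with a 12-min half-life", {
    body <- default_body()
    tbw <- totalBodyWater(body$sex, body$age, body$height, body$mass)
    # no doses: flat natural abundance
    empty <- standardDoseSchedule(nDoses = 0)
    es0 <- synthesizeLoadingSeries(empty[0, ], body, sampleTimes = c(0, 100))
    expect_equal(es0@enrichment, c(0.015, 0.015))
    # 18 x 50 ml of 70% solution approaches baseline + 1.5 % (42 L TBW)
    sched <- standardDoseSchedule(nDoses = 18)
    es <- synthesizeLoadingSeries(sched, body,
                                  sampleTimes = c(seq(0, 540, 30), 1e5))
    expect_equal(tail(es@enrichment, 1), 0.015 + 100 * 630 / (tbw * 1000),
                 tolerance = 1e-6)
    expect_equal(tail(es@enrichment, 1), 1.515, tolerance = 0.01)
    # monotone non-decreasing, bounded by baseline + total dose / TBW
    expect_true(all(diff(es@enrichment) >= 0))
    expect_true(all(es@enrichment <= 0.015 + 100 * 630 / (tbw * 1000) + 1e-9))
    # one half-life after a single dose: half the asymptotic contribution
    one <- data.frame(time_min = 0, volume_ml = 50, d2o_fraction = 0.7)
    es1 <- synthesizeLoadingSeries(one, body, sampleTimes = c(12, 1e5))
    contrib <- 100 * 35 / (tbw * 1000)
    expect_equal(es1@enrichment[1] - 0.015, contrib / 2, tolerance = 1e-9)
})
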