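test_that("noiseless data are inverted exactly by both fitting stages", {
    fx <- noiseless_fit_fixture()
    truth <- fx$truth
    b1 <- fx$b1
    fitted <- b1@qcFlags == 0L
    expect_gt(sum(fitted), 500)
    ta <- truth@b1Field * 60
    expect_lt(max(abs(b1@flipAngle[fitted] - ta[fitted]) / ta[fitted]), 1e-3)
    tr1 <- 1000 / truth@t1Map
    expect_lt(max(abs(b1@R1[fitted] - tr1[fitted]) / tr1[fitted]), 1e-3)
    maps <- fx$maps
    ok <- maps@qcFlags == 0L
    tt <- ratesToTimes(maps)
    expect_lt(max(abs(tt$T1[ok] - truth@t1Map[ok]) / truth@t1Map[ok]), 1e-3)
    expect_lt(max(abs(tt$T2star[ok] - truth@t2starMap[ok]) /
                  truth@t2starMap[ok]), 1e-3)
})

test_that("every voxel is exactly one of fitted or flagged", {
    fx <- noiseless_fit_fixture()
    for (m in list(fx$b1, fx$maps)) {
        expect_true(all(m@qcFlags %in% 0:3))
        has_value <- as.vector(!is.na(m@amplitude))
        expect_identical(has_value, as.vector(m@qcFlags %in% c(0L, 2L)))
    }
})

test_that("signal constant across TR is flagged as a bound hit", {
    gs <- c(8, 8, 8)
    proto <- relax_proto_for(gs)
    sig <- array(1, c(gs, proto@nEchoes, length(trList(proto))))
    d <- MEGEDataset(sig, proto)
    b1 <- fitFlipAngleMap(d)
    expect_true(all(b1@qcFlags == 2L))
    # fully relaxed at every TR drives R1 to its upper information limit
    expect_true(all(abs(b1@R1[!is.na(b1@R1)] - 20) < 1e-3))
})

test_that("flip-angle fitting requires at least three TRs", {
    gs <- c(8, 8, 8)
    proto <- MEGEProtocol(trList = c(100, 300), te1 = 4.3, deltaTE = 8.4,
                          nEchoes = 3, nominalFlip = 60,
                          fov = gs * c(6, 6, 10), voxelSize = c(6, 6, 10))
    d <- MEGEDataset(array(1, c(gs, 3, 2)), proto)
    expect_error(fitFlipAngleMap(d), "3 TR")
})

test_that("fit is invariant to the ordering of TR measurements", {
    trs <- c(68, 136, 272, 544, 816)
    w <- sqrt(c(8, 4, 2, 1, 1))
    y <- satrecSignal(2.4, 55, 1000 / 320, trs) +
        c(0.01, -0.02, 0.015, -0.01, 0.02)
    perm <- c(4, 1, 5, 3, 2)
    a <- DeutRelax:::.fit_satrec_voxel(y, trs, 60, weights = w)
    b <- DeutRelax:::.fit_satrec_voxel(y[perm], trs[perm], 60,
                                       weights = w[perm])
    expect_equal(a$flip, b$flip, tolerance = 1e-6)
    expect_equal(a$R1, b$R1, tolerance = 1e-6)
    tes <- c(4.3, 12.7, 21.1)
    grid <- spgrSignal(1, 55, 1000 / 320, 1000 / 32, TR = trs, TE = tes)
    yg <- as.vector(t(grid)) + 0.002 * sin(seq_len(15))
    f1 <- DeutRelax:::.fit_relax_voxel(yg, trs, tes, 55, 3)
    # permute columns (TRs) of the echo x TR matrix with matched data
    ym <- matrix(yg, nrow = 3)
    f2 <- DeutRelax:::.fit_relax_voxel(as.vector(ym[, perm]), trs[perm],
                                       tes, 55, 3)
    expect_equal(f1$R1, f2$R1, tolerance = 1e-6)
    expect_equal(f1$R2star, f2$R2star, tolerance = 1e-6)
})

test_that("flip-angle smoothing is a valid-neighbour boxcar mean", {
    # uniform map is unchanged
    u <- array(7, c(8, 8, 8))
    expect_equal(smoothFlipAngleMap(u), u)
    # interior impulse spreads v/125 to every voxel within the window
    z <- array(0, c(9, 9, 9))
    z[5, 5, 5] <- 125
    s <- smoothFlipAngleMap(z)
    expect_equal(s[5, 5, 5], 1)
    expect_equal(s[3, 3, 3], 1)   # window just reaches the impulse
    expect_equal(s[7, 5, 5], 1)
    expect_equal(s[2, 5, 5], 0)   # outside the 5x5x5 reach
    # corner voxel averages over its 27 in-volume neighbours
    r <- array(seq_len(9^3), c(9, 9, 9))
    sc <- smoothFlipAngleMap(r)
    expect_equal(sc[1, 1, 1], mean(r[1:3, 1:3, 1:3]))
    # voxels with no valid neighbour stay NA
    nav <- array(NA_real_, c(8, 8, 8)); nav[1, 1, 1] <- 5
    sn <- smoothFlipAngleMap(nav)
    expect_equal(sn[1, 1, 1], 5)
    expect_true(is.na(sn[8, 8, 8]))
})

test_that("dual fit validates its inputs", {
    fx <- noiseless_fit_fixture()
    alpha <- fx$b1@flipAngle
    bad <- alpha; bad[which(fx$b1@qcFlags == 0L)[1]] <- NA
    expect_error(fitRelaxationMaps(fx$data, bad), "missing")
    gs <- c(8, 8, 8)
    proto1 <- MEGEProtocol(trList = 100, te1 = 4.3, deltaTE = 8.4,
                           nEchoes = 1, nominalFlip = 90,
                           fov = gs * c(6, 6, 10), voxelSize = c(6, 6, 10))
    d1 <- MEGEDataset(array(1, c(gs, 1, 1)), proto1)
    expect_error(fitRelaxationMaps(d1, array(90, gs)), ">= 2")
})

test_that("mono-exponential T2* fitting recovers decays exactly", {
    gs <- c(8, 8, 8)
    # 15-echo proton protocol, TE1 = 2.5 ms, dTE = 2.57 ms
    proto <- MEGEProtocol(trList = 41, te1 = 2.5, deltaTE = 2.57,
                          nEchoes = 15, nominalFlip = 15,
                          fov = gs * c(6, 6, 10), voxelSize = c(6, 6, 10))
    tes <- echoTimes(proto)
    sig <- array(0, c(gs, 15, 1))
    decay <- 2 * exp(-tes / 24)
    for (j in 1:15) sig[, , , j, 1] <- decay[j]
    d <- MEGEDataset(sig, proto)
    maps <- fitT2starMonoexp(d)
    r2 <- maps@R2star[!is.na(maps@R2star)]
    expect_lt(max(abs(1000 / r2 - 24) / 24), 1e-4)
    # two points determine T2* exactly: S(2.5) and S(26.5), ratio e^-1
    proto2 <- MEGEProtocol(trList = 41, te1 = 2.5, deltaTE = 24,
                           nEchoes = 2, nominalFlip = 15,
                           fov = gs * c(6, 6, 10), voxelSize = c(6, 6, 10))
    sig2 <- array(0, c(gs, 2, 1))
    sig2[, , , 1, 1] <- 100 * exp(-2.5 / 24)
    sig2[, , , 2, 1] <- 100 * exp(-26.5 / 24)
    m2 <- fitT2starMonoexp(MEGEDataset(sig2, proto2))
    expect_equal(unique(round(1000 / m2@R2star[!is.na(m2@R2star)], 6)), 24)
    # constant signal drives R2* to the lower bound with flag 2
    sig3 <- array(0, c(gs, 2, 1)); sig3[, , , , 1] <- 5
    m3 <- fitT2starMonoexp(MEGEDataset(sig3, proto2))
    expect_true(all(m3@qcFlags == 2L))
    expect_error(fitT2starMonoexp(d1 <- MEGEDataset(
        array(1, c(gs, 1, 1)),
        MEGEProtocol(trList = 41, te1 = 2.5, deltaTE = 2.6, nEchoes = 1,
                     nominalFlip = 15, fov = gs * c(6, 6, 10),
                     voxelSize = c(6, 6, 10)))), "2 echoes")
})
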