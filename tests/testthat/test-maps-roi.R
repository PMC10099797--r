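test_that("echo summation is the identity for one echo and is linear", {
    gs <- c(8, 8, 8)
    proto <- MEGEProtocol(trList = c(100, 200, 400), te1 = 5, deltaTE = 5,
                          nEchoes = 1, nominalFlip = 60,
                          fov = gs * c(6, 6, 10), voxelSize = c(6, 6, 10))
    sig <- array(runif(prod(gs) * 3), c(gs, 1, 3))
    d <- MEGEDataset(sig, proto)
    expect_equal(sumOverEchoes(d, "TE"), sig[, , , 1, ])
    d2 <- MEGEDataset(3 * sig, proto)
    expect_equal(sumOverEchoes(d2, "TE_and_TR"),
                 3 * sumOverEchoes(d, "TE_and_TR"))
})

test_that("TE-summed CSF signal increases with TR in noiseless data", {
    fx <- noiseless_fit_fixture()
    summed <- sumOverEchoes(fx$data, "TE")
    v <- which(fx$truth@labelMap == 1L)[1]
    idx <- arrayInd(v, dim(fx$truth@labelMap))
    expect_true(all(diff(summed[idx[1], idx[2], idx[3], ]) > 0))
})

test_that("affine resampling honours the voxel-to-world convention", {
    x <- array(runif(6 * 5 * 4), c(6, 5, 4))
    I4 <- diag(4)
    expect_equal(resampleToGrid(x, I4, I4, dim(x), "nearest"), x)
    expect_equal(resampleToGrid(x, I4, I4, dim(x), "trilinear"), x,
                 tolerance = 1e-12)
    # integer translation of a binary mask preserves interior counts
    m <- array(0, c(10, 10, 6)); m[4:6, 4:6, 3:4] <- 1
    tr <- diag(4); tr[1, 4] <- 2   # target voxel i samples source i+2
    shifted <- resampleToGrid(m, I4, tr, dim(m), "nearest")
    expect_equal(sum(shifted), sum(m))
    expect_equal(shifted[2:4, 4:6, 3:4], m[4:6, 4:6, 3:4])
    # 2x nearest-neighbour downsampling of an all-ones mask stays all ones
    ones <- array(1, c(8, 8, 8))
    dst <- diag(c(2, 2, 2, 1))
    down <- resampleToGrid(ones, I4, dst, c(4, 4, 4), "nearest")
    expect_true(all(down == 1))
    # binary in, binary out under nearest
    rb <- resampleToGrid(m, I4, diag(c(1.7, 1.3, 1.1, 1)), c(6, 8, 5),
                         "nearest")
    expect_true(all(rb %in% c(0, 1)))
    expect_error(resampleToGrid(x, matrix(0, 4, 4), I4, dim(x)),
                 "invertible")
})

test_that("CSF mask refinement keeps the largest interior components", {
    blob <- array(0, c(12, 12, 8)); blob[3:6, 3:6, 3:5] <- 1
    expect_equal(refineCSFMask(blob, k = 1), blob == 1)
    two <- blob; two[9:10, 9:10, 3] <- 1   # small second blob
    expect_equal(refineCSFMask(two, k = 1), blob == 1)
    expect_equal(refineCSFMask(two, k = 2), two == 1)
    expect_warning(out <- refineCSFMask(array(0, c(4, 4, 4))), "empty")
    expect_false(any(out))
    # phantom: cortical rim + 2 ventricles + cistern; pruning against the
    # background leaves exactly the two ventricles
    ph <- buildPhantom(gridShape = c(16, 16, 12), seed = 7)
    mk <- phantomMasks(ph)
    kept <- refineCSFMask(mk$CSF, k = 2, exterior = mk$background)
    expect_equal(kept, mk$ventricle)
})

test_that("ROI statistics reproduce the printed per-visit summary row", {
    v <- visitRelaxationTimes()
    d2 <- roiStatistics(list(csf_t1 = v$csf_t1_2h, csf_t2 = v$csf_t2star_2h,
                             gm_t1 = v$gm_t1_2h, gm_t2 = v$gm_t2star_2h,
                             wm_t1 = v$wm_t1_2h, wm_t2 = v$wm_t2star_2h),
                        rounding = "table1", nucleus = "2H")
    expect_equal(d2$mean, c(510, 90, 320, 32, 290, 30))
    h1 <- roiStatistics(list(csf = v$csf_t2star_1h, gm = v$gm_t2star_1h,
                             wm = v$wm_t2star_1h),
                        rounding = "table1", nucleus = "1H")
    expect_equal(h1$mean, c(97, 24, 23))
})

test_that("ROI statistics over a union equal the pooled combination", {
    set.seed(4)
    x <- array(rnorm(10^3, 300, 40), c(10, 10, 10))
    m1 <- array(FALSE, dim(x)); m1[1:4, , ] <- TRUE
    m2 <- array(FALSE, dim(x)); m2[7:10, , ] <- TRUE
    s <- roiStatistics(x, list(a = m1, b = m2, u = m1 | m2))
    n1 <- s$n[1]; n2 <- s$n[2]
    M <- (n1 * s$mean[1] + n2 * s$mean[2]) / (n1 + n2)
    expect_equal(s$mean[3], M)
    pooled <- sqrt(((n1 - 1) * s$sd[1]^2 + (n2 - 1) * s$sd[2]^2 +
                    n1 * (s$mean[1] - M)^2 + n2 * (s$mean[2] - M)^2) /
                   (n1 + n2 - 1))
    expect_equal(s$sd[3], pooled)
    # constant map: SD 0; flagged voxels are excluded; empty mask errors
    cx <- array(5, c(6, 6, 6))
    qc <- array(0L, dim(cx)); qc[1, 1, 1] <- 1L
    sc <- roiStatistics(cx, list(all = array(TRUE, dim(cx))), qc = qc)
    expect_equal(sc$mean, 5); expect_equal(sc$sd, 0)
    expect_equal(sc$n, 6^3 - 1L)
    expect_error(roiStatistics(cx, list(none = array(FALSE, dim(cx)))),
                 "empty")
})

test_that("SNR estimate is mean over background SD, scale invariant", {
    img <- array(0, c(10, 10, 4))
    tis <- array(FALSE, dim(img)); tis[3:8, 3:8, 2:3] <- TRUE
    bg <- array(FALSE, dim(img)); bg[1, , ] <- TRUE
    img[tis] <- 16
    set.seed(2); img[bg] <- rnorm(sum(bg), 0, 1)
    snr <- estimateSNR(img, tis, bg)
    expect_equal(snr, 16 / stats::sd(img[bg]))
    expect_equal(estimateSNR(5 * img, tis, bg), snr)
    expect_error(estimateSNR(img, tis, tis), "disjoint")
    expect_error(estimateSNR(img, tis, array(FALSE, dim(img))), "non-empty")
    expect_error(estimateSNR(array(1, dim(img)), tis, bg), "zero background")
})

test_that("two-sample t-test matches the reference implementation", {
    expect_equal(twoSampleTTest(c(1, 2, 3), c(1, 2, 3)),
                 list(t = 0, df = 4, p = 1))
    set.seed(7)
    for (i in 1:100) {
        a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
        b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
        for (variant in c("pooled", "welch")) {
            ours <- twoSampleTTest(a, b, variant)
            ref <- stats::t.test(a, b, var.equal = variant == "pooled")
            expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
            expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
            expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
        }
        sw <- twoSampleTTest(b, a)
        fw <- twoSampleTTest(a, b)
        expect_equal(sw$t, -fw$t)
        expect_equal(sw$p, fw$p)
    }
    # CSF vs GM deuterium T1 on the per-visit values: p ~ 0.004
    v <- visitRelaxationTimes()
    expect_equal(twoSampleTTest(v$csf_t1_2h, v$gm_t1_2h)$p, 0.004011,
                 tolerance = 1e-3)
})
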