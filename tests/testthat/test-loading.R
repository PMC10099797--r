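test_that("total body water matches Watson and fraction conventions", {
    expect_equal(totalBodyWater("male", 30, 175, 70, "fraction"), 42.0)
    expect_equal(totalBodyWater("male", 30, 175, 70, "watson"), 42.0292,
                 tolerance = 1e-5)
    expect_equal(totalBodyWater("female", 40, 165, 60, "watson"),
                 -2.097 + 0.1069 * 165 + 0.2466 * 60, tolerance = 1e-10)
    expect_error(totalBodyWater("male", 30, 175, 70, "fraction",
                                fraction = 0), "positive")
    expect_error(totalBodyWater("male", -1, 175, 70), "positive")
})

test_that("dose-based enrichment is the dose/TBW ratio in atom percent", {
    sched <- standardDoseSchedule(nDoses = 18)   # 900 ml of 70% solution
    expect_equal(enrichmentFromDoses(sched, tbw = 42), 1.5)
    expect_equal(enrichmentFromDoses(sched[0, ], 42,
                                     includeBaseline = TRUE), 0.015)
    # linearity in dose volume
    big <- sched; big$volume_ml <- 2 * big$volume_ml
    expect_equal(enrichmentFromDoses(big, 42),
                 2 * enrichmentFromDoses(sched, 42))
    # cumulative variant is a non-decreasing step series ending at the total
    cum <- enrichmentFromDoses(sched, 42, cumulative = TRUE)
    expect_equal(nrow(cum), 18)
    expect_true(all(diff(cum$enrichment) > 0))
    expect_equal(tail(cum$enrichment, 1), 1.5)
    expect_error(enrichmentFromDoses(sched, 0), "positive")
})

test_that("spectral integration approximates the peak area and is linear", {
    f <- seq(-1500, 1500, by = 1)
    hw <- 10
    lorentz <- (1 / pi) * hw / ((f - 60)^2 + hw^2)  # unit-area, off-centre
    sp <- data.frame(frequency_hz = f, magnitude = lorentz)
    area <- integrateHDOSignal(sp, window = 1000)
    expect_equal(area, 1, tolerance = 0.02)
    # against a numerical integration oracle over the same window
    oracle <- stats::integrate(function(x) (1 / pi) * hw / ((x - 60)^2 + hw^2),
                               60 - 1000, 60 + 1000)$value
    expect_equal(area, oracle, tolerance = 0.005)
    sp3 <- sp; sp3$magnitude <- 3 * sp3$magnitude
    expect_equal(integrateHDOSignal(sp3, 1000), 3 * area)
    zero <- sp; zero$magnitude <- 0
    expect_equal(integrateHDOSignal(zero, 1000), 0)
    expect_error(integrateHDOSignal(sp, 0), "positive")
    expect_error(integrateHDOSignal(sp, 2000), "bandwidth")
})

test_that("natural-abundance scaling converts signal ratios to atom %", {
    expect_equal(enrichmentFromSignal(100, 1), 1.5)
    expect_equal(enrichmentFromSignal(1, 1), 0.015)
    expect_equal(enrichmentFromSignal(0, 1), 0)
    expect_error(enrichmentFromSignal(1, 0), "positive")
})

test_that("time-course normalization is anchored at the reference ROI", {
    tc <- data.frame(time_min = c(0, 30, 60),
                     cistern = c(1, 2, 4), ventricle = c(0.5, 1, 2),
                     brain = c(0.2, 0.4, 0.8))
    out <- normalizeTimecourse(tc, "cistern")
    expect_equal(tail(out$cistern, 1), 1)
    # between-ROI ratios preserved at every time point
    expect_equal(out$ventricle / out$cistern, tc$ventricle / tc$cistern)
    expect_equal(out$brain[1], 0.05)
    expect_error(normalizeTimecourse(tc, "nope"), "not found")
})

test_that("signal-derived enrichment recovers the programmed loading curve", {
    body <- default_body()
    sched <- standardDoseSchedule(nDoses = 18)
    times <- seq(0, 540, by = 30)
    es <- synthesizeLoadingSeries(sched, body, sampleTimes = times)
    # a noise-free spectrometer: signal proportional to enrichment, with the
    # pre-dose natural-abundance scan as baseline
    gain <- 37.2
    signals <- gain * es@enrichment
    baseline <- gain * 0.015
    recovered <- enrichmentFromSignal(signals, baseline)
    expect_lt(max(abs(recovered - es@enrichment) / es@enrichment), 0.01)
    # dose-model asymptote equals the synthetic series' asymptote
    tbw <- totalBodyWater(body$sex, body$age, body$height, body$mass)
    late <- synthesizeLoadingSeries(sched, body, sampleTimes = 1e6)
    expect_equal(enrichmentFromDoses(sched, tbw, includeBaseline = TRUE),
                 late@enrichment, tolerance = 1e-9)
})

test_that("quantification operations are homogeneous of degree one", {
    set.seed(3)
    for (c in c(0.25, 4)) {
        s <- runif(1, 1, 10); b <- runif(1, 0.5, 2)
        expect_equal(enrichmentFromSignal(c * s, c * b),
                     enrichmentFromSignal(s, b))
        expect_equal(enrichmentFromSignal(c * s, b),
                     c * enrichmentFromSignal(s, b))
        tc <- data.frame(time_min = 1:3, a = runif(3), ref = runif(3) + 1)
        sc <- tc; sc[c("a", "ref")] <- c * sc[c("a", "ref")]
        # normalization is invariant under a common signal rescaling
        expect_equal(normalizeTimecourse(sc, "ref"),
                     normalizeTimecourse(tc, "ref"))
        sp <- data.frame(frequency_hz = -50:50,
                         magnitude = dnorm(-50:50, 0, 5))
        expect_equal(integrateHDOSignal(
            transform(sp, magnitude = c * magnitude), 30),
            c * integrateHDOSignal(sp, 30))
    }
})
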