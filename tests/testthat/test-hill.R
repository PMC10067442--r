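test_that("series assembly averages duplicates and keeps every point", {
    mkWell <- function(plate, well, cmpd, conc, act, day = 7,
                       readout = "gfp_area_total")
        data.frame(plate_id = plate, well = well, day = day,
                   role = "sample", compound_id = cmpd, conc_m = conc,
                   gfp_area_total = 1, worm_number = 1L,
                   readout = readout, activity_pct = act,
                   normalizable = TRUE, stringsAsFactors = FALSE)
    w <- rbind(mkWell("P1", "C03", "a", 1e-6, -20),
               mkWell("P1", "C04", "a", 1e-6, -40),
               mkWell("P2", "C03", "a", 5e-6, -80),
               mkWell("P1", "D03", "b", 1e-6, -10))
    expect_warning(ser <- assembleSeries(w), "b")  # b has 1 concentration
    expect_length(ser, 1L)
    s <- ser[[1]]
    expect_equal(s@conc, c(1e-6, 5e-6))
    expect_equal(s@activity, c(-30, -80))          # duplicate mean
    expect_equal(s@n, c(2L, 1L))

    # an 11-point intra-plate follow-up titration keeps its 11 points
    conc <- 1e-8 * 3^(0:10)
    w11 <- do.call(rbind, lapply(seq_along(conc), function(i)
        mkWell("F1", sprintf("C%02d", i + 2), "c", conc[i], -i)))
    s11 <- assembleSeries(w11)[[1]]
    expect_length(s11@conc, 11L)
})

test_that("noiseless 4PL parameters are recovered essentially exactly", {
    s <- makeSeries(bottom = 0, top = -100, logEc50 = -6, slope = 1)
    f <- fitHill(s)
    expect_true(f@converged)
    expect_equal(f@nParams, 4L)
    expect_lt(abs(f@logEc50 - (-6)) / 6, 0.001)         # <= 0.1% relative
    expect_lt(abs(f@hillSlope - 1), 0.001)
    expect_lt(abs(f@bottom - 0), 0.1)                   # 0.1% of the span
    expect_lt(abs(f@top - (-100)) / 100, 0.001)
    expect_gt(f@r2, 0.9999)
    expect_false(f@extrapolated)

    steep <- makeSeries(logEc50 = -6.5, slope = 6)      # ivermectin-like
    fs <- fitHill(steep)
    expect_lt(abs(fs@logEc50 - (-6.5)), 0.01)
    expect_lt(abs(fs@hillSlope - 6) / 6, 0.01)
})

test_that("flat series report non-convergence, not an exception", {
    s <- makeSeries(bottom = 0, top = 0, slope = 1)
    f <- fitHill(s)
    expect_false(f@converged)
    expect_match(f@message, "flat")
})

test_that("stochastic EC50 recovery stays within 0.1 log at 5% noise", {
    errs <- vapply(1:100, function(seed) {
        s <- makeSeries(noiseSd = 5, seed = seed, slope = 1.5)
        fitHill(s)@logEc50 - (-6)
    }, 0)
    expect_lte(median(abs(errs)), 0.1)

    # bias <= 0.05 over a grid of true EC50s kept >= 1.5 decades inside
    # the tested range, so both plateaus stay sampled
    for (le in c(-7, -6.4, -5.8)) {
        errs <- vapply(1:100, function(seed) {
            s <- makeSeries(logEc50 = le, noiseSd = 5, seed = 1000 + seed)
            fitHill(s)@logEc50 - le
        }, 0)
        expect_lte(abs(mean(errs)), 0.05)
    }
})

test_that("fits are invariant to concentration unit rescaling", {
    s <- makeSeries(noiseSd = 3, seed = 12)
    f1 <- fitHill(s)
    s2 <- methods::new("TitrationSeries", compoundId = s@compoundId,
                       readout = s@readout, day = s@day,
                       conc = s@conc * 1e3, activity = s@activity,
                       n = s@n, plateId = s@plateId)
    f2 <- fitHill(s2)
    expect_equal(f2@logEc50, f1@logEc50 + 3, tolerance = 1e-4)
    expect_equal(f2@hillSlope, f1@hillSlope, tolerance = 1e-4)
    expect_equal(f2@top, f1@top, tolerance = 1e-4)
})

test_that("fitted asymptote order follows the data direction", {
    down <- fitHill(makeSeries(bottom = 0, top = -100, noiseSd = 2,
                               seed = 5))
    expect_lt(down@top, down@bottom)
    up <- fitHill(makeSeries(bottom = 0, top = 80, noiseSd = 2, seed = 6))
    expect_gt(up@top, up@bottom)
})

test_that("EC50s outside the tested range are flagged extrapolated", {
    s <- makeSeries(conc = 10^seq(-6, -4, length.out = 7), logEc50 = -8,
                    slope = 1)
    f <- fitHill(s)
    expect_true(f@extrapolated)
})

test_that("short series fall back to the constrained 3-parameter model", {
    conc <- 10^seq(-8, -4, length.out = 3)
    s <- methods::new("TitrationSeries", compoundId = "x",
                      readout = "gfp_area_total", day = 7, conc = conc,
                      activity = hill4(log10(conc), 0, -100, -6, 1),
                      n = rep(1L, 3), plateId = rep("P", 3))
    f <- fitHill(s)
    expect_true(f@converged)
    expect_equal(f@nParams, 3L)
    expect_equal(f@top, -100)           # full-kill plateau fixed
})

test_that("outlier masking flags a planted spike and respects the cap", {
    # a noiseless clean series is never masked
    exact <- makeSeries()
    expect_length(maskOutliers(exact, fitHill(exact))@maskedPoints, 0L)

    # a plateau point displaced by 10x the (known) noise SD is masked;
    # noiseSd is the plate-control activity SD the pipeline supplies
    clean <- makeSeries(noiseSd = 5, seed = 31)
    spiked <- clean
    spiked@activity[2] <- spiked@activity[2] - 10 * 5
    f1 <- maskOutliers(spiked, fitHill(spiked), noiseSd = 5)
    expect_true(2L %in% f1@maskedPoints)

    # at most 2 of 7 points are ever masked
    wild <- clean
    wild@activity[c(2, 4, 6)] <- wild@activity[c(2, 4, 6)] + c(150, -150, 150)
    f2 <- maskOutliers(wild, fitHill(wild), noiseSd = 5)
    expect_lte(length(f2@maskedPoints), 2L)

    # without an external noise scale, masking is deliberately
    # conservative: the same clean series stays unmasked
    expect_length(maskOutliers(clean, fitHill(clean))@maskedPoints, 0L)
})
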