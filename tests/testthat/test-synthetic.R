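test_that("library generation is seeded, counted and validated", {
    lib <- makeLibrary(10, activeFraction = 0, seed = 3)
    expect_equal(nrow(lib), 10L)
    expect_true(all(lib$true_efficacy == 0))

    big <- makeLibrary(643, activeFraction = 0.13, seed = 1)
    expect_equal(sum(big$is_active), floor(0.13 * 643))  # 83
    expect_equal(sum(big$is_active), 83L)
    expect_true(all(big$true_ec50_m > 0))
    expect_true(all(big$true_efficacy >= 0 & big$true_efficacy <= 1))
    expect_equal(unique(nchar(big$fingerprint)), 729L)

    expect_identical(makeLibrary(25, 0.2, seed = 7),
                     makeLibrary(25, 0.2, seed = 7))
    expect_false(identical(makeLibrary(25, 0.2, seed = 7),
                           makeLibrary(25, 0.2, seed = 8)))

    expect_error(makeLibrary(2.5, seed = 1), "integer")
    expect_error(makeLibrary(10, seed = -1), "seed")
    expect_error(makeLibrary(10, activeFraction = 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("structure-activity linkage concentrates hits in chemotypes", {
    lib <- makeLibrary(300, activeFraction = 0.1, chemotypeClusters = 50,
                       activeClusters = 5, seed = 4, fingerprintBits = 64)
    expect_equal(sum(lib$is_active), 30L)
    # actives occupy few chemotype clusters compared to uniform draws
    expect_lte(length(unique(lib$chemotype_cluster[lib$is_active])), 8L)
    unif <- makeLibrary(300, activeFraction = 0.1, chemotypeClusters = 50,
                        seed = 4, fingerprintBits = 64)
    expect_gt(length(unique(unif$chemotype_cluster[unif$is_active])), 8L)
})

test_that("fingerprints cluster: within-chemotype similarity exceeds between", {
    lib <- makeLibrary(120, activeFraction = 0, chemotypeClusters = 4,
                       seed = 11, fingerprintBits = 256)
    fp <- fingerprintMatrix(lib)
    cl <- lib$chemotype_cluster
    d <- as.matrix(dist(fp, method = "manhattan"))
    same <- d[outer(cl, cl, "==") & upper.tri(d)]
    diff <- d[outer(cl, cl, "!=") & upper.tri(d)]
    expect_lt(mean(same), mean(diff))
})

test_that("inter-plate titration reproduces the screening dilution design", {
    lib <- makeLibrary(60, seed = 1)
    plates <- makeInterplateTitration(lib, nPoints = 7, dilutionFactor = 5,
                                      topStock = 20e-3,
                                      inWellDilution = 240)
    expect_length(plates, 7L)
    stocks <- vapply(plates, function(p) {
        w <- layoutWells(p)
        max(w$conc_m[w$role == "sample"]) * 240
    }, 0)
    expect_equal(min(stocks), 1.28e-6, tolerance = 1e-12)   # 1.28 uM
    expect_equal(max(stocks), 20e-3)

    lo <- makeInterplateTitration(lib, topStock = 2.5e-3)
    stocks2 <- vapply(lo, function(p) {
        w <- layoutWells(p)
        max(w$conc_m[w$role == "sample"]) * 240
    }, 0)
    expect_equal(min(stocks2), 160e-9, tolerance = 1e-12)   # 160 nM

    # control column: 8 fixed wells at 41.7 uM final, 1:3 series to 4.57 uM
    w <- layoutWells(plates[[1]])
    tox <- w[w$role == "toxic_control_titration", ]
    expect_equal(nrow(tox), 16L)
    expect_equal(signif(max(tox$conc_m) * 1e6, 3), 41.7)
    expect_equal(signif(min(tox$conc_m) * 240 * 1e6, 3), 4.57)
    neu <- w[w$role == "neutral_control", ]
    expect_equal(nrow(neu), 16L)
    expect_true(all(neu$conc_m == 0))

    two <- makeInterplateTitration(lib, nPoints = 2, dilutionFactor = 10,
                                   topStock = 1e-3)
    s2 <- vapply(two, function(p) {
        w <- layoutWells(p)
        max(w$conc_m[w$role == "sample"]) * 240
    }, 0)
    expect_equal(sort(unname(s2)), c(1e-4, 1e-3))

    bigLib <- makeLibrary(400, seed = 2)
    expect_error(makeInterplateTitration(bigLib, split = FALSE), "352")
    splitPlates <- makeInterplateTitration(bigLib, nPoints = 7)
    expect_length(splitPlates, 14L)  # two plates per level
})

test_that("hill kill hazard hits the published midpoint and saturates", {
    expect_equal(killProbability(1e-6, ec50 = 1e-6, hill = 1), 0.5)
    expect_equal(killProbability(0, 1e-6, 1), 0)
    expect_lt(killProbability(1e-8, 1e-6, 4), 1e-6)
    expect_equal(killProbability(1e-3, 1e-6, 4), 1)
    expect_equal(killProbability(1e-6, 1e-6, 1, efficacy = 0.6), 0.3)
    expect_equal(killProbability(1e-6, 1e-6, 1, susceptibility = 0), 0)
})

test_that("saturating treatment empties wells; vehicle wells grow", {
    layout <- onePlateLayout(conc = 1e-3)            # >> EC50 1 uM
    lib <- rbind(oneCompound(ec50 = 1e-6, hill = 6, efficacy = 1),
                 controlCompound(16))
    pop <- simulatePopulation(layout, lib, days = 7, seed = 1)
    d7 <- pop[pop$day == 7, ]
    w <- layoutWells(layout)
    samp <- d7[d7$well %in% w$well[w$role == "sample"], ]
    stages <- c("egg", "L1", "L2", "L3", "L4", "adult")
    expect_true(all(rowSums(samp[, stages]) == 0))

    # neutral wells: mean day-7 worm count exceeds the day-0 seeding
    # across 200 replicate seeds
    neuWell <- w$well[w$role == "neutral_control"][1L]
    totals <- vapply(1:200, function(s) {
        p <- simulatePopulation(layout, lib, days = 7, seed = s)
        sum(p[p$day == 7 & p$well == neuWell,
              c("L1", "L2", "L3", "L4", "adult")])
    }, 0)
    expect_gt(mean(totals), 10)
})

test_that("living-worm count is non-increasing under full-efficacy kill", {
    layout <- onePlateLayout(conc = 1e-3)
    lib <- rbind(oneCompound(ec50 = 1e-6, hill = 6, efficacy = 1,
                             eggSusc = 1),
                 controlCompound(16))
    pop <- simulatePopulation(layout, lib, days = 7, seed = 42)
    w <- layoutWells(layout)
    samp <- pop[pop$well %in% w$well[w$role == "sample"], ]
    byDay <- tapply(rowSums(samp[, c("egg", "L1", "L2", "L3", "L4",
                                     "adult")]), samp$day, sum)
    expect_true(all(diff(byDay[order(as.numeric(names(byDay)))]) <= 0))
})

test_that("mean day-7 count is non-increasing in concentration", {
    # one compound at increasing concentration across wells of one plate
    wells <- wellNames384()
    concs <- c(0, 10^seq(-7.5, -4.5, length.out = 6))
    role <- rep("sample", 384L)
    role[wellColumn384(wells) == 1L] <- "neutral_control"
    role[wellColumn384(wells) == 2L] <- "toxic_control_titration"
    compound <- rep(NA_character_, 384L)
    cc <- rep(0, 384L)
    samp <- wells[wellColumn384(wells) >= 3L][1:length(concs)]
    compound[match(samp, wells)] <- "CMPD0001"
    cc[match(samp, wells)] <- concs
    col2 <- wells[wellColumn384(wells) == 2L]
    compound[match(col2, wells)] <- "CTRL-LEV"
    cc[match(col2, wells)] <- c(rep(10e-3, 8), 10e-3 / 3^(0:7)) / 240
    layout <- methods::new("PlateLayout", plateId = "MONO",
                           wells = data.frame(well = wells, role = role,
                                              compound_id = compound,
                                              conc_m = cc,
                                              stringsAsFactors = FALSE),
                           readSchedule = 7)
    lib <- rbind(oneCompound(ec50 = 1e-6, hill = 1.5, efficacy = 0.9),
                 controlCompound(16))
    tot <- matrix(0, 100, length(concs))
    for (s in 1:100) {
        p <- simulatePopulation(layout, lib, days = 7, seed = s)
        d7 <- p[p$day == 7, ]
        tot[s, ] <- rowSums(d7[match(samp, d7$well),
                               c("L1", "L2", "L3", "L4", "adult")])
    }
    means <- colMeans(tot)
    expect_true(all(diff(means) <= 0.03 * max(means)))
    expect_lt(means[length(concs)], 0.1 * means[1])
})

test_that("event emission conserves worms and separates stages", {
    st <- rbind(stateRow(well = "C03", L1 = 40, adult = 25),
                stateRow(well = "D03", L3 = 30, egg = 50))
    optics0 <- opticsConfig(debrisRate = 0)
    ev <- emitLscEvents(st, optics0, seed = 5)
    expect_equal(nrow(ev), 40 + 25 + 30)      # eggs are not emitted
    expect_identical(emitLscEvents(st, optics0, seed = 5), ev)

    empty <- emitLscEvents(stateRow(well = "C03"), optics0, seed = 1)
    expect_equal(nrow(empty), 0L)

    # mean object size increases monotonically from L1 to adult
    big <- stateRow(well = "C03", L1 = 500, L2 = 500, L3 = 500, L4 = 500,
                    adult = 500)
    cev <- emitCopasEvents(big, seed = 2)
    expect_equal(nrow(cev), 2500L)
    # per-stage LSC size means, emitted one stage at a time
    areaByStage <- vapply(c("L1", "L2", "L3", "L4", "adult"), function(s) {
        one <- stateRow(well = "C03")
        one[[s]] <- 2000
        mean(emitLscEvents(one, optics0, seed = 3)$area)
    }, 0)
    expect_true(all(diff(areaByStage) > 0))
})
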