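test_that("stage gates validate non-overlap and ranges", {
    expect_s3_class(defaultStageGates(), "StageGates")
    expect_error(stageGates(c("L1", "L2"), tofMin = c(10, 50),
                            tofMax = c(60, 100), ecMin = c(5, 20),
                            ecMax = c(25, 50)),
                 "overlapping gates: L1 and L2")
    # overlapping TOF but disjoint EC boxes are legal
    g <- stageGates(c("a", "b"), tofMin = c(10, 10), tofMax = c(100, 100),
                    ecMin = c(5, 30), ecMax = c(25, 60))
    expect_equal(nrow(g), 2L)
    expect_error(stageGates("x", 10, 5, 1, 2), "min <= max")
})

test_that("classification partitions events and ignores gate order", {
    gates <- defaultStageGates()
    ev <- data.frame(tof = c(200, 5000, 60, 350), ec = c(100, 5, 20, 200))
    d <- classifyEvents(ev, gates, treatment = "t")
    expect_equal(unname(d$counts["L3"]), 1)
    expect_equal(unname(d$counts["L1"]), 1)
    expect_equal(unname(d$counts["L4"]), 1)
    expect_equal(d$unclassified, 1)
    expect_equal(sum(d$counts) + d$unclassified, d$total)

    perm <- gates[c(3, 1, 5, 2, 4), ]
    class(perm) <- class(gates)
    d2 <- classifyEvents(ev, perm, treatment = "t")
    expect_equal(d2$counts[names(d$counts)], d$counts)
})

test_that("mixed populations are recovered within 3 binomial SDs", {
    n <- c(L1 = 700, L2 = 300, L3 = 400, L4 = 250, adult = 350)
    st <- stateRow(well = "A01", L1 = n["L1"], L2 = n["L2"], L3 = n["L3"],
                   L4 = n["L4"], adult = n["adult"])
    ev <- emitCopasEvents(st, seed = 21)
    d <- classifyEvents(ev, treatment = "mixed")
    expect_equal(sum(d$counts) + d$unclassified, sum(n))
    tot <- sum(n)
    for (s in names(n)) {
        sd3 <- 3 * sqrt(tot * (n[[s]] / tot) * (1 - n[[s]] / tot))
        expect_lte(abs(d$counts[[s]] - n[[s]]), sd3)
    }
    # 50/50 two-stage recovery
    st2 <- stateRow(well = "A01", L1 = 1000, adult = 1000)
    d2 <- classifyEvents(emitCopasEvents(st2, seed = 22))
    expect_lte(abs(d2$counts[["L1"]] - 1000), 3 * sqrt(2000 * 0.25))
    expect_lte(abs(d2$counts[["adult"]] - 1000), 3 * sqrt(2000 * 0.25))

    expect_equal(classifyEvents(emitCopasEvents(stateRow(well = "A01"),
                                                seed = 1))$total, 0)
})

test_that("heat-map binning follows the count scale with lower-bin ties", {
    breaks <- c(10, 100, 1000, 5000, 15000)
    dists <- list(
        structure(list(treatment = "hi",
                       counts = c(L1 = 20000, L2 = 15000, L3 = 5, L4 = 10,
                                  adult = 500),
                       unclassified = 0, total = 35515),
                  class = "StageDistribution"))
    m <- heatmapMatrix(dists, breaks)
    expect_equal(dim(m), c(1L, 5L))
    expect_equal(m["hi", "L1"], 6L)       # > 15000: top bin
    expect_equal(m["hi", "L2"], 5L)       # equal to breakpoint: lower bin
    expect_equal(m["hi", "L3"], 1L)       # < 10: bottom bin
    expect_equal(m["hi", "L4"], 1L)       # tie at the bottom breakpoint
    expect_equal(m["hi", "adult"], 3L)
    expect_error(heatmapMatrix(dists, numeric()), "empty")
    expect_error(heatmapMatrix(dists, c(10, 10)), "strictly increasing")
})

test_that("a 6-well life-stage scenario reaches the heat-map ceiling", {
    # 2000 mixed worms per well, 20000-worm capacity: vehicle exceeds the
    # >15000 top bin by day 7 while a saturating kill falls below 10
    lib <- rbind(oneCompound(id = "KILL", ec50 = 1e-8, hill = 6,
                             efficacy = 1, eggSusc = 1),
                 controlCompound(16))
    dyn <- dynamicsConfig(seedWorms = 2000, seedStage = "mixed",
                          carryingCapacity = 20000)
    wells <- wellNames384()
    role <- rep("sample", 384L)
    role[wellColumn384(wells) == 1L] <- "neutral_control"
    role[wellColumn384(wells) == 2L] <- "toxic_control_titration"
    compound <- rep(NA_character_, 384L); cc <- rep(0, 384L)
    compound[match("A03", wells)] <- "KILL"; cc[match("A03", wells)] <- 1e-5
    col2 <- wells[wellColumn384(wells) == 2L]
    compound[match(col2, wells)] <- "CTRL-LEV"
    cc[match(col2, wells)] <- c(rep(10e-3, 8), 10e-3 / 3^(0:7)) / 240
    layout <- methods::new("PlateLayout", plateId = "LS",
                           wells = data.frame(well = wells, role = role,
                                              compound_id = compound,
                                              conc_m = cc,
                                              stringsAsFactors = FALSE),
                           readSchedule = 7)
    pop <- simulatePopulation(layout, lib, days = 7, dynamics = dyn,
                              seed = 3)
    d7 <- pop[pop$day == 7, ]
    vehicle <- sum(d7[d7$well == "A01", c("L1", "L2", "L3", "L4", "adult")])
    killed <- sum(d7[d7$well == "A03", c("L1", "L2", "L3", "L4", "adult")])
    expect_gt(vehicle, 15000)
    expect_lt(killed, 10)
})
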