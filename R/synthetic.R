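## Synthetic screen generator: seeded, ground-truth-annotated compound
## libraries, 384-well titration layouts, stage-structured worm populations
## over a multi-day time course, and emitted cytometry event tables.

#' Population dynamics configuration
#'
#' Parameters of the discrete stage-structured population model used by
#' [simulatePopulation()].  The model advances in half-day steps; a worm
#' passes egg (1 day), L1, L2, L3, L4 (half a day each) and becomes a
#' reproducing adult 2 days after hatching, so one egg-to-egg life cycle
#' takes about 3 days and a 7-day incubation spans two full cycles.
#'
#' @param seedWorms worms seeded per well at day 0 (default 10, the
#'   ten-worms-per-30-microlitre-well screening density).
#' @param seedStage `"L1"` (synchronized screen seeding), `"mixed"` (equal
#'   split over L1-adult, as in development and life-stage plates), or a
#'   named vector of per-stage counts overriding `seedWorms`.
#' @param broodPerAdultPerDay eggs laid per adult per day (default 40;
#'   order-of-magnitude of the C. elegans brood spread over the laying
#'   period).
#' @param carryingCapacity ceiling on total individuals per well (default
#'   2000 for a 30 microlitre 384-well well; use 20000 for 6-well
#'   life-stage plates).
#' @param baseDeathRate compound-independent death probability per worm per
#'   day.
#' @param eggSusceptibility default susceptibility multiplier for eggs when
#'   the library does not carry per-stage columns (eggshell protection).
#' @return a `DynamicsConfig` list.
#' @export
dynamicsConfig <- function(seedWorms = 10, seedStage = "L1",
                           broodPerAdultPerDay = 40,
                           carryingCapacity = 2000,
                           baseDeathRate = 0.01,
                           eggSusceptibility = 0.2) {
    stopifnot(seedWorms >= 0, broodPerAdultPerDay >= 0,
              carryingCapacity >= 1, baseDeathRate >= 0, baseDeathRate < 1)
    structure(list(seedWorms = seedWorms, seedStage = seedStage,
                   broodPerAdultPerDay = broodPerAdultPerDay,
                   carryingCapacity = carryingCapacity,
                   baseDeathRate = baseDeathRate,
                   eggSusceptibility = eggSusceptibility),
              class = "DynamicsConfig")
}

#' Laser-scanning cytometry optics configuration
#'
#' Per-life-stage lognormal feature distributions (arithmetic mean and CV)
#' for object area, perimeter and peak intensity, plus a sub-gate debris
#' model.  Defaults place every worm stage comfortably inside the default
#' object gate (perimeter 100-2200, area 1000-180000, peak 150-1500) and
#' debris almost entirely outside it, with mean object size increasing
#' monotonically from L1 to adult.
#'
#' @param areaMean,perimeterMean,peakMean named per-stage means (L1..adult);
#'   area in square micrometres, perimeter in micrometres, peak intensity in
#'   arbitrary fluorescence units.
#' @param areaCv,perimeterCv,peakCv coefficients of variation (scalar or
#'   per-stage).
#' @param debrisRate expected debris objects per well per read (Poisson).
#' @param debrisArea,debrisPerimeter,debrisPeak `c(mean, cv)` of the debris
#'   feature distributions.
#' @return an `OpticsConfig` list.
#' @export
opticsConfig <- function(
        areaMean = c(L1 = 2500, L2 = 6000, L3 = 15000, L4 = 35000,
                     adult = 70000),
        areaCv = 0.28,
        perimeterMean = c(L1 = 300, L2 = 450, L3 = 700, L4 = 1000,
                          adult = 1200),
        perimeterCv = c(L1 = 0.25, L2 = 0.25, L3 = 0.25, L4 = 0.22,
                        adult = 0.2),
        peakMean = c(L1 = 350, L2 = 420, L3 = 500, L4 = 600, adult = 700),
        peakCv = 0.25,
        debrisRate = 20,
        debrisArea = c(300, 0.5),
        debrisPerimeter = c(60, 0.5),
        debrisPeak = c(80, 0.5)) {
    expand <- function(x) {
        if (length(x) == 1L) x <- rep(x, 5L)
        stats::setNames(as.numeric(x), LARVAL_STAGES)
    }
    stopifnot(debrisRate >= 0)
    structure(list(areaMean = expand(areaMean), areaCv = expand(areaCv),
                   perimeterMean = expand(perimeterMean),
                   perimeterCv = expand(perimeterCv),
                   peakMean = expand(peakMean), peakCv = expand(peakCv),
                   debrisRate = debrisRate, debrisArea = debrisArea,
                   debrisPerimeter = debrisPerimeter,
                   debrisPeak = debrisPeak),
              class = "OpticsConfig")
}

#' COPAS flow model configuration
#'
#' Per-stage lognormal clouds for time of flight (TOF, an object length
#' proxy), extinction (EC, an optical density proxy) and green fluorescence.
#' Default separation keeps the five stage clouds essentially disjoint, so
#' rectangular TOF x EC gates recover stage counts to within binomial error.
#'
#' @param tofMean,ecMean,greenMean named per-stage means (L1..adult).
#' @param tofCv,ecCv,greenCv coefficients of variation.
#' @param debrisRate expected sub-gate debris events per emission (Poisson);
#'   default 0.
#' @return a `FlowConfig` list.
#' @export
flowConfig <- function(
        tofMean = c(L1 = 60, L2 = 120, L3 = 200, L4 = 350, adult = 600),
        tofCv = 0.12,
        ecMean = c(L1 = 20, L2 = 50, L3 = 100, L4 = 200, adult = 400),
        ecCv = 0.12,
        greenMean = c(L1 = 50, L2 = 100, L3 = 200, L4 = 400, adult = 800),
        greenCv = 0.3,
        debrisRate = 0) {
    expand <- function(x) {
        if (length(x) == 1L) x <- rep(x, 5L)
        stats::setNames(as.numeric(x), LARVAL_STAGES)
    }
    structure(list(tofMean = expand(tofMean), tofCv = expand(tofCv),
                   ecMean = expand(ecMean), ecCv = expand(ecCv),
                   greenMean = expand(greenMean), greenCv = expand(greenCv),
                   debrisRate = debrisRate),
              class = "FlowConfig")
}

#' Built-in toxic-control compound (levamisole-like)
#'
#' One-row compound table for the intra-plate toxic control: low-micromolar
#' EC50 (8 uM), graded slope 1.5, full efficacy.  Include it in the library
#' passed to [simulatePopulation()] whenever layouts from
#' [makeInterplateTitration()] are simulated.
#'
#' @param fingerprintBits fingerprint length (all-zero bits; the control is
#'   excluded from chemotype analyses).
#' @return one-row library `data.frame`.
#' @export
controlCompound <- function(fingerprintBits = 729) {
    data.frame(compound_id = "CTRL-LEV",
               annotation = "toxic control (levamisole-like)",
               true_ec50_m = 8e-6, true_hill = 1.5, true_efficacy = 1,
               is_active = TRUE, chemotype_cluster = NA_integer_,
               fingerprint = strrep("0", fingerprintBits),
               susc_egg = 0.2, susc_L1 = 1, susc_L2 = 1, susc_L3 = 1,
               susc_L4 = 1, susc_adult = 1,
               stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic compound library
#'
#' Draws `nCompounds` compound specifications with ground-truth Hill
#' pharmacology and clustered binary chemotype fingerprints.  Exactly
#' `floor(activeFraction * nCompounds)` compounds are active: their EC50 is
#' log-uniform over `ec50Range`, their efficacy uniform on
#' `efficacyRange`, and their slope graded (lognormal around 1.5,
#' levamisole-like) or steep (uniform 4-8, ivermectin-like) with
#' probability `1 - steepFraction` / `steepFraction`.  Inactive compounds
#' have efficacy 0.  Fingerprints share a per-chemotype-cluster signature
#' bit block plus sparse background bits, so within-cluster similarity
#' exceeds between-cluster similarity.
#'
#' @param nCompounds library size (positive integer).
#' @param activeFraction fraction of true actives in `[0, 1]`.
#' @param chemotypeClusters number of chemotype clusters.
#' @param seed RNG seed (non-negative integer); identical seeds give
#'   byte-identical libraries.
#' @param fingerprintBits fingerprint length (default 729).
#' @param ec50Range molar range for active EC50s (default 10 nM - 10 uM,
#'   inside the tested in-well range).
#' @param efficacyRange efficacy range for actives.
#' @param steepFraction fraction of actives with a steep slope.
#' @param activeClusters optional count of chemotype clusters carrying the
#'   structure-activity relationship: actives are then drawn cluster by
#'   cluster from this many randomly chosen chemotypes (any remaining
#'   active quota drawn at random), emulating screens whose hits
#'   concentrate in structural classes.  `NULL` (default) spreads actives
#'   uniformly.
#' @return `data.frame` with columns `compound_id`, `annotation`,
#'   `true_ec50_m`, `true_hill`, `true_efficacy`, `is_active`,
#'   `chemotype_cluster`, `fingerprint` (0/1 bitstring) and per-stage
#'   susceptibility columns `susc_egg` ... `susc_adult`.
#' @examples
#' lib <- makeLibrary(20, activeFraction = 0.25, seed = 1)
#' sum(lib$is_active)
#' @export
makeLibrary <- function(nCompounds, activeFraction = 0.13,
                        chemotypeClusters = 20, seed,
                        fingerprintBits = 729,
                        ec50Range = c(1e-8, 1e-5),
                        efficacyRange = c(0.7, 1),
                        steepFraction = 0.2,
                        activeClusters = NULL) {
    n <- checkCount(nCompounds, "nCompounds")
    chemotypeClusters <- checkCount(chemotypeClusters, "chemotypeClusters")
    fingerprintBits <- checkCount(fingerprintBits, "fingerprintBits")
    if (activeFraction < 0 || activeFraction > 1)
        stop("activeFraction must be in [0, 1]")
    seed <- checkSeed(seed)
    set.seed(seed)

    cluster <- sample.int(chemotypeClusters, n, replace = TRUE)
    nActive <- floor(activeFraction * n)
    active <- rep(FALSE, n)
    if (nActive > 0) {
        if (is.null(activeClusters)) {
            active[sample.int(n, nActive)] <- TRUE
        } else {
            # concentrate hits in structural classes
            hot <- sample.int(chemotypeClusters,
                              min(activeClusters, chemotypeClusters))
            pool <- which(cluster %in% hot)
            take <- utils::head(pool[order(match(cluster[pool], hot))],
                                nActive)
            active[take] <- TRUE
            short <- nActive - length(take)
            if (short > 0)
                active[sample(which(!active), short)] <- TRUE
        }
    }

    ec50 <- rep(1e-4, n)
    hill <- rep(1, n)
    eff <- rep(0, n)
    if (nActive > 0) {
        ec50[active] <- 10^stats::runif(nActive, log10(ec50Range[1]),
                                        log10(ec50Range[2]))
        steep <- stats::runif(nActive) < steepFraction
        h <- exp(stats::rnorm(nActive, log(1.5), 0.3))
        h[steep] <- stats::runif(sum(steep), 4, 8)
        hill[active] <- h
        eff[active] <- stats::runif(nActive, efficacyRange[1],
                                    efficacyRange[2])
    }

    nSig <- min(25L, max(5L, fingerprintBits %/% 30L))
    sigBits <- lapply(seq_len(chemotypeClusters),
                      function(k) sample.int(fingerprintBits, nSig))
    fp <- matrix(stats::runif(n * fingerprintBits) < 0.03, n, fingerprintBits)
    for (i in seq_len(n)) {
        on <- stats::runif(nSig) < 0.95
        fp[i, sigBits[[cluster[i]]][on]] <- TRUE
    }
    fpStr <- apply(fp, 1L, function(b) paste(as.integer(b), collapse = ""))

    data.frame(
        compound_id = sprintf("CMPD%04d", seq_len(n)),
        annotation = ifelse(active,
                            sprintf("active moa-%d", cluster), "inactive"),
        true_ec50_m = ec50, true_hill = hill, true_efficacy = eff,
        is_active = active, chemotype_cluster = cluster,
        fingerprint = fpStr,
        susc_egg = 0.2, susc_L1 = 1, susc_L2 = 1, susc_L3 = 1,
        susc_L4 = 1, susc_adult = 1,
        stringsAsFactors = FALSE)
}

#' Fingerprint bit matrix from a library table
#'
#' @param library library `data.frame` with a `fingerprint` bitstring
#'   column.
#' @return numeric 0/1 matrix, one row per compound, rownames compound ids.
#' @export
fingerprintMatrix <- function(library) {
    nb <- unique(nchar(library$fingerprint))
    if (length(nb) != 1L)
        stop("fingerprints must all have the same length")
    m <- t(vapply(strsplit(library$fingerprint, ""),
                  function(b) as.numeric(b == "1"), numeric(nb)))
    rownames(m) <- library$compound_id
    m
}

#' Build seven-point inter-plate titration layouts
#'
#' Produces one set of 384-well plates per concentration level: plate level
#' `k` (k = 0 .. nPoints-1) carries every library compound at stock
#' `topStock / dilutionFactor^k`, converted to final in-well concentration
#' by `stock / inWellDilution`.  Column 1 is the DMSO neutral control;
#' column 2 carries the toxic control (wells 1-8 fixed at
#' `controlTopStock / inWellDilution`, wells 9-16 an eight-point 1:3
#' titration from `controlTopStock`).  Columns 3-24 hold up to 352 sample
#' wells; a larger library is split across several plates per level (set
#' `split = FALSE` to instead raise an error naming the capacity).
#'
#' @param library library `data.frame` (see [makeLibrary()]).
#' @param nPoints number of inter-plate concentration levels (>= 2).
#' @param dilutionFactor inter-plate dilution ratio (> 1; default 5).
#' @param topStock top stock concentration in molar (default 10 mM).
#' @param inWellDilution stock-to-well dilution factor (default 240).
#' @param controlTopStock toxic-control top stock (default 10 mM, giving a
#'   41.7 uM full-kill well concentration at 240-fold dilution).
#' @param controlDilution intra-plate control titration ratio (default 3).
#' @param readSchedule days on which plates are read (default days 3 and 7).
#' @param split split an oversized library across plates per level.
#' @return list of [PlateLayout-class] objects.
#' @examples
#' lib <- makeLibrary(60, seed = 1)
#' plates <- makeInterplateTitration(lib, topStock = 20e-3)
#' length(plates)
#' @export
makeInterplateTitration <- function(library, nPoints = 7,
                                    dilutionFactor = 5, topStock = 10e-3,
                                    inWellDilution = 240,
                                    controlTopStock = 10e-3,
                                    controlDilution = 3,
                                    readSchedule = c(3, 7),
                                    split = TRUE) {
    nPoints <- checkCount(nPoints, "nPoints", min = 2L)
    if (dilutionFactor <= 1) stop("dilutionFactor must be > 1")
    if (topStock <= 0) stop("topStock must be positive")
    if (inWellDilution <= 0) stop("inWellDilution must be positive")

    allWells <- wellNames384()
    sampleWells <- allWells[wellColumn(allWells) >= 3L]
    capacity <- length(sampleWells)   # 352
    ids <- library$compound_id
    if (length(ids) > capacity && !split)
        stop(sprintf(
            "library of %d compounds exceeds the %d sample wells available on one plate",
            length(ids), capacity))
    chunks <- split(ids, ceiling(seq_along(ids) / capacity))

    col1 <- allWells[wellColumn(allWells) == 1L]
    col2 <- allWells[wellColumn(allWells) == 2L]
    ctrlFixed <- col2[1:8]
    ctrlTitr <- col2[9:16]
    ctrlConc <- c(rep(controlTopStock, 8L),
                  controlTopStock / controlDilution^(0:7)) / inWellDilution

    layouts <- list()
    for (k in seq_len(nPoints) - 1L) {
        stock <- topStock / dilutionFactor^k
        for (j in seq_along(chunks)) {
            cmpds <- chunks[[j]]
            well <- allWells
            role <- rep("sample", 384L)
            role[wellColumn(well) == 1L] <- "neutral_control"
            role[wellColumn(well) == 2L] <- "toxic_control_titration"
            compound <- rep(NA_character_, 384L)
            conc <- rep(0, 384L)
            compound[match(sampleWells[seq_along(cmpds)], well)] <- cmpds
            conc[match(sampleWells[seq_along(cmpds)], well)] <-
                stock / inWellDilution
            compound[match(c(ctrlFixed, ctrlTitr), well)] <- "CTRL-LEV"
            conc[match(c(ctrlFixed, ctrlTitr), well)] <- ctrlConc
            pid <- if (length(chunks) == 1L) sprintf("P%02d", k + 1L)
                   else sprintf("P%02d-%d", k + 1L, j)
            layouts[[pid]] <- methods::new(
                "PlateLayout", plateId = pid,
                wells = data.frame(well = well, role = role,
                                   compound_id = compound, conc_m = conc,
                                   stringsAsFactors = FALSE),
                readSchedule = as.numeric(readSchedule))
        }
    }
    layouts
}

#' Per-day Hill kill probability
#'
#' Daily per-worm kill hazard under compound exposure:
#' `efficacy * susceptibility * c^h / (c^h + EC50^h)`, clamped to `[0, 1]`.
#'
#' @param conc final in-well molar concentration.
#' @param ec50 compound EC50 (molar); @param hill Hill slope.
#' @param efficacy fraction of full kill in `[0, 1]`.
#' @param susceptibility life-stage multiplier (>= 0).
#' @return kill probability per worm per day.
#' @export
killProbability <- function(conc, ec50, hill, efficacy = 1,
                            susceptibility = 1) {
    frac <- ifelse(conc > 0, conc^hill / (conc^hill + ec50^hill), 0)
    pmin(1, pmax(0, efficacy * susceptibility * frac))
}

# stage label of each internal age bin (two half-day egg bins, then one
# half-day bin per larval stage, then the absorbing adult pool)
BIN_STAGES <- c("egg", "egg", "L1", "L2", "L3", "L4", "adult")

#' Simulate per-well worm populations over a time course
#'
#' Discrete stage-structured stochastic model on half-day steps: cohorts
#' age egg -> L1 -> L2 -> L3 -> L4 -> adult (egg 1 day, each larval stage
#' half a day), adults lay eggs at a fixed daily rate subject to a per-well
#' carrying capacity, and every individual survives each step with
#' probability set by the compound's Hill kill hazard (see
#' [killProbability()]) at the well concentration, scaled by the compound's
#' per-stage susceptibility, plus a small background death rate.  All
#' randomness flows from per-plate substreams derived from `seed` and the
#' plate id, so results do not depend on the order plates are simulated.
#'
#' @param layouts a [PlateLayout-class] or list of them.
#' @param library library table; every non-`NA` `compound_id` in the
#'   layouts must appear in it (include [controlCompound()]).
#' @param days time-course length in days (>= 1).
#' @param dynamics a [dynamicsConfig()].
#' @param seed RNG seed.
#' @return `data.frame` with columns `plate_id`, `well`, `day` and
#'   per-stage counts `egg`, `L1`, `L2`, `L3`, `L4`, `adult` for every well
#'   and integer day 0..`days`.
#' @export
simulatePopulation <- function(layouts, library, days = 7,
                               dynamics = dynamicsConfig(), seed) {
    if (methods::is(layouts, "PlateLayout")) layouts <- list(layouts)
    days <- checkCount(days, "days")
    seed <- checkSeed(seed)
    out <- lapply(layouts, simulatePlate, library = library, days = days,
                  dynamics = dynamics, seed = seed)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

simulatePlate <- function(layout, library, days, dynamics, seed) {
    w <- layoutWells(layout)
    nW <- nrow(w)
    unknown <- setdiff(stats::na.omit(unique(w$compound_id)),
                       library$compound_id)
    if (length(unknown))
        stop("layout references unknown compound(s): ",
             paste(unknown, collapse = ", "))
    set.seed(deriveSeed(seed, layout@plateId))

    idx <- match(w$compound_id, library$compound_id)
    eff <- ifelse(is.na(idx), 0, library$true_efficacy[idx])
    ec50 <- ifelse(is.na(idx), 1, library$true_ec50_m[idx])
    hill <- ifelse(is.na(idx), 1, library$true_hill[idx])
    suscCols <- paste0("susc_", c("egg", "L1", "L2", "L3", "L4", "adult"))
    if (all(suscCols %in% names(library))) {
        suscTab <- as.matrix(library[, suscCols])
    } else {
        suscTab <- matrix(1, nrow(library), 6L,
                          dimnames = list(NULL, suscCols))
        suscTab[, 1L] <- dynamics$eggSusceptibility
    }
    # 7 bins x wells susceptibility (two egg bins share the egg column)
    binToStage <- c(1L, 1L, 2L, 3L, 4L, 5L, 6L)
    susc <- matrix(1, 7L, nW)
    has <- !is.na(idx)
    susc[, has] <- t(suscTab[idx[has], binToStage, drop = FALSE])

    pKillDay <- matrix(0, 7L, nW)
    for (b in 1:7)
        pKillDay[b, ] <- killProbability(w$conc_m, ec50, hill, eff, susc[b, ])
    dt <- 0.5
    pDieStep <- 1 - ((1 - pKillDay) * (1 - dynamics$baseDeathRate))^dt

    state <- matrix(0, 7L, nW)
    seedStage <- dynamics$seedStage
    if (is.numeric(seedStage)) {
        for (s in names(seedStage)) {
            b <- match(s, c("egg", NA, "L1", "L2", "L3", "L4", "adult"))
            state[b, ] <- seedStage[[s]]
        }
    } else if (identical(seedStage, "mixed")) {
        per <- dynamics$seedWorms / 5
        base <- floor(per)
        extra <- round((per - base) * 5)
        state[3:7, ] <- base
        if (extra > 0) state[2L + seq_len(extra), ] <-
            state[2L + seq_len(extra), ] + 1
    } else {
        state[3L, ] <- dynamics$seedWorms
    }

    record <- function(day, state) {
        counts <- rbind(egg = state[1L, ] + state[2L, ],
                        state[3:7, , drop = FALSE])
        rownames(counts) <- STAGES
        data.frame(plate_id = layout@plateId, well = w$well, day = day,
                   t(counts), stringsAsFactors = FALSE, check.names = FALSE)
    }
    out <- vector("list", days + 1L)
    out[[1L]] <- record(0, state)

    brood <- dynamics$broodPerAdultPerDay
    K <- dynamics$carryingCapacity
    for (step in seq_len(days * 2L)) {
        # survival
        surv <- stats::rbinom(length(state), as.vector(state),
                              1 - as.vector(pDieStep))
        state <- matrix(surv, 7L, nW)
        # aging: L4 graduates into the absorbing adult pool
        state[7L, ] <- state[7L, ] + state[6L, ]
        state[2:6, ] <- state[1:5, , drop = FALSE]
        state[1L, ] <- 0
        # egg laying under the carrying capacity
        lay <- stats::rpois(nW, state[7L, ] * brood * dt)
        room <- pmax(0, K - colSums(state))
        state[1L, ] <- pmin(lay, room)
        if (step %% 2L == 0L) out[[step %/% 2L + 1L]] <- record(step / 2, state)
    }
    do.call(rbind, out)
}

# expand per-stage counts in a population table into one row per worm,
# returning (rowIndex, stage) for the non-egg stages
expandWorms <- function(states) {
    counts <- as.matrix(states[, LARVAL_STAGES, drop = FALSE])
    n <- as.vector(t(counts))                 # row-major: row1 L1..adult, ...
    stage <- rep(rep(LARVAL_STAGES, nrow(counts)), n)
    rowIdx <- rep(rep(seq_len(nrow(counts)), each = 5L), n)
    list(rowIdx = rowIdx, stage = stage)
}

#' Emit laser-scanning cytometry object events from simulated populations
#'
#' One fluorescent-object event per living worm (larvae and adults; eggs are
#' not emitted) with lognormal area, perimeter and peak intensity drawn from
#' the per-stage optics model, plus Poisson sub-gate debris objects per
#' well.
#'
#' @param states population table from [simulatePopulation()] (any subset of
#'   rows, e.g. one read day).
#' @param optics an [opticsConfig()].
#' @param seed RNG seed (per-plate substreams).
#' @return `data.frame` with columns `plate_id`, `well`, `day`,
#'   `perimeter`, `area`, `peak_intensity`.
#' @export
emitLscEvents <- function(states, optics = opticsConfig(), seed) {
    seed <- checkSeed(seed)
    parts <- lapply(split(states, states$plate_id), function(st) {
        set.seed(deriveSeed(seed, paste0("lsc:", st$plate_id[1L])))
        st <- st[order(st$day, st$well), , drop = FALSE]  # stable order
        ex <- expandWorms(st)
        area <- rlnormMeanCv(length(ex$stage),
                             optics$areaMean[ex$stage],
                             optics$areaCv[ex$stage])
        perim <- rlnormMeanCv(length(ex$stage),
                              optics$perimeterMean[ex$stage],
                              optics$perimeterCv[ex$stage])
        peak <- rlnormMeanCv(length(ex$stage),
                             optics$peakMean[ex$stage],
                             optics$peakCv[ex$stage])
        worms <- data.frame(plate_id = st$plate_id[ex$rowIdx],
                            well = st$well[ex$rowIdx],
                            day = st$day[ex$rowIdx],
                            perimeter = perim, area = area,
                            peak_intensity = peak,
                            stringsAsFactors = FALSE)
        nDebris <- stats::rpois(nrow(st), optics$debrisRate)
        if (sum(nDebris) > 0) {
            di <- rep(seq_len(nrow(st)), nDebris)
            debris <- data.frame(
                plate_id = st$plate_id[di], well = st$well[di],
                day = st$day[di],
                perimeter = rlnormMeanCv(length(di), optics$debrisPerimeter[1],
                                         optics$debrisPerimeter[2]),
                area = rlnormMeanCv(length(di), optics$debrisArea[1],
                                    optics$debrisArea[2]),
                peak_intensity = rlnormMeanCv(length(di), optics$debrisPeak[1],
                                              optics$debrisPeak[2]),
                stringsAsFactors = FALSE)
            worms <- rbind(worms, debris)
        }
        worms
    })
    res <- do.call(rbind, parts)
    rownames(res) <- NULL
    res
}

#' Emit COPAS flow events from simulated populations
#'
#' One (TOF, EC, green) event per living worm (larvae and adults) from the
#' per-stage bivariate lognormal flow model, tagged with the source well.
#'
#' @param states population table from [simulatePopulation()].
#' @param flow a [flowConfig()].
#' @param seed RNG seed.
#' @return `data.frame` with columns `tof`, `ec`, `green`, `source_well`,
#'   `plate_id`, `day`, and the true `stage` (ground-truth link for
#'   recovery tests; drop it to mimic a blinded instrument table).
#' @export
emitCopasEvents <- function(states, flow = flowConfig(), seed) {
    seed <- checkSeed(seed)
    parts <- lapply(split(states, states$plate_id), function(st) {
        set.seed(deriveSeed(seed, paste0("copas:", st$plate_id[1L])))
        st <- st[order(st$day, st$well), , drop = FALSE]
        ex <- expandWorms(st)
        n <- length(ex$stage)
        ev <- data.frame(
            tof = rlnormMeanCv(n, flow$tofMean[ex$stage],
                               flow$tofCv[ex$stage]),
            ec = rlnormMeanCv(n, flow$ecMean[ex$stage],
                              flow$ecCv[ex$stage]),
            green = rlnormMeanCv(n, flow$greenMean[ex$stage],
                                 flow$greenCv[ex$stage]),
            source_well = st$well[ex$rowIdx],
            plate_id = st$plate_id[ex$rowIdx],
            day = st$day[ex$rowIdx],
            stage = ex$stage,
            stringsAsFactors = FALSE)
        if (flow$debrisRate > 0) {
            nd <- stats::rpois(1L, flow$debrisRate)
            if (nd > 0) {
                debris <- data.frame(
                    tof = rlnormMeanCv(nd, 20, 0.5),
                    ec = rlnormMeanCv(nd, 5, 0.5),
                    green = rlnormMeanCv(nd, 10, 0.5),
                    source_well = NA_character_,
                    plate_id = st$plate_id[1L], day = st$day[1L],
                    stage = "debris", stringsAsFactors = FALSE)
                ev <- rbind(ev, debris)
            }
        }
        ev
    })
    res <- do.call(rbind, parts)
    rownames(res) <- NULL
    res
}
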