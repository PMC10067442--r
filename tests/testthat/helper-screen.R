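# shared fixtures, all built in code

# a titration series straight from the 4PL model, optional gaussian noise
makeSeries <- function(conc = 10^seq(-8.5, -4.3, length.out = 7),
                       bottom = 0, top = -100, logEc50 = -6, slope = 1,
                       noiseSd = 0, seed = NULL,
                       compoundId = "x", readout = "gfp_area_total",
                       day = 7) {
    if (!is.null(seed)) set.seed(seed)
    y <- hill4(log10(conc), bottom, top, logEc50, slope)
    if (noiseSd > 0) y <- y + rnorm(length(conc), 0, noiseSd)
    methods::new("TitrationSeries", compoundId = compoundId,
                 readout = readout, day = day, conc = conc, activity = y,
                 n = rep(1L, length(conc)),
                 plateId = sprintf("P%02d", seq_along(conc)))
}

# a minimal single-compound plate set for simulation tests
onePlateLayout <- function(compoundId = "CMPD0001", conc = 1e-5,
                           plateIdLabel = "T01") {
    wells <- wellNames384()
    role <- rep("sample", 384L)
    role[wellColumn384(wells) == 1L] <- "neutral_control"
    role[wellColumn384(wells) == 2L] <- "toxic_control_titration"
    compound <- rep(NA_character_, 384L)
    cc <- rep(0, 384L)
    samp <- wells[wellColumn384(wells) >= 3L]
    compound[match(samp, wells)] <- compoundId
    cc[match(samp, wells)] <- conc
    col2 <- wells[wellColumn384(wells) == 2L]
    compound[match(col2, wells)] <- "CTRL-LEV"
    cc[match(col2, wells)] <- c(rep(10e-3, 8), 10e-3 / 3^(0:7)) / 240
    methods::new("PlateLayout", plateId = plateIdLabel,
                 wells = data.frame(well = wells, role = role,
                                    compound_id = compound, conc_m = cc,
                                    stringsAsFactors = FALSE),
                 readSchedule = c(3, 7))
}

wellColumn384 <- function(well) as.integer(substr(well, 2, 3))

# one-row compound table with explicit pharmacology
oneCompound <- function(id = "CMPD0001", ec50 = 1e-6, hill = 2,
                        efficacy = 1, eggSusc = 0.2) {
    data.frame(compound_id = id, annotation = "test",
               true_ec50_m = ec50, true_hill = hill,
               true_efficacy = efficacy, is_active = efficacy > 0,
               chemotype_cluster = 1L, fingerprint = strrep("0", 16),
               susc_egg = eggSusc, susc_L1 = 1, susc_L2 = 1, susc_L3 = 1,
               susc_L4 = 1, susc_adult = 1, stringsAsFactors = FALSE)
}

# population-state table for event-emission tests
stateRow <- function(well = "C03", day = 7, egg = 0, L1 = 0, L2 = 0,
                     L3 = 0, L4 = 0, adult = 0, plate = "T01") {
    data.frame(plate_id = plate, well = well, day = day, egg = egg,
               L1 = L1, L2 = L2, L3 = L3, L4 = L4, adult = adult,
               stringsAsFactors = FALSE)
}

# the 60-compound demo screen, run once per session and memoised
demoScreenEnv <- new.env(parent = emptyenv())
demoScreen <- function() {
    if (is.null(demoScreenEnv$m)) {
        cfg <- runConfig(seed = 7,
                         outDir = file.path(tempdir(), "demo_screen"))
        demoScreenEnv$m <- runScreen(cfg, quiet = TRUE)
        demoScreenEnv$outDir <- cfg$outDir
    }
    demoScreenEnv$m
}
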