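## End-to-end orchestration: simulate -> gate -> QC -> normalize -> fit ->
## classify -> enrich, with a manifest and reproducible seeds.

#' Run a complete synthetic screen end to end
#'
#' Generates the library and inter-plate titration layouts, simulates the
#' worm populations, emits and gates LSC events at each read day, computes
#' plate QC and percent-activity normalization, assembles titration series,
#' fits four-parameter logistic curves, assigns qHTS curve classes and
#' follow-up priorities, and (when the library carries fingerprints) runs
#' the SOM chemotype-enrichment analysis on the final-day potencies.  All
#' stage tables are written as CSV under `config$outDir` together with a
#' JSON manifest (seed, per-stage row counts, QC summary); rerunning with
#' the same configuration reproduces identical outputs.
#'
#' @param config a [runConfig()].
#' @param quiet suppress per-stage progress lines.
#' @return the manifest list, invisibly; its `tables` entry holds the
#'   in-memory stage results (`library`, `qc`, `wells`, `calls`,
#'   `priority`, `enrichment`, ...).
#' @export
runScreen <- function(config = runConfig(), quiet = FALSE) {
    stopifnot(inherits(config, "RunConfig"))
    scr <- config$screen
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
    t0 <- Sys.time()

    lib <- makeLibrary(scr$n_compounds, scr$active_fraction,
                       scr$chemotype_clusters, seed = config$seed)
    simLib <- rbind(lib, controlCompound(nchar(lib$fingerprint[1L])))
    layouts <- makeInterplateTitration(
        lib, nPoints = scr$n_points, dilutionFactor = scr$dilution_factor,
        topStock = scr$top_stock_m, inWellDilution = scr$in_well_dilution,
        readSchedule = scr$read_days)
    say("simulate: %d compounds over %d plates", nrow(lib), length(layouts))
    writeLibraryCsv(lib, file.path(config$outDir, "library.csv"))
    writeLayoutCsv(layouts, file.path(config$outDir, "layouts.csv"))

    # per-plate simulate/emit/gate/aggregate keeps event tables bounded
    qcRows <- list(); wellRows <- list(); nEvents <- 0L; nGated <- 0L
    for (l in layouts) {
        pop <- simulatePopulation(l, simLib, days = scr$days,
                                  dynamics = config$dynamics,
                                  seed = config$seed)
        for (d in scr$read_days) {
            ev <- emitLscEvents(pop[pop$day == d, , drop = FALSE],
                                optics = config$optics, seed = config$seed)
            gated <- gateObjects(ev, config$gate)
            nEvents <- nEvents + nrow(ev); nGated <- nGated + nrow(gated)
            wells <- aggregateWells(gated, l, day = d)
            for (ro in scr$readouts) {
                st <- controlStats(wells, ro)
                qcRows[[length(qcRows) + 1L]] <- plateQuality(st)
                wellRows[[length(wellRows) + 1L]] <-
                    normalizeWells(wells, st)
            }
        }
    }
    qc <- do.call(rbind, c(qcRows, make.row.names = FALSE))
    normWells <- do.call(rbind, c(wellRows, make.row.names = FALSE))
    say("gate: %d/%d events passed; %d well measures", nGated, nEvents,
        nrow(normWells))
    writeTableCsv(qc, file.path(config$outDir, "plate_qc.csv"))
    writeTableCsv(normWells, file.path(config$outDir, "wells_normalized.csv"))

    series <- assembleSeries(normWells)
    # per-plate activity noise from the neutral controls drives the
    # outlier-masking scale
    neu <- normWells[normWells$role == "neutral_control", , drop = FALSE]
    noiseKey <- paste(neu$plate_id, neu$readout, neu$day)
    noiseTab <- vapply(split(neu$activity_pct, noiseKey), stats::sd, 0)
    fits <- lapply(series, function(s) {
        ns <- mean(noiseTab[paste(s@plateId, s@readout, s@day)],
                   na.rm = TRUE)
        if (!is.finite(ns) || ns <= 0) ns <- NULL
        maskOutliers(s, fitHill(s, config$fit), constraints = config$fit,
                     noiseSd = ns)
    })
    calls <- classifySeries(series, fits, config$thresholds)
    say("fit: %d series, %d active calls", length(series),
        sum(calls$is_active))
    writeTableCsv(seriesTable(series),
                  file.path(config$outDir, "series.csv"))
    writeTableCsv(calls, file.path(config$outDir, "curve_classes.csv"))

    readout0 <- scr$readouts[1L]
    dayLast <- max(scr$read_days)
    dayFirst <- min(scr$read_days)
    pri <- prioritize(
        calls[calls$readout == readout0 & calls$day == dayFirst, ],
        calls[calls$readout == readout0 & calls$day == dayLast, ])
    writeTableCsv(pri, file.path(config$outDir, "priority.csv"))

    enrichment <- NULL
    som <- NULL
    if (all(nchar(lib$fingerprint) > 0)) {
        som <- trainSom(fingerprintMatrix(lib), config$som$rows,
                        config$som$cols, config$som$epochs,
                        seed = config$seed)
        d7 <- calls[calls$readout == readout0 & calls$day == dayLast, ]
        logAc50 <- ifelse(d7$is_active, log10(d7$ec50_m), NA_real_)
        names(logAc50) <- d7$compound_id
        topConc <- scr$top_stock_m / scr$in_well_dilution
        pot <- imputePotency(logAc50[lib$compound_id], topConc)
        names(pot) <- lib$compound_id
        enrichment <- clusterEnrichment(som, pot,
                                        day = paste0("day", dayLast))
        writeTableCsv(enrichment,
                      file.path(config$outDir, "enrichment.csv"))
        say("enrich: %d occupied clusters, %d at p < 0.05",
            nrow(enrichment),
            sum(enrichment$p < 0.05, na.rm = TRUE))
    }

    manifest <- list(
        package = as.character(utils::packageVersion("wormQHTS")),
        seed = config$seed,
        n_compounds = nrow(lib), n_plates = length(layouts),
        n_events = nEvents, n_gated = nGated,
        n_well_measures = nrow(normWells), n_series = length(series),
        n_points = sum(vapply(series, function(s) length(s@conc), 0L)),
        n_active_calls = sum(calls$is_active),
        n_clusters = if (is.null(enrichment)) NA_integer_
                     else nrow(enrichment),
        qc_median_zprime = stats::median(qc$z_prime, na.rm = TRUE))
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("done in %.1f s", as.numeric(difftime(Sys.time(), t0,
                                              units = "secs")))
    manifest$tables <- list(library = lib, qc = qc, wells = normWells,
                            series = series, fits = fits, calls = calls,
                            priority = pri, som = som,
                            enrichment = enrichment)
    invisible(manifest)
}

#' Validate screen input CSVs
#'
#' Schema checks on library, layout and event tables: required headers,
#' well-name grammar (A01-P24), role vocabulary, concentration positivity,
#' fingerprint alphabet and numeric event features.  Violations are
#' collected with line numbers (header = line 1), never thrown.
#'
#' @param paths named list or vector with any of `library`, `layout`,
#'   `events` paths.
#' @return `data.frame` report: `file`, `line`, `message`; zero rows when
#'   everything is clean.
#' @export
validateInputs <- function(paths) {
    paths <- as.list(paths)
    bad <- list()
    note <- function(file, line, msg)
        bad[[length(bad) + 1L]] <<- data.frame(
            file = file, line = line, message = msg,
            stringsAsFactors = FALSE)

    if (!is.null(paths$layout)) {
        f <- paths$layout
        if (!file.exists(f)) note(f, NA_integer_, "file not found")
        else {
            x <- utils::read.csv(f, stringsAsFactors = FALSE)
            need <- c("plate_id", "well", "role", "compound_id", "conc_m")
            miss <- setdiff(need, names(x))
            if (length(miss))
                note(f, 1L, paste("missing column(s):",
                                  paste(miss, collapse = ", ")))
            else {
                ln <- seq_len(nrow(x)) + 1L
                okWell <- grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", x$well)
                for (i in which(!okWell))
                    note(f, ln[i], paste("malformed well name:", x$well[i]))
                for (i in which(!x$role %in% WELL_ROLES))
                    note(f, ln[i], paste("unknown role:", x$role[i]))
                for (i in which(!is.na(x$conc_m) & x$conc_m < 0))
                    note(f, ln[i], "negative concentration")
            }
        }
    }
    if (!is.null(paths$library)) {
        f <- paths$library
        if (!file.exists(f)) note(f, NA_integer_, "file not found")
        else {
            x <- utils::read.csv(f, stringsAsFactors = FALSE,
                                 colClasses = c(fingerprint = "character"))
            need <- c("compound_id", "annotation", "true_ec50_m",
                      "true_hill", "true_efficacy", "fingerprint")
            miss <- setdiff(need, names(x))
            if (length(miss))
                note(f, 1L, paste("missing column(s):",
                                  paste(miss, collapse = ", ")))
            else {
                ln <- seq_len(nrow(x)) + 1L
                for (i in which(!is.na(x$true_ec50_m) & x$true_ec50_m <= 0))
                    note(f, ln[i], "true_ec50_m must be positive")
                for (i in which(x$true_efficacy < 0 | x$true_efficacy > 1))
                    note(f, ln[i], "true_efficacy outside [0, 1]")
                for (i in which(grepl("[^01]", x$fingerprint)))
                    note(f, ln[i], "fingerprint contains non-0/1 characters")
                if (length(unique(nchar(x$fingerprint))) > 1L)
                    note(f, 1L, "fingerprints differ in length")
            }
        }
    }
    if (!is.null(paths$events)) {
        f <- paths$events
        if (!file.exists(f)) note(f, NA_integer_, "file not found")
        else {
            x <- utils::read.csv(f, stringsAsFactors = FALSE)
            need <- c("well", "perimeter", "area", "peak_intensity")
            miss <- setdiff(need, names(x))
            if (length(miss))
                note(f, 1L, paste("missing column(s):",
                                  paste(miss, collapse = ", ")))
            else {
                ln <- seq_len(nrow(x)) + 1L
                for (col in c("perimeter", "area", "peak_intensity"))
                    for (i in which(!is.na(x[[col]]) & x[[col]] < 0))
                        note(f, ln[i], paste("negative", col))
                okWell <- grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", x$well)
                for (i in which(!okWell))
                    note(f, ln[i], paste("malformed well name:", x$well[i]))
            }
        }
    }
    if (!length(bad))
        return(data.frame(file = character(), line = integer(),
                          message = character(), stringsAsFactors = FALSE))
    do.call(rbind, c(bad, make.row.names = FALSE))
}
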