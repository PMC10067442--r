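## Plain-CSV interchange for libraries, layouts, events and results, and
## the YAML run configuration.

#' Read and write screen tables
#'
#' Thin CSV wrappers with the documented headers: library tables
#' (`compound_id`, `annotation`, `true_ec50_m`, `true_hill`,
#' `true_efficacy`, `fingerprint`, ...), plate layouts (`plate_id`,
#' `well`, `role`, `compound_id`, `conc_m`), event tables and per-well
#' measure tables.  `readLayoutCsv()` returns a list of
#' [PlateLayout-class] objects; `writeLayoutCsv()` flattens one.
#'
#' @param path CSV file path.
#' @param x table (or list of layouts) to write.
#' @param readSchedule read days attached to layouts read from CSV.
#' @return the table, or (for writers) the path, invisibly.
#' @name screen-io
NULL

#' @rdname screen-io
#' @export
readLibraryCsv <- function(path) {
    lib <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(fingerprint = "character"))
    need <- c("compound_id", "annotation", "true_ec50_m", "true_hill",
              "true_efficacy", "fingerprint")
    miss <- setdiff(need, names(lib))
    if (length(miss))
        stop("library CSV lacks column(s): ", paste(miss, collapse = ", "))
    lib
}

#' @rdname screen-io
#' @export
writeLibraryCsv <- function(x, path) {
    utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' @rdname screen-io
#' @export
writeLayoutCsv <- function(x, path) {
    if (methods::is(x, "PlateLayout")) x <- list(x)
    flat <- do.call(rbind, lapply(x, function(l)
        cbind(plate_id = plateId(l), layoutWells(l))))
    utils::write.csv(flat, path, row.names = FALSE)
    invisible(path)
}

#' @rdname screen-io
#' @export
readLayoutCsv <- function(path, readSchedule = c(3, 7)) {
    flat <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("plate_id", "well", "role", "compound_id", "conc_m")
    miss <- setdiff(need, names(flat))
    if (length(miss))
        stop("layout CSV lacks column(s): ", paste(miss, collapse = ", "))
    lapply(split(flat, flat$plate_id), function(p)
        methods::new("PlateLayout", plateId = p$plate_id[1L],
                     wells = p[, c("well", "role", "compound_id", "conc_m")],
                     readSchedule = as.numeric(readSchedule)))
}

#' @rdname screen-io
#' @export
readEventsCsv <- function(path) {
    ev <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("well", "perimeter", "area", "peak_intensity")
    miss <- setdiff(need, names(ev))
    if (length(miss))
        stop("event CSV lacks column(s): ", paste(miss, collapse = ", "))
    ev
}

#' @rdname screen-io
#' @export
writeTableCsv <- function(x, path) {
    utils::write.csv(x, path, row.names = FALSE)
    invisible(path)
}

#' Read a YAML run configuration
#'
#' Single YAML document with optional sections `screen` (library size,
#' active fraction, titration design, seed), `dynamics`, `optics`, `flow`,
#' `gate`, `fit`, `thresholds` and `som`; every value omitted falls back
#' to the package default.  See [runConfig()] for the resulting structure.
#'
#' @param path YAML file path.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(runConfig, y)
}

#' Build a run configuration
#'
#' @param screen named list overriding screen-level defaults
#'   (`n_compounds`, `active_fraction`, `chemotype_clusters`, `n_points`,
#'   `dilution_factor`, `top_stock_m`, `in_well_dilution`, `days`,
#'   `read_days`, `readouts`).
#' @param dynamics,optics,flow,gate,fit,thresholds,som named lists of
#'   overrides for the corresponding stage configurations.
#' @param seed integer seed recorded in every output.
#' @param outDir output directory for [runScreen()].
#' @return a `RunConfig` list.
#' @export
runConfig <- function(screen = list(), dynamics = list(), optics = list(),
                      flow = list(), gate = list(), fit = list(),
                      thresholds = list(), som = list(), seed = 1,
                      outDir = tempfile("qhts_run_")) {
    scr <- utils::modifyList(list(
        n_compounds = 60L, active_fraction = 0.13, chemotype_clusters = 10L,
        n_points = 7L, dilution_factor = 5, top_stock_m = 10e-3,
        in_well_dilution = 240, days = 7L, read_days = c(3, 7),
        readouts = c("gfp_area_total", "worm_number")), screen)
    structure(list(screen = scr,
                   dynamics = do.call(dynamicsConfig, dynamics),
                   optics = do.call(opticsConfig, optics),
                   flow = do.call(flowConfig, flow),
                   gate = do.call(gateSpec, gate),
                   fit = do.call(fitConstraints, fit),
                   thresholds = do.call(classThresholds, thresholds),
                   som = utils::modifyList(
                       list(rows = NULL, cols = NULL, epochs = 20), som),
                   seed = checkSeed(seed), outDir = outDir),
              class = "RunConfig")
}
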