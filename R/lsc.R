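## Object gating and per-well aggregation of laser-scanning cytometry
## events into the two screen readouts: total GFP area and worm number.

#' Default object gate
#'
#' The published screening filters: perimeter 100-2200, area 1000-180000,
#' peak intensity 150-1500, all intervals closed on both ends.
#'
#' @param perimeterRange,areaRange,peakIntensityRange closed `c(min, max)`
#'   intervals.
#' @return a [GateSpec-class].
#' @export
gateSpec <- function(perimeterRange = c(100, 2200),
                     areaRange = c(1000, 180000),
                     peakIntensityRange = c(150, 1500)) {
    methods::new("GateSpec", perimeterRange = as.numeric(perimeterRange),
                 areaRange = as.numeric(areaRange),
                 peakIntensityRange = as.numeric(peakIntensityRange))
}

#' Gate object events
#'
#' Keeps exactly the events whose perimeter, area and peak intensity all lie
#' inside the gate's closed intervals; input order is preserved.  Gating is
#' idempotent, and widening any bound can only keep more events.
#'
#' @param events `data.frame` with columns `perimeter`, `area`,
#'   `peak_intensity` (other columns pass through).
#' @param gate a [GateSpec-class].
#' @return the gated subset of `events`.
#' @examples
#' ev <- data.frame(perimeter = c(500, 500), area = c(5000, 999),
#'                  peak_intensity = c(300, 300))
#' nrow(gateObjects(ev, gateSpec()))
#' @export
gateObjects <- function(events, gate = gateSpec()) {
    stopifnot(all(c("perimeter", "area", "peak_intensity") %in%
                  names(events)))
    methods::validObject(gate)
    keep <- events$perimeter >= gate@perimeterRange[1] &
        events$perimeter <= gate@perimeterRange[2] &
        events$area >= gate@areaRange[1] &
        events$area <= gate@areaRange[2] &
        events$peak_intensity >= gate@peakIntensityRange[1] &
        events$peak_intensity <= gate@peakIntensityRange[2]
    events[keep, , drop = FALSE]
}

#' Aggregate gated events into per-well readouts
#'
#' One row per layout well: `gfp_area_total` is the summed area of gated
#' events in the well and `worm_number` their count; wells without events
#' get 0/0.  Role, compound and concentration are joined from the layout.
#'
#' @param gated gated event table (see [gateObjects()]); must only contain
#'   wells present in `layout`.
#' @param layout a [PlateLayout-class].
#' @param day day index recorded on the output (events from other days are
#'   excluded if the table carries a `day` column).
#' @return `data.frame` with columns `plate_id`, `well`, `day`, `role`,
#'   `compound_id`, `conc_m`, `gfp_area_total`, `worm_number`.
#' @export
aggregateWells <- function(gated, layout, day) {
    w <- layoutWells(layout)
    if ("day" %in% names(gated)) gated <- gated[gated$day == day, ,
                                                drop = FALSE]
    if ("plate_id" %in% names(gated))
        gated <- gated[gated$plate_id == plateId(layout), , drop = FALSE]
    bad <- setdiff(unique(gated$well), w$well)
    if (length(bad))
        stop("event(s) reference unknown well(s): ",
             paste(bad, collapse = ", "))
    f <- factor(gated$well, levels = w$well)
    cnt <- as.integer(table(f))
    area <- stats::setNames(rep(0, nrow(w)), w$well)
    if (nrow(gated)) {
        s <- tapply(gated$area, f, sum, default = 0)
        s[is.na(s)] <- 0
        area[names(s)] <- s
    }
    data.frame(plate_id = plateId(layout), well = w$well, day = day,
               role = w$role, compound_id = w$compound_id,
               conc_m = w$conc_m,
               gfp_area_total = as.numeric(area), worm_number = cnt,
               stringsAsFactors = FALSE)
}
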