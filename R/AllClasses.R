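#' @import methods
NULL

STAGES <- c("egg", "L1", "L2", "L3", "L4", "adult")
LARVAL_STAGES <- c("L1", "L2", "L3", "L4", "adult")
WELL_ROLES <- c("sample", "neutral_control", "toxic_control_titration",
                "internal_control")

#' Plate layout for a 384-well screening plate
#'
#' Maps each of the 384 wells (rows A-P, columns 01-24) to a role, a
#' compound and a final in-well concentration.  Column 1 carries the DMSO
#' neutral control (concentration 0); column 2 carries the toxic-control
#' compound, eight wells at a fixed full-kill concentration and eight wells
#' as a 1:3 titration.  Columns 3-24 are sample wells.
#'
#' @slot plateId single plate identifier.
#' @slot wells `data.frame` with columns `well`, `role`, `compound_id`,
#'   `conc_m` (final molar concentration; 0 and `NA` compound for empty or
#'   neutral wells), one row per well, all 384 wells present exactly once.
#' @slot readSchedule integer days on which the plate is read.
#' @export
setClass("PlateLayout",
    representation(plateId = "character", wells = "data.frame",
                   readSchedule = "numeric"))

setValidity("PlateLayout", function(object) {
    w <- object@wells
    msg <- character()
    need <- c("well", "role", "compound_id", "conc_m")
    if (!all(need %in% names(w)))
        return(paste("wells must have columns", paste(need, collapse = ", ")))
    if (nrow(w) != 384L) msg <- c(msg, "a plate layout must have 384 wells")
    if (anyDuplicated(w$well)) msg <- c(msg, "duplicated well names")
    bad <- !grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", w$well)
    if (any(bad))
        msg <- c(msg, paste("malformed well names:",
                            paste(utils::head(w$well[bad], 3), collapse = ", ")))
    if (!all(w$role %in% WELL_ROLES))
        msg <- c(msg, "unknown well role")
    neu <- w$role == "neutral_control"
    if (any(neu) && any(w$conc_m[neu] != 0))
        msg <- c(msg, "neutral_control wells must have concentration 0")
    if (any(!is.na(w$conc_m) & w$conc_m < 0))
        msg <- c(msg, "negative concentration")
    if (length(object@plateId) != 1L) msg <- c(msg, "plateId must be length 1")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Object-gating window for laser-scanning cytometry events
#'
#' Closed intervals on perimeter, area and peak intensity; an object is a
#' worm iff all three features fall inside their interval.  Defaults are the
#' screening filters: perimeter 100-2200, area 1000-180000, peak intensity
#' 150-1500.
#'
#' @slot perimeterRange,areaRange,peakIntensityRange numeric length-2
#'   `c(min, max)` closed intervals.
#' @export
setClass("GateSpec",
    representation(perimeterRange = "numeric", areaRange = "numeric",
                   peakIntensityRange = "numeric"))

setValidity("GateSpec", function(object) {
    for (s in c("perimeterRange", "areaRange", "peakIntensityRange")) {
        r <- slot(object, s)
        if (length(r) != 2L || anyNA(r)) return(paste(s, "must be c(min, max)"))
        if (r[1] > r[2]) return(paste(s, "has min > max"))
    }
    TRUE
})

#' Control-well summary statistics for one plate and readout
#'
#' Means and sample standard deviations (n-1 denominator) of the raw
#' readout over the neutral (DMSO) and positive (full-kill toxic control)
#' wells, used for plate quality statistics and percent-activity
#' normalization.
#'
#' @slot muNeutral,sigmaNeutral,muPositive,sigmaPositive readout-unit
#'   summaries of the two control sets.
#' @slot nNeutral,nPositive control well counts (each at least 2).
#' @slot readout readout name the statistics were computed on.
#' @slot plateId,day provenance.
#' @export
setClass("ControlStats",
    representation(muNeutral = "numeric", sigmaNeutral = "numeric",
                   muPositive = "numeric", sigmaPositive = "numeric",
                   nNeutral = "integer", nPositive = "integer",
                   readout = "character", plateId = "character",
                   day = "numeric"))

setValidity("ControlStats", function(object) {
    if (object@nNeutral < 2L || object@nPositive < 2L)
        return("at least 2 neutral and 2 positive control wells are required")
    TRUE
})

#' One compound's titration series
#'
#' Ordered (concentration, percent activity) points for one compound,
#' readout and day, with per-point provenance and replicate counts.
#'
#' @slot compoundId,readout character scalars; @slot day numeric day index.
#' @slot conc strictly increasing final molar concentrations.
#' @slot activity percent activity on the 0/-100 control scale.
#' @slot n replicate wells averaged into each point.
#' @slot plateId plate of origin per point.
#' @export
setClass("TitrationSeries",
    representation(compoundId = "character", readout = "character",
                   day = "numeric", conc = "numeric", activity = "numeric",
                   n = "integer", plateId = "character"))

setValidity("TitrationSeries", function(object) {
    k <- length(object@conc)
    if (k < 2L) return("a titration series needs at least 2 points")
    if (length(object@activity) != k || length(object@n) != k)
        return("conc, activity and n must have equal length")
    if (any(diff(object@conc) <= 0))
        return("concentrations must be strictly increasing")
    if (any(object@conc <= 0)) return("concentrations must be positive")
    TRUE
})

#' Four-parameter logistic (Hill) fit of a titration series
#'
#' Model: activity = bottom + (top - bottom) /
#' (1 + 10^((log_ec50 - log10(conc)) * hill_slope)).  `bottom` is the
#' zero-dose asymptote and `top` the high-dose asymptote (the slope is kept
#' positive, so a loss-of-signal curve has top < bottom; the constrained
#' three-parameter fallback fixes the high-dose plateau at -100, full kill).
#'
#' @slot bottom,top percent-activity asymptotes.
#' @slot logEc50 log10 molar midpoint; @slot hillSlope dimensionless slope.
#' @slot r2 coefficient of determination on unmasked points.
#' @slot converged whether least squares converged.
#' @slot maskedPoints indices of points excluded as outliers.
#' @slot extrapolated TRUE when the fitted EC50 lies outside the tested
#'   concentration range.
#' @slot nParams 4 for the full model, 3 for the constrained fallback.
#' @slot message diagnostic string for non-convergence.
#' @export
setClass("HillFit",
    representation(bottom = "numeric", top = "numeric", logEc50 = "numeric",
                   hillSlope = "numeric", r2 = "numeric",
                   converged = "logical", maskedPoints = "integer",
                   extrapolated = "logical", nParams = "integer",
                   message = "character"))

#' qHTS curve class assignment
#'
#' @slot cc numeric curve class: +/-1.1, +/-1.2, +/-2.1, +/-2.2, +/-3, or 4
#'   (negative = loss of signal).  Class 4 is always inactive.
#' @slot efficacy percent response span realized inside the tested range.
#' @slot isActive active call (classes -1.1, -1.2, -2.1, -2.2, -3 for a
#'   loss-of-signal screen).
#' @slot reason short code explaining the assignment.
#' @export
setClass("CurveClass",
    representation(cc = "numeric", efficacy = "numeric",
                   isActive = "logical", reason = "character"))

setValidity("CurveClass", function(object) {
    ok <- c(1.1, 1.2, 2.1, 2.2, 3)
    if (!(object@cc %in% c(ok, -ok, 4))) return("invalid curve class")
    if (object@cc == 4 && object@isActive) return("class 4 cannot be active")
    TRUE
})

#' Trained self-organizing map over compound fingerprints
#'
#' @slot somRows,somCols grid dimensions.
#' @slot codebook (somRows*somCols) x nBits matrix of unit weight vectors,
#'   unit index running column-fastest within rows (unit = (row-1)*cols+col).
#' @slot assignment integer unit index per compound.
#' @slot compoundIds compound identifier per assignment entry.
#' @export
setClass("SomGrid",
    representation(somRows = "integer", somCols = "integer",
                   codebook = "matrix", assignment = "integer",
                   compoundIds = "character"))

setValidity("SomGrid", function(object) {
    g <- object@somRows * object@somCols
    if (nrow(object@codebook) != g)
        return("codebook must have one row per grid unit")
    if (any(!is.finite(object@codebook)))
        return("codebook weights must be finite")
    if (length(object@assignment) != length(object@compoundIds))
        return("assignment and compoundIds lengths differ")
    if (length(object@assignment) &&
        (min(object@assignment) < 1L || max(object@assignment) > g))
        return("assignment indices outside the grid")
    TRUE
})
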