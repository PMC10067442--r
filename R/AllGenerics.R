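#' Accessors for wormQHTS classes
#'
#' Small accessor generics: `plateId()`, `layoutWells()`, `ec50()`,
#' `curveClass()`, `isActive()`, `somAssignment()`, `unitLabels()`.
#'
#' @param object an object of the documented class.
#' @return the slot contents (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))
#' @rdname accessors
#' @export
setGeneric("layoutWells", function(object) standardGeneric("layoutWells"))
#' @rdname accessors
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))
#' @rdname accessors
#' @export
setGeneric("curveClass", function(object) standardGeneric("curveClass"))
#' @rdname accessors
#' @export
setGeneric("isActive", function(object) standardGeneric("isActive"))
#' @rdname accessors
#' @export
setGeneric("somAssignment", function(object) standardGeneric("somAssignment"))
#' @rdname accessors
#' @export
setGeneric("unitLabels", function(object) standardGeneric("unitLabels"))

#' @rdname accessors
#' @export
setMethod("plateId", "PlateLayout", function(object) object@plateId)

#' @rdname accessors
#' @export
setMethod("layoutWells", "PlateLayout", function(object) object@wells)

#' @rdname accessors
#' @export
setMethod("ec50", "HillFit", function(object) 10^object@logEc50)

#' @rdname accessors
#' @export
setMethod("curveClass", "CurveClass", function(object) object@cc)

#' @rdname accessors
#' @export
setMethod("isActive", "CurveClass", function(object) object@isActive)

#' @rdname accessors
#' @export
setMethod("somAssignment", "SomGrid", function(object) {
    structure(object@assignment, names = object@compoundIds)
})

#' @rdname accessors
#' @export
setMethod("unitLabels", "SomGrid", function(object) {
    idx <- seq_len(object@somRows * object@somCols)
    row <- (idx - 1L) %/% object@somCols + 1L
    col <- (idx - 1L) %% object@somCols + 1L
    paste0("k", row, ".", col)
})

setMethod("show", "PlateLayout", function(object) {
    w <- object@wells
    cat("PlateLayout", object@plateId, "(384 wells)\n")
    print(table(w$role))
    cat("compounds:", length(unique(stats::na.omit(w$compound_id))), "\n")
})

setMethod("show", "GateSpec", function(object) {
    cat("GateSpec: perimeter [", object@perimeterRange[1], ",",
        object@perimeterRange[2], "], area [", object@areaRange[1], ",",
        object@areaRange[2], "], peak intensity [",
        object@peakIntensityRange[1], ",", object@peakIntensityRange[2],
        "]\n")
})

setMethod("show", "ControlStats", function(object) {
    cat(sprintf(
        "ControlStats %s day %g [%s]: neutral %.4g +/- %.4g (n=%d), positive %.4g +/- %.4g (n=%d)\n",
        object@plateId, object@day, object@readout, object@muNeutral,
        object@sigmaNeutral, object@nNeutral, object@muPositive,
        object@sigmaPositive, object@nPositive))
})

setMethod("show", "TitrationSeries", function(object) {
    cat(sprintf("TitrationSeries %s [%s, day %g]: %d points, %.3g-%.3g M\n",
                object@compoundId, object@readout, object@day,
                length(object@conc), min(object@conc), max(object@conc)))
})

setMethod("show", "HillFit", function(object) {
    if (!object@converged) {
        cat("HillFit: not converged (", object@message, ")\n")
        return(invisible(NULL))
    }
    cat(sprintf(
        "HillFit: bottom %.1f%%, top %.1f%%, EC50 %.3g M, slope %.2f, r2 %.3f%s\n",
        object@bottom, object@top, 10^object@logEc50, object@hillSlope,
        object@r2,
        if (length(object@maskedPoints))
            paste0(" (", length(object@maskedPoints), " masked)") else ""))
})

setMethod("show", "CurveClass", function(object) {
    cat(sprintf("CurveClass %s (efficacy %.1f%%, %s)\n",
                format(object@cc), object@efficacy,
                if (object@isActive) "active" else "inactive"))
})

setMethod("show", "SomGrid", function(object) {
    cat(sprintf("SomGrid %dx%d, %d compounds, %d occupied units\n",
                object@somRows, object@somCols, length(object@assignment),
                length(unique(object@assignment))))
})
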