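## Life-stage classification of COPAS flow events by rectangular TOF x EC
## gates, and binning of stage distributions for heat-map display.

#' Construct and validate a life-stage gate table
#'
#' Axis-aligned TOF x EC rectangles, one per life stage.  Gates must be
#' pairwise non-overlapping (two rectangles overlap iff both their TOF and
#' EC intervals intersect), so every event lies in at most one gate and the
#' classification is independent of gate order.
#'
#' @param stage character stage labels.
#' @param tofMin,tofMax,ecMin,ecMax numeric gate bounds (closed intervals).
#' @return validated `data.frame` of class `StageGates`.
#' @export
stageGates <- function(stage, tofMin, tofMax, ecMin, ecMax) {
    g <- data.frame(stage = stage, tof_min = tofMin, tof_max = tofMax,
                    ec_min = ecMin, ec_max = ecMax,
                    stringsAsFactors = FALSE)
    if (any(g$tof_min > g$tof_max) || any(g$ec_min > g$ec_max))
        stop("gate ranges must have min <= max")
    if (anyDuplicated(g$stage)) stop("duplicated stage labels")
    n <- nrow(g)
    if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        tofOverlap <- g$tof_min[i] <= g$tof_max[j] &&
            g$tof_min[j] <= g$tof_max[i]
        ecOverlap <- g$ec_min[i] <= g$ec_max[j] &&
            g$ec_min[j] <= g$ec_max[i]
        if (tofOverlap && ecOverlap)
            stop(sprintf("overlapping gates: %s and %s",
                         g$stage[i], g$stage[j]))
    }
    class(g) <- c("StageGates", "data.frame")
    g
}

#' Default life-stage gates
#'
#' Rectangles calibrated against the synthetic flow model of
#' [flowConfig()] (the instrument's own TOF/EC units are protocol-specific
#' and not published, so gates are expressed in the simulated units).
#'
#' @return a [stageGates()] table for L1-adult.
#' @export
defaultStageGates <- function() {
    stageGates(stage = c("L1", "L2", "L3", "L4", "adult"),
               tofMin = c(30, 88, 155, 265, 461),
               tofMax = c(87.9, 154.9, 264.9, 460.9, 1300),
               ecMin = c(8, 33, 70, 145, 291),
               ecMax = c(32.9, 69.9, 144.9, 290.9, 1000))
}

#' Classify flow events into life stages
#'
#' Assigns each event to the unique gate containing its (TOF, EC) point,
#' or to `unclassified`.
#'
#' @param events `data.frame` with columns `tof`, `ec`.
#' @param gates a [stageGates()] table.
#' @param treatment label attached to the returned distribution.
#' @return `StageDistribution`: a list with `treatment`, named `counts` per
#'   gate stage, `unclassified`, and `total` (= sum of counts +
#'   unclassified, always).
#' @export
classifyEvents <- function(events, gates = defaultStageGates(),
                           treatment = "unlabelled") {
    if (!inherits(gates, "StageGates"))
        gates <- stageGates(gates$stage, gates$tof_min, gates$tof_max,
                            gates$ec_min, gates$ec_max)
    assign <- rep(NA_integer_, nrow(events))
    for (i in seq_len(nrow(gates))) {
        inside <- events$tof >= gates$tof_min[i] &
            events$tof <= gates$tof_max[i] &
            events$ec >= gates$ec_min[i] & events$ec <= gates$ec_max[i]
        assign[inside] <- i
    }
    counts <- tabulate(assign, nbins = nrow(gates))
    names(counts) <- gates$stage
    structure(list(treatment = treatment, counts = counts,
                   unclassified = sum(is.na(assign)),
                   total = nrow(events)),
              class = "StageDistribution")
}

#' @export
print.StageDistribution <- function(x, ...) {
    cat("StageDistribution [", x$treatment, "]: ",
        paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
        ", unclassified=", x$unclassified, "\n", sep = "")
    invisible(x)
}

#' Bin stage distributions for a heat-map
#'
#' Maps every (treatment, stage) count onto ordinal bins defined by
#' strictly increasing breakpoints; a count equal to a breakpoint falls in
#' the lower bin, so with breakpoints `c(10, ..., 15000)` a count above
#' 15000 lands in the top bin and one below 10 in the bottom bin.
#'
#' @param dists list of distributions from [classifyEvents()].
#' @param breakpoints strictly increasing counts (k breakpoints define
#'   k+1 bins, labelled 1 = bottom).
#' @return integer matrix of bin labels, one row per treatment (input
#'   order), one column per stage.
#' @export
heatmapMatrix <- function(dists,
                          breakpoints = c(10, 100, 1000, 5000, 15000)) {
    if (length(breakpoints) == 0L) stop("breakpoints must not be empty")
    if (any(diff(breakpoints) <= 0))
        stop("breakpoints must be strictly increasing")
    stages <- names(dists[[1L]]$counts)
    m <- t(vapply(dists, function(d) d$counts[stages],
                  numeric(length(stages))))
    rownames(m) <- vapply(dists, `[[`, "", "treatment")
    colnames(m) <- stages
    # bin = number of breakpoints strictly below the count, + 1
    bins <- matrix(findInterval(m, breakpoints, left.open = TRUE) + 1L,
                   nrow(m), ncol(m), dimnames = dimnames(m))
    bins
}
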