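## qHTS curve classification and follow-up prioritization.

#' Curve classification thresholds
#'
#' The class-assignment rule set, reconstructed from the standard qHTS
#' scheme: class 1 = complete curve with both asymptotes supported by
#' in-range points, class 2 = one asymptote, class 3 = lowest confidence
#' (activity confined to the top tested concentration, or fit quality
#' below the r-squared floor), class 4 = inactive; sub-class .1/.2 splits
#' on the high-efficacy threshold; the sign follows the response direction
#' (negative = signal decrease).
#'
#' @param highEfficacy percent efficacy separating sub-class .1 from .2
#'   (default 80).
#' @param minEfficacy minimum percent efficacy for any active call
#'   (default 30; use `max(30, 3 * sd)` of the neutral-control activity
#'   when control noise is larger).
#' @param r2Floor fit-quality floor separating classes 1-2 from 3
#'   (default 0.9).
#' @param plateauTol asymptote-support tolerance as a fraction of the
#'   response span (default 0.15): a plateau is supported when at least one
#'   point lies within `plateauTol * span` of it.
#' @return a `ClassThresholds` list.
#' @export
classThresholds <- function(highEfficacy = 80, minEfficacy = 30,
                            r2Floor = 0.9, plateauTol = 0.15) {
    structure(list(highEfficacy = highEfficacy, minEfficacy = minEfficacy,
                   r2Floor = r2Floor, plateauTol = plateauTol),
              class = "ClassThresholds")
}

#' Assign a qHTS curve class to a fitted titration series
#'
#' Applies the rule set of [classThresholds()] to a [HillFit-class] and its
#' underlying series.  Efficacy is the response span realized inside the
#' tested concentration range (|fitted(c_max) - fitted(c_min)|).  A series
#' whose response is confined to the highest tested concentration is class
#' 3 even when the sigmoid fit is poor; unclassifiable fits default to
#' class 4 with a reason code.  For this loss-of-signal screen the active
#' classes are -1.1, -1.2, -2.1, -2.2 and -3 (gain-of-signal curves get
#' the mirrored positive classes and are not called active).
#'
#' @param fit a [HillFit-class] (converged or not).
#' @param series the fitted [TitrationSeries-class].
#' @param thresholds a [classThresholds()].
#' @return a [CurveClass-class].
#' @export
classifyCurve <- function(fit, series, thresholds = classThresholds()) {
    th <- thresholds
    act <- series@activity
    keep <- setdiff(seq_along(act), fit@maskedPoints)
    act <- act[keep]
    k <- length(act)

    cls <- function(cc, eff, reason) {
        active <- cc %in% c(-1.1, -1.2, -2.1, -2.2, -3)
        methods::new("CurveClass", cc = cc, efficacy = eff,
                     isActive = active, reason = reason)
    }

    # response confined to the highest tested concentration: class 3 by
    # direct inspection of the data, independent of fit quality
    topOnly <- k >= 2L &&
        all(abs(act[-k]) < th$minEfficacy) && abs(act[k]) >= th$minEfficacy
    if (topOnly)
        return(cls(sign(act[k]) * 3, abs(act[k]), "top_conc_only"))

    if (!fit@converged)
        return(cls(4, 0, "no_fit"))

    logc <- range(log10(series@conc))
    fLow <- hill4(logc[1], fit@bottom, fit@top, fit@logEc50, fit@hillSlope)
    fHigh <- hill4(logc[2], fit@bottom, fit@top, fit@logEc50, fit@hillSlope)
    eff <- abs(fHigh - fLow)
    dirSign <- if (fHigh < fLow) -1 else 1

    if (eff < th$minEfficacy)
        return(cls(4, eff, "below_min_efficacy"))

    span <- abs(fit@top - fit@bottom)
    tol <- th$plateauTol * max(span, 1e-9)
    lowSupported <- any(abs(act - fit@bottom) <= tol)
    highSupported <- any(abs(act - fit@top) <= tol)

    if (fit@r2 < th$r2Floor)
        return(cls(dirSign * 3, eff, "low_r2"))

    sub <- if (eff >= th$highEfficacy) 0.1 else 0.2
    if (lowSupported && highSupported)
        return(cls(dirSign * (1 + sub), eff, "both_asymptotes"))
    if (lowSupported || highSupported)
        return(cls(dirSign * (2 + sub), eff, "one_asymptote"))
    cls(dirSign * 3, eff, "no_asymptote_support")
}

#' Classification table for a set of fitted series
#'
#' @param seriesList list from [assembleSeries()].
#' @param fits matching list of [HillFit-class] objects.
#' @param thresholds a [classThresholds()].
#' @return `data.frame`: `compound_id`, `readout`, `day`, `cc`,
#'   `efficacy_pct`, `ec50_m`, `r2`, `is_active`, `reason`.
#' @export
classifySeries <- function(seriesList, fits,
                           thresholds = classThresholds()) {
    stopifnot(length(seriesList) == length(fits))
    rows <- mapply(function(s, f) {
        cl <- classifyCurve(f, s, thresholds)
        data.frame(compound_id = s@compoundId, readout = s@readout,
                   day = s@day, cc = cl@cc, efficacy_pct = cl@efficacy,
                   ec50_m = if (f@converged) 10^f@logEc50 else NA_real_,
                   r2 = if (f@converged) f@r2 else NA_real_,
                   is_active = cl@isActive, reason = cl@reason,
                   stringsAsFactors = FALSE)
    }, seriesList, fits, SIMPLIFY = FALSE)
    do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Rank compounds for follow-up
#'
#' Combines day-3 and day-7 curve classes with a counter-screen (human
#' cell viability) class: tier 1 = high-quality active classes (-1.1,
#' -1.2, -2.1) on both days; tier 2 = moderate day-3 activity (-2.2 or -3)
#' with day-7 activity; tier 3 = day-7 activity only; tier 4 = everything
#' else.  Within a tier, compounds with a counter-screen class of 4 (no
#' human-cell toxicity) rank above toxic ones; remaining ties break on
#' compound id, giving a deterministic total order.
#'
#' @param callsDay3,callsDay7 classification tables from
#'   [classifySeries()] for one readout (columns `compound_id`, `cc`,
#'   `is_active`).
#' @param counterCalls optional counter-screen table (`compound_id`,
#'   `cc`); compounds absent from it are treated as counter-inactive.
#' @return `data.frame` ordered by rank: `compound_id`, `tier`,
#'   `day3_cc`, `day7_cc`, `counter_cc`, `counter_inactive`, `rank`.
#' @export
prioritize <- function(callsDay3, callsDay7, counterCalls = NULL) {
    ids <- sort(union(callsDay3$compound_id, callsDay7$compound_id))
    cc3 <- callsDay3$cc[match(ids, callsDay3$compound_id)]
    act3 <- callsDay3$is_active[match(ids, callsDay3$compound_id)]
    cc7 <- callsDay7$cc[match(ids, callsDay7$compound_id)]
    act7 <- callsDay7$is_active[match(ids, callsDay7$compound_id)]
    act3[is.na(act3)] <- FALSE; act7[is.na(act7)] <- FALSE
    ccC <- if (is.null(counterCalls)) rep(4, length(ids))
           else counterCalls$cc[match(ids, counterCalls$compound_id)]
    ccC[is.na(ccC)] <- 4

    highQ <- function(cc) !is.na(cc) & cc %in% c(-1.1, -1.2, -2.1)
    moderate <- function(cc) !is.na(cc) & cc %in% c(-2.2, -3)
    tier <- rep(4L, length(ids))
    tier[act7] <- 3L
    tier[moderate(cc3) & act7] <- 2L
    tier[highQ(cc3) & highQ(cc7)] <- 1L
    counterInactive <- ccC == 4

    o <- order(tier, !counterInactive, ids)
    data.frame(compound_id = ids[o], tier = tier[o], day3_cc = cc3[o],
               day7_cc = cc7[o], counter_cc = ccC[o],
               counter_inactive = counterInactive[o],
               rank = seq_along(ids), stringsAsFactors = FALSE)
}
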