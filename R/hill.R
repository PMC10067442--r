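## Titration assembly and four-parameter logistic (Hill) fitting.

#' Assemble per-compound titration series from normalized wells
#'
#' Groups normalized sample wells by (compound, readout, day), averages
#' duplicate concentrations (recording the replicate count), and returns
#' one [TitrationSeries-class] per group with concentrations in strictly
#' increasing order.  Works for inter-plate titrations (one concentration
#' per plate) and intra-plate follow-up titrations alike.  Compounds with
#' fewer than 2 distinct concentrations are excluded with a warning.
#'
#' @param normWells normalized well table from [normalizeWells()]
#'   (rows from several plates/days can be concatenated); only rows with
#'   `role == "sample"` and a non-`NA` compound are used.
#' @return named list of [TitrationSeries-class] objects
#'   (`<compound>|<readout>|day<d>`).
#' @export
assembleSeries <- function(normWells) {
    w <- normWells[normWells$role == "sample" &
                   !is.na(normWells$compound_id) &
                   !is.na(normWells$activity_pct), , drop = FALSE]
    if (!nrow(w)) return(list())
    key <- paste(w$compound_id, w$readout, w$day, sep = "|")
    groups <- split(w, key)
    dropped <- character()
    out <- list()
    for (g in groups) {
        byConc <- split(g, g$conc_m)
        conc <- as.numeric(names(byConc))
        o <- order(conc)
        conc <- conc[o]; byConc <- byConc[o]
        if (length(conc) < 2L) {
            dropped <- c(dropped, g$compound_id[1L])
            next
        }
        nm <- sprintf("%s|%s|day%g", g$compound_id[1L], g$readout[1L],
                      g$day[1L])
        out[[nm]] <- methods::new(
            "TitrationSeries",
            compoundId = g$compound_id[1L], readout = g$readout[1L],
            day = as.numeric(g$day[1L]), conc = conc,
            activity = unname(vapply(byConc,
                                     function(x) mean(x$activity_pct), 0)),
            n = unname(vapply(byConc, nrow, 0L)),
            plateId = unname(vapply(byConc,
                                    function(x) x$plate_id[1L], "")))
    }
    if (length(dropped))
        warning("excluded compound(s) with < 2 distinct concentrations: ",
                paste(unique(dropped), collapse = ", "))
    out
}

#' Flatten a list of titration series to a table
#'
#' @param seriesList list from [assembleSeries()].
#' @return `data.frame` with one row per dose-response point:
#'   `compound_id`, `readout`, `day`, `conc_m`, `activity_pct`, `n`,
#'   `plate_id`.
#' @export
seriesTable <- function(seriesList) {
    do.call(rbind, c(lapply(seriesList, function(s) {
        data.frame(compound_id = s@compoundId, readout = s@readout,
                   day = s@day, conc_m = s@conc, activity_pct = s@activity,
                   n = s@n, plate_id = s@plateId,
                   stringsAsFactors = FALSE)
    }), make.row.names = FALSE))
}

#' Fit constraints for the four-parameter logistic model
#'
#' Box constraints and options honoured by [fitHill()].  `bottom` is the
#' zero-dose asymptote and `top` the high-dose asymptote (the slope is kept
#' positive; a loss-of-signal curve simply has `top < bottom`).
#'
#' @param bottomFixed,topFixed fix an asymptote at a value (`NA` = free).
#' @param slopeBounds `c(min, max)` bounds on the positive Hill slope.
#' @param asymptoteBounds `c(min, max)` bounds on both free asymptotes
#'   (percent activity).
#' @param logEc50Bounds `c(min, max)` bounds on log10 EC50 (`NA` = derive
#'   from the tested range, widened by 2 decades each side).
#' @return a `FitConstraints` list.
#' @export
fitConstraints <- function(bottomFixed = NA_real_, topFixed = NA_real_,
                           slopeBounds = c(0.2, 10),
                           asymptoteBounds = c(-150, 150),
                           logEc50Bounds = c(NA_real_, NA_real_)) {
    structure(list(bottomFixed = bottomFixed, topFixed = topFixed,
                   slopeBounds = slopeBounds,
                   asymptoteBounds = asymptoteBounds,
                   logEc50Bounds = logEc50Bounds),
              class = "FitConstraints")
}

#' Four-parameter logistic response
#'
#' `bottom + (top - bottom) / (1 + 10^((logEc50 - logc) * slope))`:
#' the model curve evaluated at log10 concentration `logc`.
#'
#' @param logc log10 molar concentration(s).
#' @param bottom,top zero-dose and high-dose asymptotes (percent).
#' @param logEc50 log10 molar midpoint; @param slope positive Hill slope.
#' @return fitted percent activity.
#' @export
hill4 <- function(logc, bottom, top, logEc50, slope) {
    bottom + (top - bottom) / (1 + 10^((logEc50 - logc) * slope))
}

# deterministic starting values from the data: asymptotes from the
# extreme-concentration medians, log EC50 from the half-response crossing
hillStarts <- function(logc, y) {
    k <- length(y)
    lowIdx <- seq_len(min(2L, k))
    highIdx <- seq(max(1L, k - 1L), k)
    b0 <- stats::median(y[lowIdx])
    t0 <- stats::median(y[highIdx])
    half <- (b0 + t0) / 2
    cross <- which(diff(sign(y - half)) != 0)
    l0 <- if (length(cross)) mean(logc[c(cross[1L], cross[1L] + 1L)])
          else stats::median(logc)
    list(bottom = b0, top = t0, logEc50 = l0)
}

#' Fit the four-parameter logistic dose-response model
#'
#' Weighted least squares fit of
#' `activity = bottom + (top - bottom) / (1 + 10^((logEC50 - log10 c) * slope))`
#' by Levenberg-Marquardt (via \code{minpack.lm::nlsLM}) with box
#' constraints and a deterministic three-point slope multi-start
#' (0.5, 1, 3) to avoid local minima; points are weighted by their
#' replicate count.  With fewer than 4 unmasked points the model drops to
#' the constrained three-parameter form with the high-dose (full-kill)
#' plateau fixed at -100%.  Non-convergence is reported in the returned
#' object, never as an error.  The fit is invariant to concentration unit
#' rescaling up to the corresponding log EC50 shift.
#'
#' @param series a [TitrationSeries-class].
#' @param constraints a [fitConstraints()].
#' @param masked integer indices of points to exclude (e.g. from
#'   [maskOutliers()]).
#' @return a [HillFit-class]; `r2` is computed on unmasked points and the
#'   fit is flagged `extrapolated` when the EC50 lies outside the tested
#'   concentration range.
#' @examples
#' s <- methods::new("TitrationSeries", compoundId = "x",
#'     readout = "gfp_area_total", day = 7,
#'     conc = 10^seq(-8, -4, length.out = 7),
#'     activity = hill4(seq(-8, -4, length.out = 7), 0, -100, -6, 1),
#'     n = rep(1L, 7), plateId = rep("P", 7))
#' fitHill(s)
#' @export
fitHill <- function(series, constraints = fitConstraints(),
                    masked = integer()) {
    methods::validObject(series)
    masked <- sort(unique(as.integer(masked)))
    keep <- setdiff(seq_along(series@conc), masked)
    logc <- log10(series@conc[keep])
    y <- series@activity[keep]
    wts <- as.numeric(series@n[keep])

    failFit <- function(msg) methods::new(
        "HillFit", bottom = NA_real_, top = NA_real_, logEc50 = NA_real_,
        hillSlope = NA_real_, r2 = NA_real_, converged = FALSE,
        maskedPoints = masked, extrapolated = FALSE, nParams = 0L,
        message = msg)

    if (length(y) < 3L) return(failFit("fewer than 3 unmasked points"))
    if (stats::sd(y) == 0) return(failFit("flat series (zero variance)"))

    reduced <- length(y) < 4L
    st <- hillStarts(logc, y)
    lb <- constraints$logEc50Bounds
    if (is.na(lb[1])) lb[1] <- min(logc) - 2
    if (is.na(lb[2])) lb[2] <- max(logc) + 2
    ab <- constraints$asymptoteBounds
    sb <- constraints$slopeBounds

    best <- NULL
    for (s0 in c(0.5, 1, 3)) {
        fit <- tryCatch({
            if (reduced || !is.na(constraints$topFixed)) {
                topFix <- if (!is.na(constraints$topFixed))
                    constraints$topFixed else -100
                m <- minpack.lm::nlsLM(
                    y ~ hill4(logc, bottom, topFix, logEc50, slope),
                    start = list(bottom = st$bottom,
                                 logEc50 = st$logEc50, slope = s0),
                    lower = c(ab[1], lb[1], sb[1]),
                    upper = c(ab[2], lb[2], sb[2]),
                    weights = wts,
                    control = minpack.lm::nls.lm.control(maxiter = 200))
                p <- stats::coef(m)
                list(bottom = p[["bottom"]], top = topFix,
                     logEc50 = p[["logEc50"]], slope = p[["slope"]],
                     rss = sum(wts * stats::resid(m)^2), np = 3L)
            } else if (!is.na(constraints$bottomFixed)) {
                botFix <- constraints$bottomFixed
                m <- minpack.lm::nlsLM(
                    y ~ hill4(logc, botFix, top, logEc50, slope),
                    start = list(top = st$top, logEc50 = st$logEc50,
                                 slope = s0),
                    lower = c(ab[1], lb[1], sb[1]),
                    upper = c(ab[2], lb[2], sb[2]),
                    weights = wts,
                    control = minpack.lm::nls.lm.control(maxiter = 200))
                p <- stats::coef(m)
                list(bottom = botFix, top = p[["top"]],
                     logEc50 = p[["logEc50"]], slope = p[["slope"]],
                     rss = sum(wts * stats::resid(m)^2), np = 3L)
            } else {
                m <- minpack.lm::nlsLM(
                    y ~ hill4(logc, bottom, top, logEc50, slope),
                    start = list(bottom = st$bottom, top = st$top,
                                 logEc50 = st$logEc50, slope = s0),
                    lower = c(ab[1], ab[1], lb[1], sb[1]),
                    upper = c(ab[2], ab[2], lb[2], sb[2]),
                    weights = wts,
                    control = minpack.lm::nls.lm.control(maxiter = 200))
                p <- stats::coef(m)
                list(bottom = p[["bottom"]], top = p[["top"]],
                     logEc50 = p[["logEc50"]], slope = p[["slope"]],
                     rss = sum(wts * stats::resid(m)^2), np = 4L)
            }
        }, error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$rss < best$rss))
            best <- fit
    }
    if (is.null(best)) return(failFit("least squares did not converge"))

    yhat <- hill4(logc, best$bottom, best$top, best$logEc50, best$slope)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum((y - yhat)^2) / sst else NA_real_
    methods::new("HillFit", bottom = best$bottom, top = best$top,
                 logEc50 = best$logEc50, hillSlope = best$slope, r2 = r2,
                 converged = TRUE, maskedPoints = masked,
                 extrapolated = best$logEc50 < log10(min(series@conc)) ||
                     best$logEc50 > log10(max(series@conc)),
                 nParams = best$np, message = "")
}

#' Iterative single-point outlier masking
#'
#' Masks the single worst point whose externally studentized residual
#' exceeds `threshold`, then refits; repeats until no point exceeds the
#' threshold or the mask cap is reached (default 2 points on a 7-point
#' series, scaled as `max(0, min(maxMasked, n - 5))` so short series are
#' never over-masked).
#'
#' Each candidate is studentized against a fit with that point *left out*:
#' with only 7 points and 4 parameters, ordinary least squares absorbs
#' much of a spike into the parameters and dilutes its own residual,
#' whereas the held-out prediction error exposes it.  The prediction-error
#' variance is leverage-corrected (`sigma^2 * (1 + v_i)` with `v_i` from
#' the fit Jacobian).  The noise scale `sigma` should be supplied as
#' `noiseSd`, the activity noise known from the plate's neutral-control
#' wells -- a 7-point series leaves only 2 residual degrees of freedom, too
#' few for a stable internal estimate.  Without `noiseSd` the scale falls
#' back to the leave-one-out residual SD and the threshold is raised to
#' the matching t quantile, which makes series-internal masking
#' deliberately conservative.
#'
#' @param series a [TitrationSeries-class].
#' @param fit an initial [fitHill()] result.
#' @param threshold studentized-residual multiple (default 3).
#' @param constraints passed through to [fitHill()].
#' @param maxMasked cap on masked points.
#' @param noiseSd known per-point activity noise SD (percent), typically
#'   the neutral-control activity SD of the contributing plates.
#' @return the final [HillFit-class] with `maskedPoints` filled in.
#' @export
maskOutliers <- function(series, fit = fitHill(series, constraints),
                         threshold = 3, constraints = fitConstraints(),
                         maxMasked = 2L, noiseSd = NULL) {
    cap <- max(0L, min(as.integer(maxMasked), length(series@conc) - 5L))
    masked <- fit@maskedPoints
    repeat {
        if (!fit@converged || length(masked) >= cap) return(fit)
        keep <- setdiff(seq_along(series@conc), masked)
        resFull <- series@activity[keep] -
            hill4(log10(series@conc[keep]), fit@bottom, fit@top,
                  fit@logEc50, fit@hillSlope)
        best <- NULL
        for (i in keep) {
            fi <- fitHill(series, constraints, masked = c(masked, i))
            if (!fi@converged) next
            rest <- setdiff(keep, i)
            resRest <- series@activity[rest] -
                hill4(log10(series@conc[rest]), fi@bottom, fi@top,
                      fi@logEc50, fi@hillSlope)
            dfree <- length(rest) - fi@nParams
            if (dfree < 1L) next
            lev <- predictionLeverage(fi, series@conc[rest],
                                      series@conc[i])
            e <- series@activity[i] -
                hill4(log10(series@conc[i]), fi@bottom, fi@top,
                      fi@logEc50, fi@hillSlope)
            if (is.null(noiseSd)) {
                # floor the unstable 2-df scale with a robust full-fit one
                sigma <- max(sqrt(sum(resRest^2) / dfree),
                             stats::mad(resFull))
                thr <- max(threshold, stats::qt(0.995, dfree))
            } else {
                sigma <- noiseSd
                thr <- threshold
            }
            if (sigma <= 0) next
            stud <- abs(e) / (sigma * sqrt(1 + lev))
            if (is.null(best) || stud - best$stud > 1e-12)
                best <- list(i = i, stud = stud, fit = fi, thr = thr)
        }
        if (is.null(best) || best$stud <= best$thr) return(fit)
        masked <- sort(c(masked, best$i))
        fit <- best$fit
    }
}

# prediction leverage of a held-out concentration under a 4PL fit:
# g' (J'J)^{-1} g with J the Jacobian at the fitted parameters over the
# points used in the fit
predictionLeverage <- function(fit, concRest, concHeld) {
    p0 <- c(bottom = fit@bottom, top = fit@top, logEc50 = fit@logEc50,
            slope = fit@hillSlope)
    free <- if (fit@nParams == 3L) c("bottom", "logEc50", "slope")
            else names(p0)
    jac <- function(conc) {
        logc <- log10(conc)
        vapply(free, function(nm) {
            eps <- max(1e-6, abs(p0[[nm]]) * 1e-6)
            up <- p0; up[nm] <- up[nm] + eps
            dn <- p0; dn[nm] <- dn[nm] - eps
            (hill4(logc, up[["bottom"]], up[["top"]], up[["logEc50"]],
                   up[["slope"]]) -
             hill4(logc, dn[["bottom"]], dn[["top"]], dn[["logEc50"]],
                   dn[["slope"]])) / (2 * eps)
        }, numeric(length(conc)))
    }
    J <- matrix(jac(concRest), ncol = length(free))
    g <- matrix(jac(concHeld), ncol = length(free))
    v <- tryCatch(as.numeric(g %*% solve(crossprod(J), t(g))),
                  error = function(e) 1)
    if (!is.finite(v) || v < 0) v <- 1
    v
}
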