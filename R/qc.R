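## Plate quality statistics (S/B, S/N, Z') from control wells and
## percent-activity normalization on the 0 / -100 control scale.

#' Control-well statistics for one plate, day and readout
#'
#' Means and sample standard deviations (n-1 denominator) of the raw
#' readout over (i) the neutral DMSO wells and (ii) the positive-control
#' wells, i.e. the toxic-control wells at the single full-kill
#' concentration (the maximum concentration of the toxic-control role; the
#' intra-plate 1:3 control titration wells are excluded).
#'
#' @param wells per-well table from [aggregateWells()] for one plate and
#'   day (a `role` column is required).
#' @param readout readout column name (`"gfp_area_total"` or
#'   `"worm_number"`).
#' @return a [ControlStats-class].
#' @export
controlStats <- function(wells, readout = "gfp_area_total") {
    stopifnot(readout %in% names(wells))
    pid <- unique(wells$plate_id)
    day <- unique(wells$day)
    if (length(pid) != 1L || length(day) != 1L)
        stop("controlStats expects wells from a single plate and day")
    neu <- wells[wells$role == "neutral_control", readout]
    tox <- wells[wells$role == "toxic_control_titration", , drop = FALSE]
    if (length(neu) < 2L)
        stop(sprintf("plate %s: need >= 2 neutral_control wells", pid))
    if (nrow(tox) < 2L)
        stop(sprintf("plate %s: need >= 2 toxic_control_titration wells",
                     pid))
    pos <- tox[tox$conc_m == max(tox$conc_m), readout]
    if (length(pos) < 2L)
        stop(sprintf(
            "plate %s: need >= 2 positive-control wells at the full-kill concentration",
            pid))
    methods::new("ControlStats",
                 muNeutral = mean(neu), sigmaNeutral = stats::sd(neu),
                 muPositive = mean(pos), sigmaPositive = stats::sd(pos),
                 nNeutral = length(neu), nPositive = length(pos),
                 readout = readout, plateId = pid, day = as.numeric(day))
}

#' Plate quality statistics
#'
#' Signal-to-background `S/B = mu_n / mu_p`, signal-to-noise
#' `S/N = (mu_n - mu_p) / sqrt(sigma_n^2 + sigma_p^2)` (quadrature-combined
#' noise; set `snDenominator = "neutral"` for the `(mu_n - mu_p)/sigma_n`
#' variant), and the Z-factor
#' `Z' = 1 - 3 (sigma_n + sigma_p) / |mu_n - mu_p|`.  Z' is at most 1, is
#' invariant to affine rescaling of the raw readout, and decreases as
#' control noise grows; Z' >= 0.5 is the conventional screen-ready bar.
#' Undefined statistics (zero denominators) are reported as `NA`, never as
#' errors.
#'
#' @param stats a [ControlStats-class].
#' @param snDenominator `"quadrature"` (default) or `"neutral"`.
#' @return one-row `data.frame`: `plate_id`, `day`, `readout`, `s_b`,
#'   `s_n`, `z_prime`, `n_neutral`, `n_positive`.
#' @examples
#' s <- methods::new("ControlStats", muNeutral = 100, sigmaNeutral = 10,
#'                   muPositive = 0, sigmaPositive = 10, nNeutral = 16L,
#'                   nPositive = 8L, readout = "gfp_area_total",
#'                   plateId = "P01", day = 7)
#' plateQuality(s)$z_prime  # 1 - 60/100 = 0.4
#' @export
plateQuality <- function(stats, snDenominator = c("quadrature", "neutral")) {
    snDenominator <- match.arg(snDenominator)
    mun <- stats@muNeutral; mup <- stats@muPositive
    sn <- stats@sigmaNeutral; sp <- stats@sigmaPositive
    sb <- if (mup != 0) mun / mup else NA_real_
    den <- if (snDenominator == "quadrature") sqrt(sn^2 + sp^2) else sn
    s_n <- if (den > 0) (mun - mup) / den else NA_real_
    zp <- if (mun != mup) 1 - 3 * (sn + sp) / abs(mun - mup) else NA_real_
    data.frame(plate_id = stats@plateId, day = stats@day,
               readout = stats@readout, s_b = sb, s_n = s_n, z_prime = zp,
               n_neutral = stats@nNeutral, n_positive = stats@nPositive,
               stringsAsFactors = FALSE)
}

#' Normalize well readouts to percent activity
#'
#' Affine per-plate normalization: `activity% = 100 * (x - mu_n) /
#' (mu_n - mu_p)`, so the neutral-control mean maps to 0%, the positive
#' (full-kill) control mean to -100%, and their midpoint to -50%.  Applied
#' per plate, per day, per readout; a plate whose control means coincide is
#' flagged and its wells marked unnormalizable (`NA`).
#'
#' @param wells per-well table for the plate/day the statistics were
#'   computed on.
#' @param stats the matching [ControlStats-class].
#' @return `wells` with columns `readout`, `activity_pct` and
#'   `normalizable` appended.
#' @export
normalizeWells <- function(wells, stats) {
    if (!all(wells$plate_id == stats@plateId) ||
        !all(wells$day == stats@day))
        stop("stats were computed on a different plate or day")
    x <- wells[[stats@readout]]
    span <- stats@muNeutral - stats@muPositive
    wells$readout <- stats@readout
    if (span == 0) {
        warning(sprintf("plate %s day %g: control means coincide; wells unnormalizable",
                        stats@plateId, stats@day))
        wells$activity_pct <- NA_real_
        wells$normalizable <- FALSE
    } else {
        wells$activity_pct <- 100 * (x - stats@muNeutral) / span
        wells$normalizable <- TRUE
    }
    wells
}
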