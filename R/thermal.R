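## Thermal-melt processing: blank correction, derivative Tm, aggregation flag,
## reversibility.

#' Thermal melt trace
#'
#' Ellipticity at 222 nm monitored continuously while heating (nominally every
#' 0.5 degC), optionally with the photomultiplier voltage recorded in parallel
#' and a solvent-only blank on the same grid.
#'
#' @param temperature degC grid, strictly increasing.
#' @param theta222 ellipticity at 222 nm (mean residue ellipticity or raw),
#'   same length.
#' @param pmtv optional photomultiplier voltage (V) per point.
#' @param blank optional solvent-only trace on the same grid.
#' @return an object of class `thermal_melt`.
#' @export
thermal_melt <- function(temperature, theta222, pmtv = NULL, blank = NULL) {
  temperature <- as.numeric(temperature)
  theta222 <- as.numeric(theta222)
  .assert_increasing(temperature, "temperature")
  .assert_same_length(temperature, theta222, "temperature", "theta222")
  .assert_finite(theta222, "theta222")
  if (!is.null(pmtv)) {
    pmtv <- as.numeric(pmtv)
    .assert_same_length(temperature, pmtv, "temperature", "pmtv")
  }
  if (!is.null(blank)) {
    blank <- as.numeric(blank)
    .assert_same_length(temperature, blank, "temperature", "blank")
  }
  structure(list(temperature = temperature, theta222 = theta222,
                 pmtv = pmtv, blank = blank),
            class = "thermal_melt")
}

#' @export
print.thermal_melt <- function(x, ...) {
  cat(sprintf("<thermal_melt> %d points, %.1f-%.1f degC%s%s\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              if (!is.null(x$pmtv)) ", with PMTV" else "",
              if (!is.null(x$blank)) ", with blank" else ""))
  invisible(x)
}

#' Subtract the solvent blank from a melt
#'
#' @param melt a [thermal_melt()] whose `blank` field is set (same grid).
#' @return the melt with `theta222 - blank` and the blank cleared.
#' @export
blank_correct <- function(melt) {
  stopifnot(inherits(melt, "thermal_melt"))
  if (is.null(melt$blank)) {
    stop("no blank trace present; cannot blank-correct", call. = FALSE)
  }
  melt$theta222 <- melt$theta222 - melt$blank
  melt$blank <- NULL
  melt
}

#' Melting temperature by the first-derivative method
#'
#' Smooths the 222 nm ellipticity trace with a centred moving average,
#' differentiates it by centred finite differences, and reports the
#' temperature of the extremum of largest absolute derivative as the melting
#' temperature. Tm is reported at the resolution of the temperature grid
#' (optionally refined by parabolic interpolation of the derivative peak).
#'
#' @param melt a [thermal_melt()] with at least 15 points spanning the
#'   transition.
#' @param smooth_window odd integer, moving-average window in points (default
#'   5, i.e. about 2 degC at 0.5 degC sampling).
#' @param refine if `TRUE`, refine Tm by parabolic interpolation of the
#'   derivative peak; default `FALSE` (grid resolution).
#' @return an object of class `melt_result`: a list with `tm` (degC),
#'   `derivative_trace` (data frame `temperature`, `dtheta_dT` on the interior
#'   grid), `aggregation_onset` (degC or `NA`; see [aggregation_flag()]), and
#'   `normalized_curve` (data frame `temperature`, `fraction_unfolded`,
#'   min-max normalized between pre- and post-transition plateau medians and
#'   clamped to \[0, 1\]).
#' @details The extremum searched is the one of largest absolute smoothed
#'   derivative, so the result does not depend on the sign convention of the
#'   instrument export (ellipticity at 222 nm becomes less negative on
#'   unfolding). A trace with no derivative extremum standing clearly above
#'   the background slope (e.g. a linear ramp) raises a no-transition error.
#' @examples
#' m <- gen_thermal_melt(tm = 49.5, noise_sd = 0)
#' melting_temperature(m)$tm
#' @export
melting_temperature <- function(melt, smooth_window = 5L, refine = FALSE) {
  stopifnot(inherits(melt, "thermal_melt"))
  tt <- melt$temperature; y <- melt$theta222
  n <- length(tt)
  if (n < 15L) stop("need at least 15 points spanning the transition",
                    call. = FALSE)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop("`smooth_window` must be a positive odd integer", call. = FALSE)
  }
  ys <- .movavg(y, smooth_window)
  ## centred differences on the interior grid; the derivative itself is
  ## smoothed with the same window so grid-level noise cannot move the peak
  i <- 2:(n - 1)
  d <- (ys[i + 1] - ys[i - 1]) / (tt[i + 1] - tt[i - 1])
  ti <- tt[i]
  ad <- .movavg(abs(d), smooth_window)
  peak <- which.max(ad)
  ## no-transition guard: a linear (or flat) trace has a near-constant
  ## derivative, so its maximum does not stand above the typical level.
  if (max(ad) <= 1e-12 || max(ad) < 2 * stats::median(ad) + 1e-12) {
    stop("no transition detected: derivative has no extremum above background",
         call. = FALSE)
  }
  tm <- ti[peak]
  if (refine && peak > 1L && peak < length(d)) {
    ## parabola through the three points around the |derivative| peak
    y3 <- ad[(peak - 1):(peak + 1)]
    denom <- y3[1] - 2 * y3[2] + y3[3]
    if (abs(denom) > 1e-15) {
      delta <- 0.5 * (y3[1] - y3[3]) / denom
      tm <- ti[peak] + delta * (ti[peak + 1] - ti[peak])
    }
  }
  structure(list(
    tm = tm,
    derivative_trace = data.frame(temperature = ti, dtheta_dT = d),
    aggregation_onset = if (is.null(melt$pmtv)) NA_real_ else
      suppressWarnings(aggregation_flag(melt)),
    normalized_curve = .normalize_melt(tt, y)
  ), class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  cat(sprintf("<melt_result> Tm = %.1f degC", x$tm))
  if (is.finite(x$aggregation_onset)) {
    cat(sprintf(", aggregation onset %.1f degC", x$aggregation_onset))
  }
  cat("\n")
  invisible(x)
}

## centred moving average with shrinking window at the edges
.movavg <- function(y, w) {
  if (w == 1L) return(y)
  h <- (w - 1L) %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(y[lo:hi])
  }, numeric(1))
}

## min-max normalization between pre/post-transition plateau medians
## (medians of the first and last 10% of points), clamped to [0, 1]
.normalize_melt <- function(tt, y) {
  n <- length(y)
  k <- max(2L, floor(0.1 * n))
  pre <- stats::median(y[seq_len(k)])
  post <- stats::median(y[seq.int(n - k + 1L, n)])
  span <- post - pre
  f <- if (abs(span) < 1e-15) rep(NA_real_, n) else (y - pre) / span
  data.frame(temperature = tt, fraction_unfolded = pmin(pmax(f, 0), 1))
}

#' Aggregation onset from the photomultiplier voltage
#'
#' During a CD thermal scan a rise in the photomultiplier tube voltage signals
#' increasing turbidity, i.e. aggregation. The flag is the first temperature
#' at which the voltage strictly exceeds the threshold.
#'
#' @param melt a [thermal_melt()] with `pmtv` recorded.
#' @param threshold_V voltage threshold, default 370 V.
#' @return the onset temperature (degC), or `NA` if the threshold is never
#'   exceeded. If no PMTV trace is present, returns `NA` with a warning.
#' @export
aggregation_flag <- function(melt, threshold_V = 370) {
  stopifnot(inherits(melt, "thermal_melt"))
  if (is.null(melt$pmtv)) {
    warning("no PMTV trace recorded; aggregation flag unavailable")
    return(NA_real_)
  }
  hit <- which(melt$pmtv > threshold_V)
  if (length(hit) == 0L) NA_real_ else melt$temperature[hit[1]]
}

#' Reversibility check from pre/post-scan spectra
#'
#' Compares the far-UV CD spectrum recorded after cooling back to the starting
#' temperature with the native spectrum recorded before heating. A transition
#' is called reversible when the post-cooling spectrum matches the native one
#' within a tolerance over the helical band.
#'
#' @param native,post_cooling [cd_spectrum()] objects on the same wavelength
#'   grid.
#' @param tolerance_fraction maximum allowed deviation as a fraction of the
#'   native signal scale (default 0.05).
#' @param band wavelength window (nm) over which to compare; default
#'   `c(205, 240)`, the helical far-UV band.
#' @return a list with `reversible` (logical) and `max_relative_deviation`:
#'   the largest absolute difference in the band divided by the largest
#'   absolute native signal in the band (scale-relative, so near-zero
#'   crossings of the spectrum do not blow the ratio up).
#' @export
reversibility_check <- function(native, post_cooling, tolerance_fraction = 0.05,
                                band = c(205, 240)) {
  stopifnot(inherits(native, "cd_spectrum"), inherits(post_cooling, "cd_spectrum"))
  if (length(native$wavelengths) != length(post_cooling$wavelengths) ||
      any(native$wavelengths != post_cooling$wavelengths)) {
    stop("spectra are not on the same wavelength grid", call. = FALSE)
  }
  keep <- native$wavelengths >= min(band) & native$wavelengths <= max(band)
  if (!any(keep)) stop("no points in the comparison band", call. = FALSE)
  a <- native$signal[keep]; b <- post_cooling$signal[keep]
  scale <- max(abs(a))
  if (scale == 0) stop("native spectrum is identically zero in the band",
                       call. = FALSE)
  dev <- max(abs(b - a)) / scale
  list(reversible = dev <= tolerance_fraction, max_relative_deviation = dev)
}
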