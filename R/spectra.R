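## Spectral containers and summary statistics.

#' Fluorescence emission spectrum
#'
#' A single emission scan: intensity versus wavelength at one solution
#' condition (denaturant molarity or temperature).
#'
#' @param wavelengths numeric, nm, strictly increasing.
#' @param intensities numeric, arbitrary fluorescence units, same length.
#' @param condition numeric scalar; the condition the scan was recorded at
#'   (urea molarity in M, or temperature in degC). Optional.
#' @param label free-text label.
#' @return an object of class `emission_spectrum` (a list with fields
#'   `wavelengths`, `intensities`, `condition`, `label`).
#' @examples
#' es <- emission_spectrum(300:320, dnorm(300:320, 308, 5))
#' avg_emission_wavelength(es)
#' @export
emission_spectrum <- function(wavelengths, intensities, condition = NA_real_,
                              label = "") {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  .assert_increasing(wavelengths, "wavelengths")
  .assert_same_length(wavelengths, intensities, "wavelengths", "intensities")
  .assert_finite(intensities, "intensities")
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 condition = as.numeric(condition)[1], label = label),
            class = "emission_spectrum")
}

#' Circular dichroism spectrum
#'
#' Holds either a raw ellipticity scan (mdeg) or one already converted to mean
#' residue ellipticity (deg cm^2 dmol^-1); `units` records which.
#'
#' @param wavelengths numeric, nm, strictly increasing.
#' @param signal numeric, same length as `wavelengths`.
#' @param units `"mdeg"` (raw instrument ellipticity) or `"mre"` (mean residue
#'   ellipticity).
#' @param pathlength_cm cuvette path length, cm (needed for conversion).
#' @param conc_mg_ml protein concentration, mg/mL (needed for conversion).
#' @param mean_residue_mass mean residue molecular mass, g/mol. The
#'   conventional value of 110 per residue is the default.
#' @param label free-text label.
#' @return an object of class `cd_spectrum`.
#' @seealso [mean_residue_ellipticity()], [ellipticity_ratio()]
#' @export
cd_spectrum <- function(wavelengths, signal, units = c("mdeg", "mre"),
                        pathlength_cm = NA_real_, conc_mg_ml = NA_real_,
                        mean_residue_mass = 110, label = "") {
  units <- match.arg(units)
  wavelengths <- as.numeric(wavelengths)
  signal <- as.numeric(signal)
  .assert_increasing(wavelengths, "wavelengths")
  .assert_same_length(wavelengths, signal, "wavelengths", "signal")
  .assert_finite(signal, "signal")
  structure(list(wavelengths = wavelengths, signal = signal, units = units,
                 pathlength_cm = pathlength_cm, conc_mg_ml = conc_mg_ml,
                 mean_residue_mass = mean_residue_mass, label = label),
            class = "cd_spectrum")
}

#' Spectral titration series
#'
#' A matrix of signal over a shared wavelength grid (rows) and an ascending
#' condition axis (columns), e.g. far-UV CD scans recorded at increasing urea
#' concentration. This is the substrate for [svd_denoise()].
#'
#' @param wavelengths numeric, nm, strictly increasing (row axis).
#' @param conditions numeric, strictly increasing (column axis), e.g. urea M.
#' @param matrix numeric matrix, `length(wavelengths)` x `length(conditions)`.
#' @return an object of class `spectral_series`.
#' @export
spectral_series <- function(wavelengths, conditions, matrix) {
  wavelengths <- as.numeric(wavelengths)
  conditions <- as.numeric(conditions)
  matrix <- as.matrix(matrix)
  .assert_increasing(wavelengths, "wavelengths")
  .assert_increasing(conditions, "conditions")
  if (nrow(matrix) != length(wavelengths) || ncol(matrix) != length(conditions)) {
    stop("`matrix` must be length(wavelengths) x length(conditions)",
         call. = FALSE)
  }
  .assert_finite(matrix, "matrix")
  dimnames(matrix) <- NULL
  structure(list(wavelengths = wavelengths, conditions = conditions,
                 matrix = matrix),
            class = "spectral_series")
}

#' Equilibrium unfolding curve
#'
#' A one-dimensional observable (intensity-averaged emission wavelength, or
#' ellipticity at 222 nm) as a function of denaturant concentration; the
#' substrate for [fit_two_state()] and [fit_three_state()].
#'
#' @param x denaturant concentration, M; non-negative, strictly increasing.
#' @param y observable; finite.
#' @param probe `"far_uv_cd"` or `"fluorescence"`.
#' @param temperature_K absolute temperature of the experiment. Default
#'   283.15 K (10 degC).
#' @return an object of class `unfolding_curve`.
#' @export
unfolding_curve <- function(x, y, probe = c("far_uv_cd", "fluorescence"),
                            temperature_K = .T_DEFAULT_K) {
  probe <- match.arg(probe)
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(x < 0)) stop("denaturant concentrations must be non-negative",
                       call. = FALSE)
  .assert_increasing(x, "x")
  .assert_same_length(x, y, "x", "y")
  .assert_finite(y, "y")
  if (temperature_K <= 0) stop("`temperature_K` must be positive", call. = FALSE)
  structure(list(x = x, y = y, probe = probe,
                 temperature_K = temperature_K),
            class = "unfolding_curve")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d points, %.0f-%.0f nm", length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (is.finite(x$condition)) cat(sprintf(", condition %.3g", x$condition))
  cat("\n")
  invisible(x)
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %d points, %.0f-%.0f nm, units: %s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$units))
  invisible(x)
}

#' @export
print.spectral_series <- function(x, ...) {
  cat(sprintf("<spectral_series> %d wavelengths x %d conditions\n",
              length(x$wavelengths), length(x$conditions)))
  invisible(x)
}

#' @export
print.unfolding_curve <- function(x, ...) {
  cat(sprintf("<unfolding_curve> %d points, 0-%.2f M, probe: %s, T = %.2f K\n",
              length(x$x), max(x$x), x$probe, x$temperature_K))
  invisible(x)
}

## operations -----------------------------------------------------------------

#' Convert raw ellipticity to mean residue ellipticity
#'
#' Applies the standard normalization per peptide bond:
#' \deqn{[\Theta]_\lambda = \theta_{mdeg} \cdot M_{res} /
#'   (10 \, l_{cm} \, c_{mg/mL})}
#' where \eqn{M_{res}} is the mean residue molecular mass (110 g/mol by
#' convention), \eqn{l} the path length in cm and \eqn{c} the protein
#' concentration in mg/mL.
#'
#' @param raw a [cd_spectrum()] with `units = "mdeg"` and positive
#'   `pathlength_cm` and `conc_mg_ml` metadata.
#' @return a `cd_spectrum` with `units = "mre"` on the same wavelength grid.
#' @examples
#' s <- cd_spectrum(222, 100, "mdeg", pathlength_cm = 0.1, conc_mg_ml = 0.2)
#' mean_residue_ellipticity(s)$signal  # 55000
#' @export
mean_residue_ellipticity <- function(raw) {
  stopifnot(inherits(raw, "cd_spectrum"))
  if (raw$units != "mdeg") {
    stop("spectrum is not in raw mdeg units", call. = FALSE)
  }
  l <- raw$pathlength_cm; conc <- raw$conc_mg_ml; mrw <- raw$mean_residue_mass
  if (!is.finite(l) || l <= 0 || !is.finite(conc) || conc <= 0 ||
      !is.finite(mrw) || mrw <= 0) {
    stop("path length, concentration and mean residue mass must all be set and positive",
         call. = FALSE)
  }
  out <- raw
  out$signal <- raw$signal * mrw / (10 * l * conc)
  out$units <- "mre"
  out
}

#' Intensity-averaged emission wavelength
#'
#' The first moment of an emission spectrum,
#' \eqn{\bar\lambda = \sum_i I_i \lambda_i / \sum_i I_i}: an integral
#' statistic of spectral shape and position that is robust to point noise and
#' tracks tertiary-structure changes during unfolding.
#'
#' @param spec an [emission_spectrum()].
#' @param window optional `c(lo, hi)` wavelength window (nm) restricting the
#'   sums; by default the full recorded range is used.
#' @return the intensity-averaged wavelength, nm. Always within the wavelength
#'   range of the (windowed) spectrum.
#' @details Negative intensities (as can arise after baseline subtraction) are
#'   clipped to zero with a warning, since the statistic is a weighted mean
#'   that requires non-negative weights. A spectrum with no positive intensity
#'   is an error.
#' @export
avg_emission_wavelength <- function(spec, window = NULL) {
  stopifnot(inherits(spec, "emission_spectrum"))
  wl <- spec$wavelengths; ii <- spec$intensities
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    keep <- wl >= min(window) & wl <= max(window)
    wl <- wl[keep]; ii <- ii[keep]
  }
  if (length(wl) < 1L) stop("no points in the requested window", call. = FALSE)
  if (any(ii < 0)) {
    warning("negative intensities clipped to zero before averaging")
    ii <- pmax(ii, 0)
  }
  tot <- sum(ii)
  if (!is.finite(tot) || tot <= 0) {
    stop("total intensity is not positive; average emission wavelength undefined",
         call. = FALSE)
  }
  sum(ii * wl) / tot
}

#' Ellipticity ratio between two wavelengths
#'
#' Ratio of the (mean residue) ellipticity at two wavelengths, by default
#' 222 nm over 208 nm: a diagnostic of inter-helical packing in all-helical
#' proteins. Values below 0.9 are conventionally read as non-interacting
#' helices rather than coiled-coil-like packed helices; see
#' [helix_packing_flag()].
#'
#' @param spec a [cd_spectrum()].
#' @param num_nm,den_nm numerator and denominator wavelengths, nm. Off-grid
#'   values are linearly interpolated between neighbouring grid points.
#' @return the dimensionless ratio `signal(num_nm) / signal(den_nm)`.
#' @export
ellipticity_ratio <- function(spec, num_nm = 222, den_nm = 208) {
  stopifnot(inherits(spec, "cd_spectrum"))
  rng <- range(spec$wavelengths)
  for (w in c(num_nm, den_nm)) {
    if (w < rng[1] || w > rng[2]) {
      stop(sprintf("wavelength %.1f nm outside recorded range [%.1f, %.1f]",
                   w, rng[1], rng[2]), call. = FALSE)
    }
  }
  num <- stats::approx(spec$wavelengths, spec$signal, xout = num_nm)$y
  den <- stats::approx(spec$wavelengths, spec$signal, xout = den_nm)$y
  tol <- 1e-12 * max(abs(spec$signal), 1)
  if (abs(den) <= tol) {
    stop("denominator ellipticity is zero within tolerance; ratio undefined",
         call. = FALSE)
  }
  num / den
}

#' Classify helix packing from a 222/208 ellipticity ratio
#'
#' @param ratio ellipticity ratio from [ellipticity_ratio()].
#' @param threshold boundary below which helices are flagged as
#'   non-interacting (convention: 0.9).
#' @return `TRUE` if the ratio falls below the boundary (non-interacting /
#'   reduced inter-helical contacts), else `FALSE`.
#' @export
helix_packing_flag <- function(ratio, threshold = 0.9) {
  stopifnot(is.numeric(ratio), is.finite(ratio))
  ratio < threshold
}

#' SVD denoising of a spectral series
#'
#' Decomposes the wavelength x condition signal matrix by singular value
#' decomposition and reconstructs it from its leading components, removing
#' high-frequency noise and low-amplitude random errors while preserving the
#' independent spectral components that actually vary along the titration.
#'
#' @param series a [spectral_series()] with at least 2 rows and 2 columns.
#' @param rank number of components to retain, or `"auto"` to select the rank
#'   automatically: components are kept when their singular value exceeds
#'   twice the median singular value *and* their left singular vector is
#'   smooth in wavelength (lag-1 autocorrelation > 0.8). Signal components are
#'   smooth; noise components are not.
#' @return a `spectral_series` holding the rank-k reconstruction, with
#'   diagnostics in `attr(, "svd")`: `singular_values`, `rank`, and
#'   `variance_retained` (fraction of total squared signal captured).
#' @examples
#' ss <- gen_rank_k_series(k = 2, noise_sd = 0.01, seed = 1)
#' den <- svd_denoise(ss, rank = "auto")
#' attr(den, "svd")$rank
#' @export
svd_denoise <- function(series, rank = "auto") {
  stopifnot(inherits(series, "spectral_series"))
  m <- series$matrix
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("matrix must have at least 2 rows and 2 columns", call. = FALSE)
  }
  dec <- svd(m)
  kmax <- length(dec$d)
  if (identical(rank, "auto")) {
    keep <- .auto_rank_keep(dec)
    k <- max(1L, sum(keep))
  } else {
    k <- as.integer(rank)
    if (is.na(k) || k < 1L || k > kmax) {
      stop(sprintf("rank must be in 1..%d (or \"auto\")", kmax), call. = FALSE)
    }
  }
  idx <- seq_len(k)
  recon <- dec$u[, idx, drop = FALSE] %*%
    (dec$d[idx] * t(dec$v[, idx, drop = FALSE]))
  out <- spectral_series(series$wavelengths, series$conditions, recon)
  attr(out, "svd") <- list(
    singular_values = dec$d,
    rank = k,
    variance_retained = sum(dec$d[idx]^2) / sum(dec$d^2)
  )
  out
}

## Auto rank rule: large singular value AND smooth left singular vector.
.auto_rank_keep <- function(dec) {
  d <- dec$d
  big <- d > 2 * stats::median(d)
  smooth <- vapply(seq_along(d), function(j) {
    u <- dec$u[, j]
    n <- length(u)
    if (n < 3L || stats::sd(u) == 0) return(FALSE)
    stats::cor(u[-1], u[-n]) > 0.8
  }, logical(1))
  big & smooth
}
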