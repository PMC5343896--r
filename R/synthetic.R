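## Seeded synthetic-data generators with embedded ground truth. Each one is a
## pure function of its arguments (seed included), and records the generating
## parameters in attr(, "truth") for recovery tests.

## default condition grids: 0-9 M urea in 0.25 M steps; 20-75 degC in 0.5 degC
.urea_grid <- function() seq(0, 9, by = 0.25)
.temp_grid <- function() seq(20, 75, by = 0.5)

#' Generate a two-state unfolding curve
#'
#' Forward evaluation of [two_state_model()] on a urea grid plus Gaussian
#' noise, with the generating parameters recorded in `attr(, "truth")`.
#'
#' @param dG_H2O,m thermodynamic ground truth (kcal/mol, kcal/mol/M).
#' @param yN,sN,yU,sU baseline ground truth.
#' @param x urea grid, M; must lie within \[0, 9\]. Default 0-9 M in 0.25 M
#'   steps (36 intervals).
#' @param noise_sd Gaussian noise standard deviation, observable units.
#' @param seed integer seed (same seed, same curve) or `NULL`.
#' @param temperature_K absolute temperature, K.
#' @param probe probe tag for the curve.
#' @return an [unfolding_curve()] with a `truth` attribute.
#' @export
gen_two_state_curve <- function(dG_H2O, m, yN = 1, sN = 0.005, yU = 0,
                                sU = -0.002, x = .urea_grid(), noise_sd = 0,
                                seed = NULL, temperature_K = .T_DEFAULT_K,
                                probe = "far_uv_cd") {
  if (any(x < 0) || any(x > 9)) {
    stop("urea grid must lie within [0, 9] M", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  y0 <- two_state_model(x, dG_H2O, m, yN, sN, yU, sU, temperature_K)
  y <- with_seed(seed, y0 + stats::rnorm(length(x), 0, noise_sd))
  out <- unfolding_curve(x, y, probe = probe, temperature_K = temperature_K)
  attr(out, "truth") <- list(kind = "two_state_curve", dG_H2O = dG_H2O, m = m,
                             yN = yN, sN = sN, yU = yU, sU = sU,
                             noise_sd = noise_sd, seed = seed,
                             temperature_K = temperature_K)
  out
}

#' Generate a three-state unfolding curve
#'
#' Forward evaluation of [three_state_model()] plus Gaussian noise. The
#' default baselines emulate an intensity-averaged emission wavelength
#' observable: native near 308 nm, unfolded near 317 nm, intermediate in
#' between.
#'
#' @param m_IN,D50_IN,m_UI,D50_UI thermodynamic ground truth.
#' @param aN,bN,FI,aU,bU signal ground truth.
#' @param x urea grid, M, within \[0, 9\].
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed or `NULL`.
#' @param temperature_K absolute temperature, K.
#' @return an [unfolding_curve()] (probe `"fluorescence"`) with a `truth`
#'   attribute. A generator whose midpoints are out of order (`D50_IN >
#'   D50_UI`) warns but still generates.
#' @export
gen_three_state_curve <- function(m_IN, D50_IN, m_UI, D50_UI,
                                  aN = 308, bN = 0.05, FI = 313,
                                  aU = 317, bU = 0.1,
                                  x = .urea_grid(), noise_sd = 0, seed = NULL,
                                  temperature_K = .T_DEFAULT_K) {
  if (any(x < 0) || any(x > 9)) {
    stop("urea grid must lie within [0, 9] M", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (D50_IN > D50_UI) {
    warning("midpoints out of order (D50_IN > D50_UI); generating anyway")
  }
  y0 <- three_state_model(x, m_IN, D50_IN, m_UI, D50_UI, aN, bN, FI, aU, bU,
                          temperature_K)
  y <- with_seed(seed, y0 + stats::rnorm(length(x), 0, noise_sd))
  out <- unfolding_curve(x, y, probe = "fluorescence",
                         temperature_K = temperature_K)
  attr(out, "truth") <- list(kind = "three_state_curve", m_IN = m_IN,
                             D50_IN = D50_IN, m_UI = m_UI, D50_UI = D50_UI,
                             aN = aN, bN = bN, FI = FI, aU = aU, bU = bU,
                             noise_sd = noise_sd, seed = seed,
                             temperature_K = temperature_K)
  out
}

#' Generate a series of Gaussian-band emission spectra
#'
#' One Gaussian emission band per condition, whose centre, width and
#' amplitude may each be constant, a per-condition vector, or a function of
#' the condition. Emulates a tyrosine-like band near 308 nm that broadens and
#' gains intensity with denaturant.
#'
#' For the default band geometry the truncation of the Gaussian at the grid
#' edges shifts the intensity-averaged wavelength from the band centre by
#' less than 0.05 nm, so the centre doubles as a closed-form expectation for
#' [avg_emission_wavelength()].
#'
#' @param conditions condition axis (urea M), ascending.
#' @param center band centre, nm: scalar, vector over conditions, or
#'   function of the condition. Default 308.
#' @param width band standard deviation, nm: scalar/vector/function. Default
#'   widens linearly from 4 to 6 nm across the condition axis.
#' @param amplitude peak amplitude: scalar/vector/function. Default grows
#'   from 1 to 1.6 (unfolding increases the emission intensity).
#' @param wavelengths emission wavelength grid, nm; default 290-440 in 1 nm
#'   steps.
#' @param noise_sd Gaussian noise sd on intensities.
#' @param seed integer seed or `NULL`.
#' @return a list of [emission_spectrum()] objects (one per condition) with a
#'   `truth` attribute recording the per-condition centre/width/amplitude.
#' @export
gen_emission_series <- function(conditions = .urea_grid(), center = 308,
                                width = NULL, amplitude = NULL,
                                wavelengths = seq(290, 440, by = 1),
                                noise_sd = 0, seed = NULL) {
  nc <- length(conditions)
  expand <- function(par, default) {
    if (is.null(par)) par <- default
    if (is.function(par)) return(vapply(conditions, par, numeric(1)))
    if (length(par) == 1L) return(rep(par, nc))
    stopifnot(length(par) == nc)
    as.numeric(par)
  }
  span <- diff(range(conditions))
  frac <- if (span > 0) (conditions - min(conditions)) / span else rep(0, nc)
  centers <- expand(center, 308)
  widths <- expand(width, 4 + 2 * frac)
  amps <- expand(amplitude, 1 + 0.6 * frac)
  if (any(centers < min(wavelengths)) || any(centers > max(wavelengths))) {
    stop("band centre outside the wavelength grid", call. = FALSE)
  }
  specs <- with_seed(seed, lapply(seq_len(nc), function(i) {
    ii <- amps[i] * exp(-0.5 * ((wavelengths - centers[i]) / widths[i])^2) +
      stats::rnorm(length(wavelengths), 0, noise_sd)
    emission_spectrum(wavelengths, pmax(ii, 0), condition = conditions[i])
  }))
  attr(specs, "truth") <- list(kind = "emission_series",
                               conditions = conditions, centers = centers,
                               widths = widths, amplitudes = amps,
                               noise_sd = noise_sd, seed = seed)
  specs
}

#' Generate a thermal melt
#'
#' A logistic sigmoid in temperature between two sloping baselines, plus
#' Gaussian noise, with an optional photomultiplier-voltage ramp that first
#' exceeds a threshold at a configurable temperature (emulating aggregation
#' after the transition) and an optional constant solvent blank.
#'
#' @param tm logistic midpoint, degC; must lie inside the scan range.
#' @param width logistic scale parameter, degC (default 2).
#' @param theta_pre,slope_pre native-baseline intercept (value at `tm`) and
#'   slope.
#' @param theta_post,slope_post unfolded-baseline intercept and slope.
#' @param temperature scan grid, degC; default 20-75 in 0.5 steps.
#' @param noise_sd Gaussian noise sd.
#' @param pmtv_onset temperature at which the PMTV first exceeds 370 V, or
#'   `NULL` for no PMTV trace.
#' @param blank constant solvent blank value, or `NULL`.
#' @param seed integer seed or `NULL`.
#' @return a [thermal_melt()] with a `truth` attribute.
#' @export
gen_thermal_melt <- function(tm = 49.5, width = 2, theta_pre = -9400,
                             slope_pre = 8, theta_post = -2500,
                             slope_post = 4, temperature = .temp_grid(),
                             noise_sd = 0, pmtv_onset = NULL, blank = NULL,
                             seed = NULL) {
  if (tm < min(temperature) || tm > max(temperature)) {
    stop("midpoint must lie inside the scan range", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  f <- 1 / (1 + exp(-(temperature - tm) / width))
  pre <- theta_pre + slope_pre * (temperature - tm)
  post <- theta_post + slope_post * (temperature - tm)
  y0 <- pre + (post - pre) * f
  y <- with_seed(seed, y0 + stats::rnorm(length(temperature), 0, noise_sd))
  pmtv <- NULL
  if (!is.null(pmtv_onset)) {
    step <- stats::median(diff(temperature))
    pmtv <- ifelse(temperature < pmtv_onset, 300,
                   300 + 150 * (temperature - pmtv_onset + step))
  }
  blank_vec <- if (is.null(blank)) NULL else rep(blank, length(temperature))
  out <- thermal_melt(temperature, y, pmtv = pmtv, blank = blank_vec)
  attr(out, "truth") <- list(kind = "thermal_melt", tm = tm, width = width,
                             theta_pre = theta_pre, slope_pre = slope_pre,
                             theta_post = theta_post, slope_post = slope_post,
                             noise_sd = noise_sd, pmtv_onset = pmtv_onset,
                             blank = blank, seed = seed)
  out
}

## ideal C-alpha helix: radius 0.23 nm, rise 0.15 nm, 100 degrees per residue
.ideal_helix <- function(n_res, radius = 0.23, rise = 0.15, twist_deg = 100) {
  i <- seq_len(n_res) - 1
  ang <- i * twist_deg * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), rise * i)
}

#' Generate a jittered two-helix trajectory
#'
#' Builds two ideal C-alpha helices at a set centroid separation and emits
#' frames with optional rigid-body wobble plus per-residue isotropic Gaussian
#' jitter. Ground-truth RMSF (`sigma * sqrt(3)` per residue) and the helix
#' centroid separation are recorded.
#'
#' @param n_frames number of frames.
#' @param n_res residues per helix.
#' @param separation centroid-centroid distance between the two helices, nm.
#' @param sigma per-residue isotropic jitter sd per coordinate, nm; scalar or
#'   one value per residue (both helices concatenated).
#' @param wobble_sd sd of a per-frame rigid-body translation of the whole
#'   system, nm (no jitter within the frame); default 0.
#' @param resno_a,resno_b starting residue numbers of the two helices
#'   (defaults follow the PPARgamma LBD numbering of H3 and H12).
#' @param seed integer seed or `NULL`.
#' @return a [trajectory()] of C-alpha atoms (resname ALA, chains A/B) with a
#'   `truth` attribute (`base` noiseless coordinates, `separation`,
#'   per-residue `rmsf`, `sigma`).
#' @export
gen_jitter_trajectory <- function(n_frames = 100, n_res = 12, separation = 1.14,
                                  sigma = 0.02, wobble_sd = 0,
                                  resno_a = 276, resno_b = 466, seed = NULL) {
  h1 <- .ideal_helix(n_res)
  h2 <- .ideal_helix(n_res)
  ## place the second helix so the centroid distance is exactly `separation`
  h2 <- sweep(h2, 2, colMeans(h2))
  h2 <- sweep(h2, 2, colMeans(h1) + c(separation, 0, 0), `+`)
  base <- rbind(h1, h2)
  na <- nrow(base)
  sigma <- if (length(sigma) == 1L) rep(sigma, na) else {
    stopifnot(length(sigma) == na); as.numeric(sigma)
  }
  coords <- with_seed(seed, {
    arr <- array(NA_real_, c(n_frames, na, 3))
    for (f in seq_len(n_frames)) {
      shift <- if (wobble_sd > 0) stats::rnorm(3, 0, wobble_sd) else c(0, 0, 0)
      jit <- matrix(stats::rnorm(na * 3, 0, rep(sigma, 3)), ncol = 3)
      arr[f, , ] <- sweep(base + jit, 2, shift, `+`)
    }
    arr
  })
  atoms <- data.frame(
    resno = c(resno_a + seq_len(n_res) - 1L, resno_b + seq_len(n_res) - 1L),
    resname = "ALA", atom = "CA",
    chain = rep(c("A", "B"), each = n_res),
    stringsAsFactors = FALSE)
  out <- trajectory(coords, atoms)
  attr(out, "truth") <- list(kind = "jitter_trajectory", base = base,
                             separation = separation, sigma = sigma,
                             rmsf = sigma * sqrt(3), wobble_sd = wobble_sd,
                             n_frames = n_frames, seed = seed)
  out
}

#' Generate a low-rank spectral series
#'
#' A sum of `k` outer products of smooth wavelength bases (Gaussian bands)
#' and condition profiles (sigmoids), plus Gaussian noise: the canonical
#' test-bed for [svd_denoise()].
#'
#' @param k true rank (number of independent spectral components).
#' @param wavelengths wavelength grid, nm.
#' @param conditions condition axis (urea M).
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed or `NULL`.
#' @return a [spectral_series()] with a `truth` attribute containing the
#'   rank and the noiseless matrix.
#' @export
gen_rank_k_series <- function(k = 2, wavelengths = seq(200, 250, by = 1),
                              conditions = .urea_grid(), noise_sd = 0,
                              seed = NULL) {
  nw <- length(wavelengths); nc <- length(conditions)
  if (k > min(nw, nc)) stop("k exceeds matrix dimensions", call. = FALSE)
  centers <- seq(min(wavelengths) + 5, max(wavelengths) - 5, length.out = k)
  mids <- seq(min(conditions) + 1, max(conditions) - 1, length.out = k)
  clean <- matrix(0, nw, nc)
  for (j in seq_len(k)) {
    basis <- exp(-0.5 * ((wavelengths - centers[j]) / 8)^2)
    profile <- 1 / (1 + exp(-(conditions - mids[j]) / 0.8))
    ## alternate signs so components stay linearly independent and sizeable
    clean <- clean + (10 / j) * outer(basis, if (j %% 2) 1 - profile else profile)
  }
  noisy <- with_seed(seed, clean + matrix(stats::rnorm(nw * nc, 0, noise_sd),
                                          nw, nc))
  out <- spectral_series(wavelengths, conditions, noisy)
  attr(out, "truth") <- list(kind = "rank_k_series", k = k, clean = clean,
                             noise_sd = noise_sd, seed = seed)
  out
}
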