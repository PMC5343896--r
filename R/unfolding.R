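## Equilibrium unfolding under the linear extrapolation model (LEM):
## two-state N = U and three-state N = I = U fits with sloping baselines.

## exponent clamp before exp(): keeps K finite without affecting any
## physically reachable value
.EXP_CLAMP <- 700

.exp_safe <- function(z) exp(pmin(pmax(z, -.EXP_CLAMP), .EXP_CLAMP))

#' Two-state unfolding signal model
#'
#' The linear extrapolation model assumes the unfolding free energy varies
#' linearly with denaturant: \eqn{\Delta G(x) = \Delta G^{H_2O} - m x}, so the
#' unfolding equilibrium constant is \eqn{K(x) = \exp((m x - \Delta
#' G^{H_2O})/RT)}. With linear native and unfolded baselines the observed
#' signal is
#' \deqn{y(x) = \frac{y_N + s_N x + (y_U + s_U x) K(x)}{1 + K(x)}.}
#'
#' @param x denaturant concentration, M (vectorized).
#' @param dG_H2O unfolding free energy in water, kcal/mol.
#' @param m denaturant dependence of the free energy (m-value), kcal/mol/M,
#'   stored positive.
#' @param yN,sN native baseline intercept and slope.
#' @param yU,sU unfolded baseline intercept and slope.
#' @param temperature_K absolute temperature, K.
#' @return the modelled signal at each `x`.
#' @examples
#' # at the midpoint x = dG/m the signal is the mean of the two baselines
#' two_state_model(3.5, dG_H2O = 3.5, m = 1, yN = 1, yU = 0)
#' @export
two_state_model <- function(x, dG_H2O, m, yN, sN = 0, yU, sU = 0,
                            temperature_K = .T_DEFAULT_K) {
  stopifnot(temperature_K > 0)
  RT <- .R_KCAL * temperature_K
  K <- .exp_safe((m * x - dG_H2O) / RT)
  (yN + sN * x + (yU + sU * x) * K) / (1 + K)
}

#' Midpoint of a two-state transition from the linear extrapolation model
#'
#' The denaturant concentration at which native and unfolded states are
#' equally populated: `[Urea]0.5 = dG_H2O / m`.
#'
#' @param dG_H2O unfolding free energy in water, kcal/mol.
#' @param m m-value, kcal/mol/M; must be positive.
#' @return the transition midpoint, M.
#' @examples
#' midpoint_from_lem(3.07, 0.84)  # 3.65
#' @export
midpoint_from_lem <- function(dG_H2O, m) {
  if (any(m <= 0)) stop("`m` must be positive", call. = FALSE)
  dG_H2O / m
}

#' Fit a two-state unfolding curve
#'
#' Nonlinear least squares fit of [two_state_model()] to an unfolding curve,
#' with asymptotic standard errors from the Jacobian at the optimum and the
#' midpoint derived as `dG_H2O / m`.
#'
#' @param curve an [unfolding_curve()] with at least 8 points, including
#'   points on both plateaus and through the transition.
#' @return an object of class `two_state_fit`: `dG_H2O`, `m`, `yN`, `sN`,
#'   `yU`, `sU`, `urea50`, `se` (named vector of asymptotic standard errors),
#'   `temperature_K`, `converged`, `residual_norm`, `fitted`, plus the input
#'   `curve`.
#' @details Baselines are initialized by ordinary least squares on the first
#'   and last 15% of points, the midpoint from the location of the largest
#'   absolute slope of the (lightly smoothed) data, and the m-value at
#'   2 kcal/mol/M. When the two plateaus are indistinguishable relative to
#'   the baseline noise the fit is ill-conditioned and a warning is raised.
#' @examples
#' cur <- gen_two_state_curve(dG_H2O = 3.37, m = 0.95, noise_sd = 0)
#' fit <- fit_two_state(cur)
#' c(fit$dG_H2O, fit$m, fit$urea50)
#' @export
fit_two_state <- function(curve) {
  stopifnot(inherits(curve, "unfolding_curve"))
  x <- curve$x; y <- curve$y
  n <- length(x)
  if (n < 8L) stop("need at least 8 points for a two-state fit", call. = FALSE)
  TK <- curve$temperature_K

  init <- .baseline_init(x, y)
  .warn_if_flat(x, y, init)
  d50_0 <- .steepest_x(x, y)
  ## an overly steep starting m makes the transition span a single grid point
  ## and the Jacobian singular, so fall back over gentler slopes if needed
  fit <- NULL
  for (m0 in c(2, 1, 0.5, 4)) {
    start <- list(dG_H2O = m0 * d50_0, m = m0,
                  yN = init$yN, sN = init$sN, yU = init$yU, sU = init$sU)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ two_state_model(x, dG_H2O, m, yN, sN, yU, sU, temperature_K = TK),
        data = data.frame(x = x, y = y),
        start = start,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)
      ),
      error = function(e) e
    )
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    stop("two-state fit did not converge: ", conditionMessage(fit),
         call. = FALSE)
  }
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  ## the model is symmetric under (dG, m) -> (-dG, -m) with swapped baselines;
  ## normalize to the m > 0 branch
  if (est[["m"]] < 0) {
    est[c("dG_H2O", "m")] <- -est[c("dG_H2O", "m")]
    tmp <- est[c("yN", "sN")]
    est[c("yN", "sN")] <- est[c("yU", "sU")]
    est[c("yU", "sU")] <- tmp
    tmp <- se[c("yN", "sN")]
    se[c("yN", "sN")] <- se[c("yU", "sU")]
    se[c("yU", "sU")] <- tmp
  }
  structure(list(
    dG_H2O = est[["dG_H2O"]], m = est[["m"]],
    yN = est[["yN"]], sN = est[["sN"]],
    yU = est[["yU"]], sU = est[["sU"]],
    urea50 = est[["dG_H2O"]] / est[["m"]],
    se = se,
    temperature_K = TK,
    converged = isTRUE(fit$convInfo$isConv),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    fitted = stats::fitted(fit),
    curve = curve
  ), class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("<two_state_fit>\n")
  cat(sprintf("  dG_H2O = %.3f +/- %.3f kcal/mol\n", x$dG_H2O, x$se[["dG_H2O"]]))
  cat(sprintf("  m      = %.3f +/- %.3f kcal/mol/M\n", x$m, x$se[["m"]]))
  cat(sprintf("  [D]50  = %.3f M   (T = %.2f K, converged: %s)\n",
              x$urea50, x$temperature_K, x$converged))
  invisible(x)
}

#' @export
coef.two_state_fit <- function(object, ...) {
  c(dG_H2O = object$dG_H2O, m = object$m, yN = object$yN, sN = object$sN,
    yU = object$yU, sU = object$sU)
}

#' @export
predict.two_state_fit <- function(object, x = object$curve$x, ...) {
  two_state_model(x, object$dG_H2O, object$m, object$yN, object$sN,
                  object$yU, object$sU, temperature_K = object$temperature_K)
}

#' Three-state unfolding signal model
#'
#' A sequential N = I = U scheme in which each transition obeys the linear
#' extrapolation model with its own m-value and midpoint:
#' \eqn{K_1(x) = \exp(m_{IN}(x - D50_{IN})/RT)},
#' \eqn{K_2(x) = \exp(m_{UI}(x - D50_{UI})/RT)}. With linear native and
#' unfolded baselines \eqn{F_N(x) = a_N + b_N x}, \eqn{F_U(x) = a_U + b_U x}
#' and a constant intermediate signal \eqn{F_I}, the observable is the
#' population-weighted average over the three-state partition:
#' \deqn{F(x) = \frac{F_N(x) + K_1 F_I + K_1 K_2 F_U(x)}{1 + K_1 + K_1 K_2}.}
#' The unfolding free energies of the two transitions follow as
#' \eqn{\Delta G_{IN} = m_{IN} D50_{IN}} and
#' \eqn{\Delta G_{UI} = m_{UI} D50_{UI}}.
#'
#' @param x denaturant concentration, M (vectorized).
#' @param m_IN,D50_IN m-value (kcal/mol/M) and midpoint (M) of the native to
#'   intermediate transition.
#' @param m_UI,D50_UI m-value and midpoint of the intermediate to unfolded
#'   transition.
#' @param aN,bN native baseline intercept and slope.
#' @param FI intermediate-state signal (constant in denaturant).
#' @param aU,bU unfolded baseline intercept and slope.
#' @param temperature_K absolute temperature, K.
#' @return the modelled signal at each `x`.
#' @seealso [three_state_fractions()] for the state populations.
#' @export
three_state_model <- function(x, m_IN, D50_IN, m_UI, D50_UI,
                              aN, bN = 0, FI, aU, bU = 0,
                              temperature_K = .T_DEFAULT_K) {
  stopifnot(temperature_K > 0)
  RT <- .R_KCAL * temperature_K
  K1 <- .exp_safe(m_IN * (x - D50_IN) / RT)
  K2 <- .exp_safe(m_UI * (x - D50_UI) / RT)
  FN <- aN + bN * x
  FU <- aU + bU * x
  (FN + K1 * FI + K1 * K2 * FU) / (1 + K1 + K1 * K2)
}

#' Population fractions of the three-state scheme
#'
#' @inheritParams three_state_model
#' @return a matrix with columns `f_N`, `f_I`, `f_U`, one row per `x`; rows
#'   sum to 1.
#' @export
three_state_fractions <- function(x, m_IN, D50_IN, m_UI, D50_UI,
                                  temperature_K = .T_DEFAULT_K) {
  stopifnot(temperature_K > 0)
  RT <- .R_KCAL * temperature_K
  K1 <- .exp_safe(m_IN * (x - D50_IN) / RT)
  K2 <- .exp_safe(m_UI * (x - D50_UI) / RT)
  Z <- 1 + K1 + K1 * K2
  cbind(f_N = 1 / Z, f_I = K1 / Z, f_U = K1 * K2 / Z)
}

#' Fit a three-state unfolding curve
#'
#' Nonlinear least squares fit of [three_state_model()] (nine free parameters:
#' two m-values, two midpoints, two sloping baselines, one constant
#' intermediate signal) with asymptotic standard errors, and unfolding free
#' energies derived as `dG = m * D50` for each transition.
#'
#' @param curve an [unfolding_curve()] with at least 12 points.
#' @param enforce_order if `TRUE`, constrain `D50_IN < D50_UI` during the
#'   fit. Default `FALSE`.
#' @return an object of class `three_state_fit`: `m_IN`, `D50_IN`, `m_UI`,
#'   `D50_UI`, `aN`, `bN`, `FI`, `aU`, `bU`, derived `dG_IN`, `dG_UI`, `se`
#'   (named), `temperature_K`, `converged`, `residual_norm`, `suspicious`
#'   (character vector of diagnostic flags, empty when clean), `fitted`,
#'   `curve`.
#' @details Baselines are initialized from the first/last 15% of points; the
#'   two midpoints from the two largest well-separated peaks of the absolute
#'   data slope; both m-values start at 2 kcal/mol/M; the intermediate signal
#'   at the data value midway between the midpoint guesses. Fits whose
#'   intermediate signal falls outside the data range, or whose standard
#'   errors dwarf the estimates (as happens when the data contain only one
#'   transition), are flagged in `suspicious` rather than silently returned.
#' @examples
#' cur <- gen_three_state_curve(m_IN = 5.30, D50_IN = 3.26,
#'                              m_UI = 2.47, D50_UI = 6.56, noise_sd = 0)
#' fit <- fit_three_state(cur)
#' c(fit$dG_IN, fit$dG_UI)
#' @export
fit_three_state <- function(curve, enforce_order = FALSE) {
  stopifnot(inherits(curve, "unfolding_curve"))
  x <- curve$x; y <- curve$y
  n <- length(x)
  if (n < 12L) stop("need at least 12 points for a three-state fit",
                    call. = FALSE)
  TK <- curve$temperature_K

  init <- .baseline_init(x, y)
  d50 <- .two_steepest_x(x, y)
  FI0 <- stats::approx(x, y, xout = mean(d50))$y
  start <- list(m_IN = 2, D50_IN = d50[1], m_UI = 2, D50_UI = d50[2],
                aN = init$yN, bN = init$sN, FI = FI0,
                aU = init$yU, bU = init$sU)

  dat <- data.frame(x = x, y = y)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15, ptol = 1e-15)
  if (enforce_order) {
    ## reparametrize D50_UI = D50_IN + gap, gap bounded below at ~0
    start2 <- start
    start2$gap <- max(start$D50_UI - start$D50_IN, 0.1)
    start2$D50_UI <- NULL
    lower <- rep(-Inf, length(start2)); names(lower) <- names(start2)
    lower[["gap"]] <- 1e-6
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ three_state_model(x, m_IN, D50_IN, m_UI, D50_IN + gap,
                              aN, bN, FI, aU, bU, temperature_K = TK),
        data = dat, start = start2, lower = lower, control = ctrl),
      error = function(e) e)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ three_state_model(x, m_IN, D50_IN, m_UI, D50_UI,
                              aN, bN, FI, aU, bU, temperature_K = TK),
        data = dat, start = start, control = ctrl),
      error = function(e) e)
  }
  if (inherits(fit, "error")) {
    stop("three-state fit did not converge: ", conditionMessage(fit),
         call. = FALSE)
  }
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  if (enforce_order) {
    est[["D50_UI"]] <- est[["D50_IN"]] + est[["gap"]]
    ## first-order SE for the sum; correlation between the two ignored
    se[["D50_UI"]] <- sqrt(se[["D50_IN"]]^2 + se[["gap"]]^2)
    est <- est[names(est) != "gap"]; se <- se[names(se) != "gap"]
  }

  suspicious <- character(0)
  rng <- range(y)
  pad <- 0.05 * diff(rng)
  if (est[["FI"]] < rng[1] - pad || est[["FI"]] > rng[2] + pad) {
    suspicious <- c(suspicious, "intermediate signal outside data range")
  }
  for (p in c("m_IN", "D50_IN", "m_UI", "D50_UI")) {
    if (is.finite(se[[p]]) && abs(est[[p]]) > 0 &&
        se[[p]] > 10 * abs(est[[p]])) {
      suspicious <- c(suspicious,
                      sprintf("standard error of %s dwarfs the estimate", p))
    }
  }
  ## a vanishing amplitude for either transition means the data carry no
  ## information about it (two-state-shaped input)
  amp1 <- abs(est[["FI"]] - (est[["aN"]] + est[["bN"]] * est[["D50_IN"]]))
  amp2 <- abs((est[["aU"]] + est[["bU"]] * est[["D50_UI"]]) - est[["FI"]])
  if (min(amp1, amp2) < 0.02 * diff(rng)) {
    suspicious <- c(suspicious, "one transition amplitude is ~0")
  }

  structure(list(
    m_IN = est[["m_IN"]], D50_IN = est[["D50_IN"]],
    m_UI = est[["m_UI"]], D50_UI = est[["D50_UI"]],
    aN = est[["aN"]], bN = est[["bN"]], FI = est[["FI"]],
    aU = est[["aU"]], bU = est[["bU"]],
    dG_IN = est[["m_IN"]] * est[["D50_IN"]],
    dG_UI = est[["m_UI"]] * est[["D50_UI"]],
    se = se,
    temperature_K = TK,
    converged = isTRUE(fit$convInfo$isConv),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    suspicious = suspicious,
    fitted = stats::fitted(fit),
    curve = curve
  ), class = "three_state_fit")
}

#' @export
print.three_state_fit <- function(x, ...) {
  cat("<three_state_fit>\n")
  cat(sprintf("  N->I: m = %.3f +/- %.3f, D50 = %.3f +/- %.3f, dG = %.2f kcal/mol\n",
              x$m_IN, x$se[["m_IN"]], x$D50_IN, x$se[["D50_IN"]], x$dG_IN))
  cat(sprintf("  I->U: m = %.3f +/- %.3f, D50 = %.3f +/- %.3f, dG = %.2f kcal/mol\n",
              x$m_UI, x$se[["m_UI"]], x$D50_UI, x$se[["D50_UI"]], x$dG_UI))
  if (length(x$suspicious)) {
    cat("  flags:", paste(x$suspicious, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
coef.three_state_fit <- function(object, ...) {
  c(m_IN = object$m_IN, D50_IN = object$D50_IN, m_UI = object$m_UI,
    D50_UI = object$D50_UI, aN = object$aN, bN = object$bN, FI = object$FI,
    aU = object$aU, bU = object$bU)
}

#' @export
predict.three_state_fit <- function(object, x = object$curve$x, ...) {
  three_state_model(x, object$m_IN, object$D50_IN, object$m_UI, object$D50_UI,
                    object$aN, object$bN, object$FI, object$aU, object$bU,
                    temperature_K = object$temperature_K)
}

#' Choose between two-state and three-state unfolding fits
#'
#' Fits both models and prefers the one with the lower corrected Akaike
#' information criterion (AICc); a Wald-Wolfowitz runs test on the residual
#' signs of each fit is reported alongside as a lack-of-fit diagnostic.
#'
#' @param curve an [unfolding_curve()].
#' @return an object of class `model_selection`: `preferred` (`"two_state"`
#'   or `"three_state"`), `two_state` and `three_state` (the fits; the
#'   three-state slot is `NULL` when fewer than 12 points are available),
#'   `aicc` (named vector) and `runs_p` (named vector of runs-test p-values;
#'   small values mean structured residuals).
#' @details With fewer than 12 points only the two-state model is fitted and
#'   returned, with a message.
#' @export
model_select <- function(curve) {
  stopifnot(inherits(curve, "unfolding_curve"))
  fit2 <- fit_two_state(curve)
  if (length(curve$x) < 12L) {
    message("fewer than 12 points: only the two-state model was fitted")
    return(structure(list(preferred = "two_state", two_state = fit2,
                          three_state = NULL,
                          aicc = c(two_state = .aicc(fit2, 6L)),
                          runs_p = c(two_state = .runs_test_p(
                            curve$y - fit2$fitted))),
                     class = "model_selection"))
  }
  fit3 <- tryCatch(fit_three_state(curve), error = function(e) e)
  if (inherits(fit3, "error")) {
    return(structure(list(preferred = "two_state", two_state = fit2,
                          three_state = NULL,
                          aicc = c(two_state = .aicc(fit2, 6L)),
                          runs_p = c(two_state = .runs_test_p(
                            curve$y - fit2$fitted))),
                     class = "model_selection"))
  }
  aicc <- c(two_state = .aicc(fit2, 6L), three_state = .aicc(fit3, 9L))
  runs <- c(two_state = .runs_test_p(curve$y - fit2$fitted),
            three_state = .runs_test_p(curve$y - fit3$fitted))
  preferred <- names(aicc)[which.min(aicc)]
  ## do not prefer a three-state fit that is itself flagged degenerate
  if (preferred == "three_state" && length(fit3$suspicious) > 0) {
    preferred <- "two_state"
  }
  structure(list(preferred = preferred, two_state = fit2, three_state = fit3,
                 aicc = aicc, runs_p = runs),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> preferred: %s\n", x$preferred))
  cat("  AICc:", paste(sprintf("%s %.2f", names(x$aicc), x$aicc),
                       collapse = ", "), "\n")
  invisible(x)
}

## AICc from residual sum of squares; k = free mean parameters (+1 for sigma)
.aicc <- function(fit, k_mean) {
  n <- length(fit$curve$y)
  rss <- fit$residual_norm^2
  k <- k_mean + 1L
  aic <- n * log(max(rss, 1e-300) / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

## Wald-Wolfowitz runs test on residual signs (normal approximation)
.runs_test_p <- function(r) {
  s <- sign(r)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(0)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}

## shared initializers --------------------------------------------------------

## OLS baselines on the first/last 15% of points (at least 2 each)
.baseline_init <- function(x, y) {
  n <- length(x)
  k <- max(2L, floor(0.15 * n))
  head_i <- seq_len(k); tail_i <- seq.int(n - k + 1L, n)
  fN <- stats::lm.fit(cbind(1, x[head_i]), y[head_i])$coefficients
  fU <- stats::lm.fit(cbind(1, x[tail_i]), y[tail_i])$coefficients
  list(yN = fN[[1]], sN = fN[[2]], yU = fU[[1]], sU = fU[[2]],
       noise = stats::sd(c(y[head_i] - cbind(1, x[head_i]) %*% fN,
                           y[tail_i] - cbind(1, x[tail_i]) %*% fU)))
}

.warn_if_flat <- function(x, y, init) {
  mid <- mean(range(x))
  gap <- abs((init$yN + init$sN * mid) - (init$yU + init$sU * mid))
  noise <- if (is.finite(init$noise)) init$noise else 0
  if (gap <= 3 * noise + 1e-12 * max(abs(y), 1)) {
    warning("plateaus indistinguishable: fit is ill-conditioned")
  }
}

## x of the largest |dy/dx| after light smoothing
.steepest_x <- function(x, y) {
  ys <- .movavg(y, min(5L, length(y) - (1 - length(y) %% 2)))
  d <- abs(diff(ys) / diff(x))
  xc <- (x[-1] + x[-length(x)]) / 2
  xc[which.max(d)]
}

## x of the two largest well-separated |dy/dx| peaks (sorted ascending)
.two_steepest_x <- function(x, y, min_sep = 1.5) {
  ys <- .movavg(y, 5L)
  d <- abs(diff(ys) / diff(x))
  xc <- (x[-1] + x[-length(x)]) / 2
  i1 <- which.max(d)
  far <- abs(xc - xc[i1]) >= min_sep
  if (!any(far)) {
    out <- sort(c(xc[i1], xc[i1] + min_sep))
    return(pmin(pmax(out, min(x)), max(x)))
  }
  i2 <- which(far)[which.max(d[far])]
  sort(c(xc[i1], xc[i2]))
}
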