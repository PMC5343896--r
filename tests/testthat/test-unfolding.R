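# Two-state and three-state equilibrium unfolding under the linear
# extrapolation model.

test_that("two-state model has the analytic midpoint, limits and T-scaling", {
  # at x = dG/m the two states are equally populated: signal is the baseline mean
  y_mid <- two_state_model(3.5, dG_H2O = 3.5, m = 1, yN = 1, sN = 0.01,
                           yU = 0, sU = -0.01)
  expect_equal(y_mid, mean(c(1 + 0.01 * 3.5, 0 - 0.01 * 3.5)))

  # native limit at x = 0 with the strongly folded parameter set
  R <- 1.987204e-3; TK <- 283.15
  K0 <- exp(-3.37 / (R * TK))
  expect_equal(K0, 2.5e-3, tolerance = 2e-2)
  y0 <- two_state_model(0, 3.37, 0.95, yN = 1, yU = 0, temperature_K = TK)
  expect_equal(y0, (1 + 0 * K0) / (1 + K0))
  expect_lt(abs(y0 - 1), 5e-3)

  # unfolded limit, and overflow guard at absurd concentrations is finite
  expect_equal(two_state_model(9, 3.37, 0.95, yN = 1, yU = 0),
               0, tolerance = 1e-3)
  expect_true(is.finite(two_state_model(1e6, 3.37, 0.95, yN = 1, yU = 0)))

  # temperature contract: K(x) rescales consistently with RT in the exponent
  x <- 2.5; dG <- 3; m <- 1
  for (TK2 in c(283.15, 310)) {
    K <- exp((m * x - dG) / (R * TK2))
    expect_equal(two_state_model(x, dG, m, yN = 1, yU = 0, temperature_K = TK2),
                 (1 + K) ^ -1 * (1 + 0 * K) + K / (1 + K) * 0 + 0,
                 tolerance = 1e-12)
  }
})

test_that("midpoint identity reproduces dG/m and rejects bad m", {
  expect_equal(midpoint_from_lem(3.07, 0.84), 3.07 / 0.84)
  expect_equal(round(midpoint_from_lem(3.07, 0.84), 2), 3.65)
  expect_equal(midpoint_from_lem(0, 2), 0)
  expect_error(midpoint_from_lem(3, 0), "positive")
  expect_error(midpoint_from_lem(3, -1), "positive")
})

test_that("two-state fit recovers noiseless generating parameters exactly", {
  cases <- list(c(dG = 3.43, m = 0.94),   # narrow native plateau variant
                c(dG = 3.56, m = 1.00),
                c(dG = 3.20, m = 1.07))
  for (p in cases) {
    cur <- gen_two_state_curve(p[["dG"]], p[["m"]], noise_sd = 0)
    fit <- fit_two_state(cur)
    expect_true(fit$converged)
    expect_equal(fit$dG_H2O, p[["dG"]], tolerance = 1e-6)
    expect_equal(fit$m, p[["m"]], tolerance = 1e-6)
    expect_equal(fit$urea50, p[["dG"]] / p[["m"]], tolerance = 1e-9)
    expect_true(all(fit$se >= 0))
    # midpoint identity: model at urea50 sits midway between the baselines
    y50 <- predict(fit, fit$urea50)
    expect_equal(y50, mean(c(fit$yN + fit$sN * fit$urea50,
                             fit$yU + fit$sU * fit$urea50)),
                 tolerance = 1e-9)
  }
})

test_that("two-state fit matches a coarse grid-search minimizer", {
  cur <- gen_two_state_curve(3.4, 0.9, yN = 1, sN = 0, yU = 0, sU = 0,
                             noise_sd = 0.01, seed = 21)
  fit <- fit_two_state(cur)
  gs <- grid_search_two_state(cur$x, cur$y,
                              dG_grid = seq(2.5, 4.5, by = 0.05),
                              m_grid = seq(0.6, 1.2, by = 0.02),
                              yN_grid = seq(0.96, 1.04, by = 0.01),
                              yU_grid = seq(-0.04, 0.04, by = 0.01))
  expect_lte(abs(fit$dG_H2O - gs$par[["dG"]]), 0.05)
  expect_lte(abs(fit$m - gs$par[["m"]]), 0.02)
  expect_lte(fit$residual_norm^2, gs$rss + 1e-12)
})

test_that("two-state parameter recovery is unbiased under 2% noise", {
  dG <- 3.37; m <- 0.95
  amp <- 1   # baseline separation of the default generator
  ests <- t(vapply(1:100, function(s) {
    cur <- gen_two_state_curve(dG, m, noise_sd = 0.02 * amp, seed = s)
    fit <- fit_two_state(cur)
    c(fit$dG_H2O, fit$m)
  }, numeric(2)))
  expect_lt(abs(median(ests[, 1]) - dG) / dG, 0.05)
  expect_lt(abs(median(ests[, 2]) - m) / m, 0.05)
  # mean recovered dG within 2 asymptotic SEs of the generating value
  cur1 <- gen_two_state_curve(dG, m, noise_sd = 0.02 * amp, seed = 1)
  se1 <- fit_two_state(cur1)$se[["dG_H2O"]]
  expect_lt(abs(mean(ests[, 1]) - dG), 2 * se1)
})

test_that("degenerate two-state inputs are flagged", {
  x <- seq(0, 9, by = 0.25)
  flat <- unfolding_curve(x, rep(1, length(x)) + 0)
  expect_warning(try(fit_two_state(flat), silent = TRUE), "ill-conditioned")
  expect_error(fit_two_state(unfolding_curve(c(0, 1, 2), c(1, 0.5, 0))),
               "8 points")
})

test_that("three-state model limits, fractions and reductions are exact", {
  p <- list(m_IN = 5.30, D50_IN = 3.26, m_UI = 2.47, D50_UI = 6.56,
            aN = 308, bN = 0.05, FI = 313, aU = 317, bU = 0.1)
  x <- seq(0, 9, by = 0.25)

  # native limit and unfolded limit
  expect_equal(three_state_model(0, p$m_IN, p$D50_IN, p$m_UI, p$D50_UI,
                                 p$aN, p$bN, p$FI, p$aU, p$bU),
               p$aN, tolerance = 1e-6)
  expect_equal(three_state_model(9, p$m_IN, p$D50_IN, p$m_UI, p$D50_UI,
                                 p$aN, p$bN, p$FI, p$aU, p$bU),
               p$aU + p$bU * 9, tolerance = 1e-3)

  # populations sum to one everywhere, for several parameter sets
  for (seed in 1:5) {
    set.seed(seed)
    fr <- three_state_fractions(x, runif(1, 0.5, 6), runif(1, 1, 4),
                                runif(1, 0.5, 6), runif(1, 5, 8))
    expect_equal(rowSums(fr), rep(1, length(x)), tolerance = 1e-12)
    expect_true(all(fr >= 0 & fr <= 1))
  }

  # with the first transition saturated (D50_IN << 0) the model reduces to a
  # two-state transition between FI and the unfolded baseline
  red <- three_state_model(x, 5, -50, p$m_UI, p$D50_UI,
                           p$aN, p$bN, p$FI, p$aU, p$bU)
  two <- two_state_model(x, p$m_UI * p$D50_UI, p$m_UI,
                         yN = p$FI, sN = 0, yU = p$aU, sU = p$bU)
  expect_equal(red, two, tolerance = 1e-8)
})

test_that("three-state fit recovers all nine noiseless parameters", {
  sets <- list(
    list(m_IN = 5.30, D50_IN = 3.26, m_UI = 2.47, D50_UI = 6.56,
         dG_IN = 17.27, dG_UI = 16.20),
    list(m_IN = 2.48, D50_IN = 1.66, m_UI = 1.13, D50_UI = 6.58,
         dG_IN = 4.12, dG_UI = 7.43),
    list(m_IN = 1.21, D50_IN = 3.31, m_UI = 4.71, D50_UI = 6.88,
         dG_IN = 4.01, dG_UI = 32.40))
  for (p in sets) {
    cur <- gen_three_state_curve(p$m_IN, p$D50_IN, p$m_UI, p$D50_UI,
                                 noise_sd = 0)
    fit <- fit_three_state(cur)
    truth <- attr(cur, "truth")
    for (nm in c("m_IN", "D50_IN", "m_UI", "D50_UI", "aN", "bN", "FI",
                 "aU", "bU")) {
      expect_lt(abs(fit[[nm]] - truth[[nm]]) / abs(truth[[nm]]), 1e-4)
    }
    # derived free energies match the tabulated products at print precision
    expect_equal(round(fit$dG_IN, 2), round(p$m_IN * p$D50_IN, 2))
    expect_equal(round(fit$dG_UI, 2), round(p$m_UI * p$D50_UI, 2))
    # and bit-for-bit from the stored parameters
    expect_identical(fit$dG_IN, fit$m_IN * fit$D50_IN)
    expect_identical(fit$dG_UI, fit$m_UI * fit$D50_UI)
  }
})

test_that("three-state recovery stays unbiased under 2% noise", {
  p <- list(m_IN = 5.30, D50_IN = 3.26, m_UI = 2.47, D50_UI = 6.56)
  amp <- 4  # amplitude of a single transition of the default generator
  ests <- t(vapply(1:50, function(s) {
    cur <- gen_three_state_curve(p$m_IN, p$D50_IN, p$m_UI, p$D50_UI,
                                 noise_sd = 0.02 * amp, seed = 1000 + s)
    fit <- fit_three_state(cur)
    c(fit$dG_IN, fit$dG_UI, fit$m_IN, fit$m_UI)
  }, numeric(4)))
  expect_lt(abs(median(ests[, 1]) - p$m_IN * p$D50_IN) /
              (p$m_IN * p$D50_IN), 0.05)
  expect_lt(abs(median(ests[, 2]) - p$m_UI * p$D50_UI) /
              (p$m_UI * p$D50_UI), 0.05)
})

test_that("two-state-shaped data make the three-state fit confess", {
  cur <- gen_two_state_curve(3.4, 0.95, yN = 308, sN = 0.05, yU = 317,
                             sU = 0.1, noise_sd = 0.05, seed = 31)
  cur$probe <- "fluorescence"
  fit <- try(fit_three_state(cur), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    expect_gt(length(fit$suspicious), 0)
  } else {
    succeed("fit refused to converge on degenerate data")
  }
})

test_that("midpoint ordering constraint is honoured when requested", {
  cur <- gen_three_state_curve(2.5, 2.0, 2.0, 6.5, noise_sd = 0.05, seed = 41)
  fit <- fit_three_state(cur, enforce_order = TRUE)
  expect_lt(fit$D50_IN, fit$D50_UI)
  expect_warning(gen_three_state_curve(2, 6, 2, 3, noise_sd = 0), "out of order")
})

test_that("model selection prefers the generating model", {
  c2 <- gen_two_state_curve(3.4, 0.95, noise_sd = 0.02, seed = 11)
  s2 <- model_select(c2)
  expect_identical(s2$preferred, "two_state")

  c3 <- gen_three_state_curve(5.3, 3.26, 2.47, 6.56, noise_sd = 0.1, seed = 12)
  s3 <- model_select(c3)
  expect_identical(s3$preferred, "three_state")
  expect_named(s3$aicc, c("two_state", "three_state"))

  short <- unfolding_curve(seq(0, 9, length.out = 10),
                           two_state_model(seq(0, 9, length.out = 10),
                                           3.4, 0.95, yN = 1, yU = 0))
  expect_message(s <- model_select(short), "two-state")
  expect_null(s$three_state)
})
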