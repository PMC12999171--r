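ladder <- function(ec50, span = 3) 10^seq(log10(ec50) - span / 2,
                                          log10(ec50) + span / 2,
                                          length.out = 10)

test_that("Hill fit recovers noiseless parameters to under 1%", {
  s <- simulate_titration(1.1, hill_n = 1, fmin = 1, fmax = 1.45,
                          concentrations = c(0, ladder(1.1)))
  f <- fit_hill(s, n_bootstrap = 0)
  expect_equal(f$estimates$ec50, 1.1, tolerance = 0.01)
  expect_equal(f$estimates$hill_n, 1, tolerance = 0.01)
  expect_equal(f$max_dff, 0.45, tolerance = 0.01)
  # half-saturation identity of the fitted curve
  e <- f$estimates
  expect_equal(hill_curve(e$ec50, e$ec50, e$hill_n, e$fmin, e$fmax),
               (e$fmin + e$fmax) / 2)
})

test_that("Hill fit is invariant to a common fluorescence scale", {
  s <- simulate_titration(2, hill_n = 1.4, fmin = 1, fmax = 3,
                          concentrations = c(0, ladder(2)),
                          noise_sd = 0.01, seed = 12)
  f1 <- fit_hill(s, n_bootstrap = 0)
  f2 <- fit_hill(s$concentration, s$response * 7.5, n_bootstrap = 0)
  expect_equal(f2$estimates$ec50, f1$estimates$ec50, tolerance = 1e-6)
  expect_equal(f2$estimates$hill_n, f1$estimates$hill_n, tolerance = 1e-6)
})

# Titration study design used throughout: 5 replicate series (fits are to
# replicated readings, as titration experiments are run) with per-point
# noise at 2% of the response range.
test_that("noisy Hill fit stays within 10% and its bootstrap CI covers truth", {
  s <- simulate_titration(1.1, hill_n = 1, fmin = 1, fmax = 2,
                          concentrations = c(0, ladder(1.1)),
                          noise_sd = 0.02, n_replicates = 5, seed = 3)
  f <- fit_hill(s, n_bootstrap = 200, seed = 4)
  expect_equal(f$estimates$ec50, 1.1, tolerance = 0.1)
  # a proper interval around the estimate; calibration is checked below
  expect_lt(f$ec50_ci[1], f$estimates$ec50)
  expect_gt(f$ec50_ci[2], f$estimates$ec50)
})

test_that("bootstrap EC50 CI coverage is near nominal over repeated simulations", {
  conc <- c(0, ladder(1.1))
  covered <- vapply(1:100, function(i) {
    s <- simulate_titration(1.1, hill_n = 1, fmin = 1, fmax = 2,
                            concentrations = conc, noise_sd = 0.02,
                            n_replicates = 5, seed = 6000 + i)
    f <- fit_hill(s, n_bootstrap = 100, seed = 7000 + i)
    f$ec50_ci[1] <= 1.1 && f$ec50_ci[2] >= 1.1
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 0.99)
})

test_that("a titration needs at least 5 distinct concentrations", {
  expect_error(fit_hill(c(0, 1, 2, 3), c(1, 1.2, 1.5, 1.6)), "5 distinct")
})

test_that("step amplitudes are extracted from perfusion traces", {
  t <- seq(0, 100, by = 0.1)
  sch <- data.frame(concentration = c(0.5, 2, 8), onset = c(10, 40, 70))
  # flat trace -> all zero
  flat <- extract_step_amplitudes(t, rep(0.3, length(t)), sch)
  expect_equal(flat$response, c(0, 0, 0))
  # square pulses of known heights -> amplitudes equal heights
  dff <- numeric(length(t))
  heights <- c(0.2, 0.5, 0.8)
  for (i in 1:3) {
    dff[t >= sch$onset[i] & t < sch$onset[i] + 5] <- heights[i]
  }
  amp <- extract_step_amplitudes(t, dff, sch)
  expect_equal(amp$response, heights)
  # overlapping steps error
  expect_error(
    extract_step_amplitudes(t, dff, data.frame(concentration = c(1, 2),
                                               onset = c(10, 12))),
    "overlapping")
})

test_that("on-cell titration closes the loop through step extraction and the Hill fit", {
  ec50 <- 6.4
  conc <- ladder(ec50)
  onsets <- seq(10, by = 14, length.out = length(conc))  # 5 s on, 9 s wash
  t <- seq(0, max(onsets) + 14, by = 0.2)
  dff <- numeric(length(t))
  for (i in seq_along(conc)) {
    h <- hill_curve(conc[i], ec50, 1, 0, 0.9)
    dff[t >= onsets[i] & t < onsets[i] + 5] <- h
  }
  set.seed(9)
  dff <- dff + rnorm(length(t), 0, 0.01)
  series <- extract_step_amplitudes(t, dff,
                                    data.frame(concentration = conc,
                                               onset = onsets))
  f <- fit_hill(series, n_bootstrap = 0)
  expect_equal(f$estimates$ec50, ec50, tolerance = 0.1)
})

test_that("pH sigmoid fit recovers the apparent pKa", {
  ph <- seq(4.5, 9, by = 0.5)
  f_true <- 0.1 + (1 - 0.1) / (1 + 10^(6.5 - ph))
  fit <- fit_ph(ph, f_true)
  expect_equal(fit$pka, 6.5, tolerance = 0.05 / 6.5)
  expect_lt(abs(fit$pka - 6.5), 0.05)
  # midpoint identity and high-pH asymptote of the fitted model
  mid <- fit$fmin + (fit$fmax - fit$fmin) / (1 + 10^(fit$pka - fit$pka))
  expect_equal(mid, (fit$fmin + fit$fmax) / 2)
  expect_equal(fit$fmax, 1, tolerance = 0.01)
  expect_error(fit_ph(c(6, 7), c(1, 2)), "5 pH")
})

test_that("monoexponential fit recovers k_obs on a noiseless ladder to under 1%", {
  for (k in c(2, 10, 50, 120, 400)) {
    tr <- simulate_stopped_flow(k, f0 = 1, f_inf = 2,
                                duration = max(0.05, 5 / k))
    f <- fit_monoexp(tr)
    expect_equal(f$k_obs, k, tolerance = 0.01)
    expect_equal(f$f_inf, 2, tolerance = 0.01)
  }
})

test_that("a constant trace is flagged unidentifiable", {
  f <- fit_monoexp(seq(0, 1, by = 0.01), rep(3, 101))
  expect_true(is.na(f$k_obs))
  expect_match(f$flags, "unidentifiable")
})

test_that("k_obs rises monotonically over a concentration ladder", {
  conc <- c(0.5, 1, 2, 5, 10)
  k_true <- 5 + 12 * conc  # pseudo-first-order: k_obs = k_off + k_on * C
  k_hat <- vapply(seq_along(conc), function(i) {
    tr <- simulate_stopped_flow(k_true[i], f0 = 1, f_inf = 2,
                                duration = 5 / k_true[i],
                                noise_sd = 0.005, seed = 40 + i)
    fit_monoexp(tr)$k_obs
  }, numeric(1))
  expect_true(all(diff(k_hat) > 0))
  pf <- kobs_vs_concentration(k_hat, conc)
  expect_equal(pf$k_on, 12, tolerance = 0.1)
  expect_equal(pf$k_off, 5, tolerance = 0.3)
})
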