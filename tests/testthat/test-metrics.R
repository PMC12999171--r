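test_that("peak extraction recovers magnitude and sign", {
  # F0 = 100 counts, peak 177 counts -> dF/F0 = 0.77
  tr <- make_epoch_trace(0.77, 0.043, 0.073, rate = 500)
  raw <- 100 * (1 + tr$dff)
  dff <- (raw - 100) / 100
  pk <- peak_response(dff, tr$post_idx)
  expect_equal(pk$signed, 0.77, tolerance = 0.01)
  expect_equal(pk$polarity, 1)

  # identically-at-baseline trace
  flat <- peak_response(rep(0, 100), 40:90)
  expect_equal(flat$signed, 0)

  # negative-going: F0 = 100, minimum 80 -> signed -0.20, magnitude 0.20
  neg <- make_epoch_trace(0.2, 0.043, 0.073, rate = 500, polarity = -1)
  pkn <- peak_response(neg$dff, neg$post_idx)
  expect_equal(pkn$signed, -0.2, tolerance = 0.01)
  expect_equal(pkn$magnitude, 0.2, tolerance = 0.01)
  expect_equal(pkn$polarity, -1)

  expect_error(peak_response(rep(0, 10), 5:20), "outside")
})

test_that("kinetics fits recover noiseless time constants within 5%", {
  for (pars in list(c(0.77, 0.043, 0.073), c(0.3, 0.09, 0.15))) {
    tr <- make_epoch_trace(pars[1], pars[2], pars[3], rate = 250)
    kin <- fit_kinetics(tr$dff, tr$rate, tr$onset_index)
    expect_equal(kin$tau_on, pars[2], tolerance = 0.05)
    expect_equal(kin$tau_off, pars[3], tolerance = 0.05)
    expect_true(kin$rise$ok && kin$decay$ok)
  }
})

test_that("kinetics fitting flags a flat trace and reports no tau", {
  kin <- fit_kinetics(rep(0, 500), 250, 100)
  expect_false(kin$rise$ok)
  expect_false(kin$decay$ok)
  expect_true(is.na(kin$tau_on) && is.na(kin$tau_off))
})

test_that("d-prime matches its defining identities and a Gaussian simulation", {
  x <- c(rnorm(50), rnorm(50))
  same <- d_prime(c(x[1:50], x[1:50]), 1:50, 51:100)
  expect_equal(same$d_prime, 0)

  # mean difference of exactly one pooled SD
  set.seed(2)
  a <- rnorm(2000, 0, 1)
  b <- rnorm(2000, 1, 1)
  d1 <- d_prime(c(a, b), 1:2000, 2001:4000)
  expect_equal(d1$d_prime, 1, tolerance = 0.08)

  # analytic d-prime for known mu, sigma per window
  mu <- 0.6; s1 <- 0.5; s2 <- 1.5
  dd <- replicate(300, {
    d_prime(c(rnorm(60, 0, s1), rnorm(60, mu, s2)), 1:60, 61:120)$d_prime
  })
  expect_equal(mean(dd), mu / sqrt((s1^2 + s2^2) / 2), tolerance = 0.05)

  # zero pooled variance sentinel
  z <- d_prime(c(rep(1, 10), rep(3, 10)), 1:10, 11:20)
  expect_true(is.infinite(z$d_prime))
  expect_equal(z$flag, "zero-variance")
  expect_error(d_prime(rnorm(20), 1:3, 4:20), "at least 5")
})

test_that("group comparison behaves like one-way ANOVA + Tukey HSD", {
  set.seed(5)
  # identical groups: F ~ 0
  v <- rep(rnorm(10), 3)
  g <- rep(letters[1:3], each = 10)
  expect_lt(compare_groups(v, g)$f_statistic, 1e-20)

  # two groups with 5 sigma separation, n = 20: Tukey p < 0.001
  v2 <- c(rnorm(20, 0, 1), rnorm(20, 5, 1))
  g2 <- rep(c("ref", "var"), each = 20)
  cg <- compare_groups(v2, g2)
  expect_lt(cg$tukey$p_adj[1], 0.001)

  # null calibration: rejection rate approximately alpha
  rej <- mean(replicate(400, {
    compare_groups(rnorm(30), rep(1:3, each = 10))$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)

  expect_error(compare_groups(rnorm(3), c("a", "a", "b")), "at least 2 values")
})

test_that("fold change reproduces the screen's reported ratios", {
  expect_equal(round(fold_change(0.77, 0.19)$ratio, 1), 4.1)
  expect_equal(round(fold_change(67.6, 22.7)$ratio, 1), 3.0)
  expect_equal(round(fold_change(0.62, 0.19)$ratio, 1), 3.3)
  expect_equal(round(fold_change(43, 61)$percent_change), 30)
  expect_equal(fold_change(2, 2)$ratio, 1)
  expect_error(fold_change(1, 0), "nonzero")
})

test_that("metrics are scale-equivariant and polarity-symmetric", {
  m <- simulate_well(gt_improved(), small_spec(frame = 8), 17)
  a1 <- analyze_well(m)
  m2 <- m
  m2$pixels <- m$pixels * 3.7
  a2 <- analyze_well(m2)
  for (col in c("peak_signed", "tau_on", "tau_off", "d_prime")) {
    expect_equal(a1$epochs[[col]], a2$epochs[[col]], tolerance = 1e-6)
  }

  tr <- make_epoch_trace(0.5, 0.05, 0.1, rate = 250, noise_sd = 0.004,
                         seed = 31)
  pos <- fit_kinetics(tr$dff, tr$rate, tr$onset_index)
  neg <- fit_kinetics(-tr$dff, tr$rate, tr$onset_index)
  expect_equal(neg$amplitude, -pos$amplitude, tolerance = 1e-9)
  expect_equal(neg$tau_on, pos$tau_on, tolerance = 1e-9)
  expect_equal(neg$tau_off, pos$tau_off, tolerance = 1e-9)
  dp <- d_prime(tr$dff, tr$pre_idx, tr$post_idx, polarity = 1)$d_prime
  dn <- d_prime(-tr$dff, tr$pre_idx, tr$post_idx, polarity = -1)$d_prime
  expect_equal(dp, dn, tolerance = 1e-12)
})

test_that("parameter recovery over the kinetics grid has median error below 15%", {
  grid <- expand.grid(peak = c(0.1, 0.5, 1.0),
                      tau_on = c(0.02, 0.06, 0.1),
                      tau_off = c(0.05, 0.12, 0.2))
  err <- t(vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tr <- make_epoch_trace(g$peak, g$tau_on, g$tau_off, rate = 250,
                           noise_sd = 0.003, seed = 1000 + i)
    pk <- peak_response(tr$dff, tr$post_idx)
    kin <- fit_kinetics(tr$dff, tr$rate, tr$onset_index)
    abs(c(pk$magnitude / g$peak, kin$tau_on / g$tau_on,
          kin$tau_off / g$tau_off) - 1)
  }, numeric(3)))
  expect_lt(median(err[, 1]), 0.15)
  expect_lt(median(err[, 2]), 0.15)
  expect_lt(median(err[, 3]), 0.15)
})
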