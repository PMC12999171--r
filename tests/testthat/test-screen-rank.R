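test_that("well and plate QC applies the screen's discard and retest rules", {
  tab <- make_screen_tables(list(A = 0.4, B = 0.3))
  tab$wells$n_responsive[tab$wells$variant_id == "A"][1] <- 3  # < 4: discard
  tab$wells$n_responsive[tab$wells$variant_id == "B"][1:2] <- 2
  qc <- qc_wells_and_plate(tab$wells)
  expect_false(qc$wells$qc_pass[tab$wells$variant_id == "A"][1])
  # A keeps 3 passing replicates -> pass; B keeps 2 -> retest
  expect_equal(qc$variants$qc_status[qc$variants$variant_id == "A"], "pass")
  expect_equal(qc$variants$qc_status[qc$variants$variant_id == "B"], "retest")
  expect_false(qc$plate_rejected)
  expect_true(any(grepl("discarded", qc$log)))
})

test_that("a failed control well rejects the whole plate", {
  tab <- make_screen_tables(list(A = 0.4))
  tab$wells$n_responsive[tab$wells$is_control][1] <- 0
  qc <- qc_wells_and_plate(tab$wells)
  expect_true(qc$plate_rejected)
  expect_true(all(qc$variants$qc_status == "retest"))
})

test_that("a layout without control wells is an error", {
  tab <- make_screen_tables(list(A = 0.4))
  tab$wells$is_control <- FALSE
  expect_error(qc_wells_and_plate(tab$wells), "control")
})

test_that("control normalization matches the in-plate ratios", {
  expect_equal(normalize_to_control(0.38, 0.19), 2)
  expect_equal(normalize_to_control(c(0.2, 0.18), c(0.2, 0.18)), 1)
  # negative-going variant against a positive control: signed ratio
  expect_equal(normalize_to_control(-0.42, 0.19), -2.21, tolerance = 0.005)
  expect_error(normalize_to_control(1, 0), "zero")
})

test_that("variant summaries normalize to in-plate controls", {
  tab <- make_screen_tables(list(A = 0.38, B = -0.42), control_peak = 0.19,
                            pixels = 800, control_pixels = 400)
  qc <- qc_wells_and_plate(tab$wells)
  s <- summarize_variants(qc, tab$epochs)
  sA <- s[s$variant_id == "A", ]
  sB <- s[s$variant_id == "B", ]
  expect_equal(sA$norm_peak_signed, 2, tolerance = 1e-9)
  expect_equal(sA$norm_pixels, 2, tolerance = 1e-9)
  expect_equal(sB$norm_peak_signed, -0.42 / 0.19 * (1.3 / 1.3),
               tolerance = 0.01)
  expect_equal(sB$norm_peak_abs, abs(sB$norm_peak_signed), tolerance = 1e-9)
})

test_that("the responsive-pixel elimination threshold is strict and monotone", {
  tab <- make_screen_tables(list(A = 0.4, B = 0.4, C = 0.4),
                            pixels = 450)  # 4 x 450 = 1800 per variant
  tab$wells$n_responsive[tab$wells$variant_id == "A"] <- c(450, 450, 450, 449)
  qc <- qc_wells_and_plate(tab$wells)
  s <- summarize_variants(qc, tab$epochs)
  s2 <- filter_variants(s, 1800)
  expect_equal(s2$qc_status[s2$variant_id == "A"], "eliminated")  # 1799
  expect_equal(s2$qc_status[s2$variant_id == "B"], "pass")        # 1800
  # monotone in the threshold
  counts <- vapply(c(100, 1800, 1801, 5000), function(th) {
    sum(suppressWarnings(filter_variants(s, th))$qc_status == "eliminated")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_warning(filter_variants(s, 1e7), "all variants eliminated")
})

test_that("joint selection returns exactly the variants superior in both metrics", {
  peaks <- list(W1 = 0.80, W2 = 0.55, goodpeak = 0.70, null1 = 0.19,
                null2 = 0.185, lowexpr = 0.60)
  tab <- make_screen_tables(peaks, control_peak = 0.19, pixels = 800,
                            control_pixels = 400, jitter = 0.01, seed = 3)
  # goodpeak/lowexpr respond strongly but express no better than control;
  # the null variants match the control in both metrics
  tab$wells$n_responsive[tab$wells$variant_id %in% c("goodpeak", "lowexpr")] <- 300
  tab$wells$n_responsive[tab$wells$variant_id %in% c("null1", "null2")] <- 400
  qc <- qc_wells_and_plate(tab$wells)
  s <- filter_variants(summarize_variants(qc, tab$epochs),
                       min_pixels_per_plate = 100)
  winners <- select_joint_winners(s)
  expect_setequal(winners$variant_id, c("W1", "W2"))
  # ranked by normalized |dF/F0| at the 40-pulse epoch
  expect_equal(winners$variant_id[1], "W1")
})

test_that("selection is empty when no variant beats the control", {
  tab <- make_screen_tables(list(A = 0.15, B = 0.19), jitter = 0.01, seed = 5)
  qc <- qc_wells_and_plate(tab$wells)
  s <- filter_variants(summarize_variants(qc, tab$epochs), 100)
  expect_equal(nrow(select_joint_winners(s)), 0)
})

test_that("negative-going variants compete on response magnitude", {
  tab <- make_screen_tables(list(neg = -0.5), control_peak = 0.19,
                            pixels = 800, control_pixels = 400,
                            jitter = 0.01, seed = 7)
  qc <- qc_wells_and_plate(tab$wells)
  s <- filter_variants(summarize_variants(qc, tab$epochs), 100)
  winners <- select_joint_winners(s)
  expect_equal(winners$variant_id, "neg")
  expect_lt(winners$norm_peak_signed, 0)
})

test_that("normalized metrics are invariant to a plate-wide scale factor", {
  tab <- make_screen_tables(list(A = 0.4, B = 0.25), jitter = 0.01, seed = 9)
  qc1 <- qc_wells_and_plate(tab$wells)
  s1 <- summarize_variants(qc1, tab$epochs)
  tab2 <- tab
  for (col in c("peak_signed", "peak_abs", "f0")) {
    tab2$epochs[[col]] <- tab2$epochs[[col]] * 2.5
  }
  tab2$wells$f0 <- tab2$wells$f0 * 2.5
  s2 <- summarize_variants(qc_wells_and_plate(tab2$wells), tab2$epochs)
  expect_equal(s2$norm_peak_signed, s1$norm_peak_signed, tolerance = 1e-9)
  expect_equal(s2$norm_peak_abs, s1$norm_peak_abs, tolerance = 1e-9)
  expect_equal(s2$norm_f0, s1$norm_f0, tolerance = 1e-9)
})
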