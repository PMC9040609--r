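test_that("growth rate is exact on noiseless exponentials and scale-invariant", {
  tt <- seq(0, 10, 0.5)
  curve <- data.frame(time_h = tt, od = 0.1 * exp(0.14 * tt))
  expect_equal(growth_rate(curve), 0.14, tolerance = 1e-10)
  expect_equal(growth_rate(data.frame(time_h = tt, od = 0.3)), 0,
               tolerance = 1e-12)
  # invariant to multiplying OD by a positive constant
  scaled <- curve; scaled$od <- scaled$od * 37
  expect_equal(growth_rate(scaled), growth_rate(curve), tolerance = 1e-10)
  # windows with non-positive OD are skipped, not fatal
  holed <- curve; holed$od[3] <- 0
  expect_equal(growth_rate(holed), 0.14, tolerance = 1e-10)
  expect_error(growth_rate(data.frame(time_h = 1:3, od = c(0, 0, 0))))
})

test_that("od_max returns the series maximum", {
  expect_equal(od_max(data.frame(od = c(0.1, 0.5, 0.4))), 0.5)
  expect_equal(od_max(data.frame(od = rep(0.3, 5))), 0.3)
})

test_that("CFU arithmetic from spot plating", {
  expect_equal(cfu_from_spots(15, 1e5, 0.01), 1.5e8)
  expect_equal(cfu_from_spots(0, 1e5, 0.01), 0)
  expect_equal(cfu_from_spots(15, 2e5, 0.01), 2 * cfu_from_spots(15, 1e5, 0.01))
  expect_error(cfu_from_spots(15, 1e5, 0))
})

test_that("efficiency-corrected qPCR ratios follow E^(-Ct) arithmetic", {
  tgt <- tibble::tibble(sample_id = c("s1", "s2"), ct = c(20, 19),
                        efficiency = 2)
  ref <- tibble::tibble(sample_id = c("s1", "s2"), ct = c(20, 20),
                        efficiency = 2)
  out <- qpcr_relative(tgt, ref)
  expect_equal(out$rel_expression, c(1, 2))
  # self-relative expression is identically 1
  self <- qpcr_relative(tgt, tgt)
  expect_equal(self$rel_expression, c(1, 1))
  # degenerate efficiency E_t = 1 makes the ratio independent of Ct_t
  tgt1 <- tgt; tgt1$efficiency <- 1.0000001
  out1 <- qpcr_relative(tgt1, ref)
  expect_equal(out1$rel_expression[1], 1 / 2^(-20), tolerance = 1e-4)
  bad <- ref; bad$sample_id <- c("s1", "s9")
  expect_error(qpcr_relative(tgt, bad), "different samples")
})

test_that("peak detection requires local maximum, elevation and significance", {
  tp <- c(7.5, 9, 10.5, 12, 13.5)
  flat <- tidyr::expand_grid(timepoint_h = tp, replicate = 1:3)
  flat$value <- 1
  expect_equal(nrow(detect_peaks(flat)), 0)

  spiked <- flat
  set.seed(2)
  spiked$value <- 1 + rnorm(nrow(spiked), 0, 0.01)
  spiked$value[spiked$timepoint_h == 12] <-
    spiked$value[spiked$timepoint_h == 12] + 10 * 0.01
  pk <- detect_peaks(spiked)
  expect_equal(pk$timepoint_h, 12)
  expect_lt(pk$p_value, 0.05)

  # alpha = 0 returns no peaks even for huge elevations
  expect_equal(nrow(detect_peaks(spiked, alpha = 0)), 0)

  # boundary timepoints use their single neighbour
  edge <- flat
  edge$value <- rep(c(1, 1, 1, 1, 2), each = 3) + rep(rnorm(3, 0, 0.005), 5)
  pk_edge <- detect_peaks(edge)
  expect_true(13.5 %in% pk_edge$timepoint_h)

  expect_error(detect_peaks(flat, reference_time = 99), "absent")
})

test_that("survival summary separates the two limitation phenotypes", {
  sc <- tiny_scenario(seed = 14, n_proteins = 4, noise = zero_noise)
  curves <- simulate_growth_all(sc)
  surv <- survival_summary(curves)
  n_lim <- dplyr::filter(surv, condition == "N_limited")
  c_lim <- dplyr::filter(surv, condition == "C_limited")
  # cultivability collapse at ~100 h under N limitation
  expect_true(all(abs(n_lim$cfu_zero_h - 99.5) < 1e-9))
  expect_true(all(is.na(n_lim$od_decline_onset_h)))
  # OD decline but retained cultivability under C limitation
  expect_true(all(is.na(c_lim$cfu_zero_h)))
  expect_true(all(!is.na(c_lim$od_decline_onset_h)))
  expect_true(all(c_lim$terminal_alive_frac > n_lim$terminal_alive_frac))

  # a constant curve has no decline onset
  const <- tibble::tibble(condition = "x", light = "dark", replicate = 1,
                          time_h = 1:10, od = 0.5, cfu_ml = 1e8,
                          alive_frac = 1)
  expect_true(is.na(survival_summary(const)$od_decline_onset_h))
})

test_that("transcript truth peaking at transition is recovered downstream", {
  sc <- tiny_scenario(seed = 25, n_proteins = 4)
  ct <- simulate_qpcr(sc)
  rel <- qpcr_relative(dplyr::filter(ct, gene == "PR"),
                       dplyr::filter(ct, gene == "recA"))
  series <- dplyr::filter(rel, condition == "C_limited", light == "light")
  pk <- detect_peaks(series[, c("timepoint_h", "replicate")] |>
                       dplyr::mutate(value = series$rel_expression))
  expect_true(13.5 %in% pk$timepoint_h) # transition-phase PR peak
})
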