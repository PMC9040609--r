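test_that("trapezoidal integration is exact and additive", {
  tri <- data.frame(time = c(0, 1, 2), intensity = c(0, 2, 0))
  expect_equal(integrate_peak(tri), 2)
  expect_equal(integrate_peak(data.frame(time = 0:5, intensity = 0)), 0)
  set.seed(8)
  xic <- data.frame(time = sort(runif(20, 0, 10)),
                    intensity = runif(20, 0, 100))
  for (k in c(5, 10, 15)) {
    split_sum <- integrate_peak(xic[1:k, ]) +
      integrate_peak(xic[k:20, ])
    expect_equal(split_sum, integrate_peak(xic))
  }
  expect_error(integrate_peak(data.frame(time = c(1, 0), intensity = c(1, 1))))
  expect_error(integrate_peak(data.frame(time = 1, intensity = 1)))
})

test_that("amount conversion uses the 0.375 pmol spike", {
  expect_equal(standard_spike()$spike_pmol, 0.375)
  expect_equal(amount_from_ratio(1, 1), 0.375)
  expect_equal(amount_from_ratio(0, 1), 0)
  # mean peptide ratio 2 -> 0.75 pmol
  expect_equal(mean(amount_from_ratio(c(1, 3), c(1, 1))), 0.75)
  expect_error(amount_from_ratio(1, 0), "standard not detected")
})

test_that("cell counts follow the fitted linear calibration", {
  calib_tab <- data.frame(od = c(0.1, 0.4, 0.8),
                          cells_ml = 1e9 * c(0.1, 0.4, 0.8))
  calib <- fit_od_calibration(calib_tab)
  expect_equal(calib$slope, 1e9, tolerance = 1e-9)
  expect_equal(calib$intercept, 0, tolerance = 1e-3)
  expect_equal(cells_from_od(0, calib), 0, tolerance = 1e-3)
  expect_equal(cells_from_od(0.5, calib), 0.5e9 * 4.5, tolerance = 1e-6)
  expect_equal(cells_from_od(0.5, calib, volume_ml = 1), 0.5e9,
               tolerance = 1e-6)
  expect_error(cells_from_od(-1, calib))
  expect_error(fit_od_calibration(calib_tab[1:2, ]))
})

test_that("copies per cell is the molar amount times Avogadro over cells", {
  expect_equal(copies_per_cell(1e-18, 6.022e5), 1.00006, tolerance = 1e-4)
  expect_equal(copies_per_cell(1e-18, 2 * 6.022e5) * 2,
               copies_per_cell(1e-18, 6.022e5))
  expect_error(copies_per_cell(1e-18, 0))
})

test_that("scaling native areas scales amounts and copies linearly", {
  sc <- tiny_scenario(seed = 6, n_proteins = 4)
  areas <- simulate_pr_standard_areas(sc)
  curves <- simulate_growth_all(sc)
  odtab <- dplyr::filter(curves, time_h %in% sc$timepoints_h)[,
    c("condition", "light", "replicate", "time_h", "od")]
  calib <- fit_od_calibration(simulate_od_calibration(sc))
  base <- pr_quantify(areas, odtab, calib)
  scaled_areas <- areas
  scaled_areas$native_area <- scaled_areas$native_area * 3
  scaled <- pr_quantify(scaled_areas, odtab, calib)
  expect_equal(scaled$pmol, base$pmol * 3, tolerance = 1e-12)
  expect_equal(scaled$copies_per_cell, base$copies_per_cell * 3,
               tolerance = 1e-12)
})

test_that("zero-noise pipeline recovers copies/cell and fold change exactly", {
  sc <- tiny_scenario(seed = 10, n_proteins = 4, noise = zero_noise)
  areas <- simulate_pr_standard_areas(sc)
  curves <- simulate_growth_all(sc)
  odtab <- dplyr::filter(curves, time_h %in% sc$timepoints_h)[,
    c("condition", "light", "replicate", "time_h", "od")]
  calib <- fit_od_calibration(simulate_od_calibration(sc))
  pr <- pr_quantify(areas, odtab, calib, sc$spike, sc$harvest_volume_ml)
  truth <- dplyr::distinct(sc$pr_truth, condition, timepoint_h,
                           copies_per_cell)
  got <- dplyr::inner_join(pr, truth, by = c("condition", "timepoint_h"),
                           suffix = c("", "_true"))
  expect_equal(got$copies_per_cell, got$copies_per_cell_true,
               tolerance = 1e-6)
  prc <- pr_consolidate(pr)
  expect_equal(max(prc$mean_copies[prc$condition == "C_limited"]), 5606,
               tolerance = 1e-6)
  fc <- condition_fold_change(pr)
  expect_equal(fc$fold_change, 4.4, tolerance = 1e-6)
  expect_gte(fc$se, 0)
})

test_that("identical conditions give unit fold change", {
  pr <- tidyr::expand_grid(condition = c("C_limited", "N_limited"),
                           light = "light", replicate = 1:3,
                           timepoint_h = c(7.5, 9, 10.5, 12, 13.5, 15,
                                           27.5, 51.5, 75.5))
  pr$copies_per_cell <- 1000
  fc <- condition_fold_change(pr)
  expect_equal(fc$fold_change, 1)
})
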