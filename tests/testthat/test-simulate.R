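test_that("generator outputs are pure functions of scenario and seed", {
  sc <- tiny_scenario(seed = 3)
  g1 <- simulate_growth(sc, "C_limited", "light", 1, seed = 9)
  g2 <- simulate_growth(sc, "C_limited", "light", 1, seed = 9)
  expect_identical(g1, g2)
  expect_false(identical(g1$od,
                         simulate_growth(sc, "C_limited", "light", 1,
                                         seed = 10)$od))

  a1 <- simulate_pr_standard_areas(sc, seed = 4)
  a2 <- simulate_pr_standard_areas(sc, seed = 4)
  expect_identical(a1, a2)

  q1 <- simulate_qpcr(sc, seed = 4)
  q2 <- simulate_qpcr(sc, seed = 4)
  expect_identical(q1, q2)
})

test_that("noiseless growth is exactly exponential then plateaus at od_max", {
  sc <- tiny_scenario(noise = zero_noise)
  g <- simulate_growth(sc, "C_limited", "light", 1)
  early <- g[g$time_h <= 15, ]
  slopes <- diff(log(early$od)) / diff(early$time_h)
  expect_equal(slopes, rep(0.14, length(slopes)), tolerance = 1e-12)
  expect_equal(max(g$od), 0.72, tolerance = 1e-12)
})

test_that("survival phenotypes differ by limiting nutrient", {
  sc <- tiny_scenario(noise = zero_noise)
  gn <- simulate_growth(sc, "N_limited", "dark", 1)
  expect_true(all(gn$cfu_ml[gn$time_h > 100] == 0))
  expect_equal(max(gn$od), 0.83, tolerance = 1e-12)

  gc <- simulate_growth(sc, "C_limited", "dark", 1)
  late <- gc[gc$time_h > 100, ]
  expect_true(all(late$cfu_ml > 0))           # cultivable long-term
  expect_true(all(late$od < 0.72))            # but OD has declined
})

test_that("noiseless PR areas encode the exact amount ratio for both peptides", {
  sc <- tiny_scenario(noise = zero_noise)
  areas <- simulate_pr_standard_areas(sc)
  spike_pmol <- sc$spike$stock_pmol_ul * sc$spike$spike_ul
  expect_equal(spike_pmol, 0.375)
  expect_equal(areas$native_area / areas$standard_area,
               areas$true_native_pmol / spike_pmol, tolerance = 1e-12)
  # the two peptides agree exactly within a sample
  by_pep <- tidyr::pivot_wider(
    areas, id_cols = c("condition", "light", "replicate", "timepoint_h"),
    names_from = "peptide",
    values_from = c("native_area", "standard_area"))
  r1 <- by_pep$native_area_LWETQGVAK / by_pep$standard_area_LWETQGVAK
  r2 <- by_pep$native_area_NLADVVNK / by_pep$standard_area_NLADVVNK
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("noiseless Ct values follow the amplification model exactly", {
  sc <- tiny_scenario(noise = zero_noise)
  ct <- simulate_qpcr(sc)
  truth <- dplyr::inner_join(
    ct, sc$qpcr_truth,
    by = c("gene", "condition", "light", "timepoint_h"))
  expect_equal(truth$ct, -log(truth$quantity, base = truth$efficiency),
               tolerance = 1e-12)
  # E = 2 reference gene: halving the quantity adds exactly one cycle
  reca <- truth[truth$gene == "recA", ]
  expect_equal(sc$qpcr_efficiency[["recA"]], 2)
  expect_equal(-log2(reca$quantity[1] / 2) - reca$ct[1], 1)
  # recA constant across all samples
  expect_equal(length(unique(round(reca$ct, 9))), 1)
})

test_that("spectrum simulation is deterministic and channel ratios are exact at zero noise", {
  sc <- tiny_scenario(seed = 5, noise = zero_noise)
  md <- quant_metadata(sc, fractions = "cytosolic")
  s1 <- simulate_iptl_run(sc, md[1, ], seed = 2)
  s2 <- simulate_iptl_run(sc, md[1, ], seed = 2)
  f1 <- tempfile(fileext = ".mgf"); f2 <- tempfile(fileext = ".mgf")
  write_mgf(s1$spectra, f1); write_mgf(s2$spectra, f2)
  expect_identical(readLines(f1), readLines(f2))

  # every fragment pair has the intensity ratio dictated by the truth
  scheme <- label_scheme()
  truth <- s1$truth[!is.na(s1$truth$peptide), ]
  i <- match(truth$spectrum_id[1], s1$spectra$spectrum_id)
  q <- quantify_spectrum(s1$spectra$peaks[[i]], truth$peptide[1],
                         "cytosolic", scheme)
  expect_equal(q$log2_ratio, unname(truth$true_log2[1]), tolerance = 1e-9)
})

test_that("expression-level generator recovers truth at zero noise", {
  sc <- tiny_scenario(noise = zero_noise)
  expr <- simulate_expression(sc)
  truth <- dplyr::inner_join(
    expr, sc$true_log2,
    by = c("protein_id", "condition", "light", "phase"))
  expect_equal(truth$log2_ratio, truth$true_log2, tolerance = 1e-12)
  expect_true(all(expr$n_spectra >= 2))
})
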