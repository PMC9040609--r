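test_that("median-zero normalization matches hand-computed cases and is idempotent", {
  expect_equal(normalize_sample(c(-1, 0, 3)), c(-1, 0, 3))
  expect_equal(normalize_sample(c(1, 2, 4)), c(-1, 0, 2))
  set.seed(4)
  for (n in c(3, 4, 7, 10)) {           # odd and even counts
    x <- rnorm(n, 2, 3)
    z <- normalize_sample(x)
    expect_equal(median(z), 0)
    expect_equal(normalize_sample(z), z)
  }
  expect_error(normalize_sample(numeric(0)))
})

test_that("per-sample normalization zeroes every sample median", {
  tab <- tidyr::expand_grid(sample_id = c("s1", "s2", "s3"),
                            protein_id = sprintf("p%d", 1:9))
  set.seed(9)
  tab$log2_abundance <- rnorm(nrow(tab), 1, 2)
  out <- normalize_samples(tab)
  meds <- tapply(out$log2_abundance, out$sample_id, median)
  expect_equal(as.numeric(meds), rep(0, 3))
})

test_that("replicate consolidation follows the sqrt(sigma_x^2 + mu_SE^2) formula", {
  expect_equal(consolidate_replicates(c(1, 1, 1), c(0.2, 0.2, 0.2)),
               tibble::tibble(mean_log2 = 1, error = 0.2, sigma_x = 0,
                              mu_se = 0.2, n_replicates = 3L,
                              low_confidence = FALSE))
  two <- consolidate_replicates(c(0, 2), c(0, 0))
  expect_equal(two$mean_log2, 1)
  expect_equal(two$error, sqrt(2))
  three <- consolidate_replicates(c(0, 0, 0), c(0.3, 0.4, 0.5))
  expect_equal(three$mean_log2, 0)
  expect_equal(three$error, 0.4)

  one <- consolidate_replicates(1.5, 0.3)
  expect_equal(one$mean_log2, 1.5)
  expect_equal(one$error, 0.3)
  expect_true(one$low_confidence)
})

test_that("consolidated error dominates both of its components", {
  set.seed(12)
  for (i in 1:25) {
    x <- rnorm(3); se <- abs(rnorm(3, 0.2, 0.1))
    out <- consolidate_replicates(x, se)
    expect_gte(out$error + 1e-12, out$sigma_x)
    expect_gte(out$error + 1e-12, out$mu_se)
    expect_lte(out$error, out$sigma_x + out$mu_se + 1e-12)
  }
})

test_that("fraction assignment prefers more spectra with cytosolic tie-break", {
  tab <- tibble::tibble(
    protein_id = c("p1", "p1", "p2", "p3", "p3"),
    fraction = c("membrane", "cytosolic", "cytosolic", "membrane",
                 "cytosolic"),
    n_spectra = c(10L, 7L, 4L, 5L, 5L)
  )
  out <- assign_fraction(tab)
  expect_equal(out$fraction_assigned[out$protein_id == "p1"], "membrane")
  expect_equal(out$fraction_assigned[out$protein_id == "p2"], "cytosolic")
  expect_equal(out$fraction_assigned[out$protein_id == "p3"], "cytosolic")
})

test_that("phase designation is 3/4/2 over the nine standard timepoints", {
  tp <- c(7.5, 9, 10.5, 12, 13.5, 15, 27.5, 51.5, 75.5)
  ph <- assign_phase(tp)
  expect_equal(ph$phase[ph$timepoint_h == 7.5], "exponential")
  expect_equal(ph$phase[ph$timepoint_h == 10.5], "exponential")
  expect_equal(ph$phase[ph$timepoint_h == 12], "transition")
  expect_equal(ph$phase[ph$timepoint_h == 27.5], "transition")
  expect_equal(ph$phase[ph$timepoint_h == 51.5], "stationary")
  expect_equal(ph$phase[ph$timepoint_h == 75.5], "stationary")
  expect_equal(as.integer(table(ph$phase)[c("exponential", "transition",
                                            "stationary")]),
               c(3L, 4L, 2L))
  # proportional split for other counts, labels non-decreasing in time
  ph6 <- assign_phase(c(1, 2, 3, 4, 5, 6))
  expect_equal(rle(ph6$phase)$values,
               c("exponential", "transition", "stationary"))
  expect_error(assign_phase(c(1, 2)))
  expect_error(assign_phase(c(2, 1, 3)))
})

test_that("fraction summary satisfies the partition identities", {
  # 2 membrane-only, 3 cytosolic-only, 2 in both (one assigned each way)
  tab <- tibble::tibble(
    protein_id = c("m1", "m2", "c1", "c2", "c3", "b1", "b1", "b2", "b2"),
    fraction = c("membrane", "membrane", "cytosolic", "cytosolic",
                 "cytosolic", "membrane", "cytosolic", "membrane",
                 "cytosolic"),
    n_spectra = c(3L, 4L, 2L, 2L, 5L, 9L, 2L, 2L, 8L)
  )
  out <- fraction_summary(tab)
  expect_equal(out$membrane_only, 2)
  expect_equal(out$cytosolic_only, 3)
  expect_equal(out$both, 2)
  expect_equal(out$total, out$membrane_only + out$cytosolic_only + out$both)
  expect_equal(out$assigned_membrane + out$assigned_cytosolic, out$both)
  expect_equal(out$assigned_membrane, 1)

  empty <- fraction_summary(tab[0, ])
  expect_true(all(unlist(empty) == 0))
})

test_that("replicate-level table is normalized, fraction-resolved and phased", {
  sc <- tiny_scenario(seed = 19)
  md <- scenario_metadata(sc)
  md_sub <- dplyr::filter(md, condition == "C_limited", light == "light",
                          replicate == 1, timepoint_h == 7.5)
  chain <- run_quant_chain(sc, md_sub, seed = 3)
  repl <- expression_replicates(chain$proteins, md)
  expect_true(all(repl$phase == "exponential"))
  expect_true(all(repl$timepoint_h == 7.5))
  # one fraction per protein after assignment
  per_prot <- tapply(repl$fraction, repl$protein_id,
                     function(f) length(unique(f)))
  expect_true(all(per_prot == 1))
})
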