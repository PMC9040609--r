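# replicate-level table builder for hand-constructed contrast inputs
fake_replicates <- function(values_a, values_b, protein = "p1",
                            phase = "stationary") {
  tibble::tibble(
    protein_id = protein,
    condition = rep(c("C_limited", "N_limited"),
                    c(length(values_a), length(values_b))),
    light = "light",
    replicate = c(seq_along(values_a), seq_along(values_b)),
    timepoint_h = 51.5,
    phase = phase,
    log2_ratio = c(values_a, values_b),
    se = 0.1, n_spectra = 3L
  )
}

cn_contrast <- make_contrast(
  "C_vs_N_stationary",
  group_a = list(condition = "C_limited", phase = "stationary"),
  group_b = list(condition = "N_limited", phase = "stationary")
)

test_that("contrast fitting reproduces pooled two-group arithmetic", {
  f1 <- fit_contrast(fake_replicates(c(2, 2), c(1, 1)), cn_contrast)
  expect_equal(f1$effect, 1)
  expect_equal(f1$s2, 0)

  f2 <- fit_contrast(fake_replicates(c(0, 2), c(0, 0)), cn_contrast)
  expect_equal(f2$effect, 1)
  expect_equal(f2$s2, 1)
  expect_equal(f2$df, 2L)

  swapped <- make_contrast("N_vs_C", cn_contrast$group_b, cn_contrast$group_a)
  f3 <- fit_contrast(fake_replicates(c(0, 2), c(0, 0)), swapped)
  expect_equal(f3$effect, -1)

  # proteins with a 1-observation group are skipped
  f4 <- fit_contrast(fake_replicates(c(1), c(0, 0)), cn_contrast)
  expect_equal(nrow(f4), 0)
})

test_that("shrinkage has the correct fixed points and limits", {
  set.seed(5)
  tab <- purrr::map_dfr(1:30, function(i) {
    fake_replicates(rnorm(3, 1), rnorm(3, 0), protein = sprintf("p%02d", i))
  })
  fits <- fit_contrast(tab, cn_contrast)

  # identical variances are a fixed point of the shrinkage map
  same <- fits
  same$s2 <- rep(0.25, nrow(same))
  mod_same <- ebayes_moderate(same)
  expect_equal(mod_same$table$s2_post, same$s2, tolerance = 1e-9)

  # d0 -> Inf: t = effect / (s0 * sqrt(1/nA + 1/nB))
  mod_inf <- ebayes_moderate(fits, d0 = Inf)
  expect_equal(mod_inf$table$t,
               fits$effect / sqrt(mod_inf$s02 * (1 / 3 + 1 / 3)),
               tolerance = 1e-9)

  # d0 -> 0: moderated t equals the ordinary equal-variance t-test
  mod_0 <- ebayes_moderate(fits, d0 = 0)
  i <- 7
  ref <- t.test(tab$log2_ratio[tab$protein_id == sprintf("p%02d", i) &
                                 tab$condition == "C_limited"],
                tab$log2_ratio[tab$protein_id == sprintf("p%02d", i) &
                                 tab$condition == "N_limited"],
                var.equal = TRUE)
  expect_equal(mod_0$table$t[mod_0$table$protein_id == sprintf("p%02d", i)],
               unname(ref$statistic), tolerance = 1e-9)
  expect_equal(mod_0$table$p_value[mod_0$table$protein_id == sprintf("p%02d", i)],
               ref$p.value, tolerance = 1e-9)
})

test_that("moments shrinkage agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(2)
  truesd <- sqrt(0.04 * stats::rf(150, 8, 8))
  tab <- purrr::map_dfr(seq_along(truesd), function(i) {
    fake_replicates(rnorm(3, 0, truesd[i]), rnorm(3, 0, truesd[i]),
                    protein = sprintf("p%03d", i))
  })
  fits <- fit_contrast(tab, cn_contrast)
  mod <- ebayes_moderate(fits)
  sq <- limma::squeezeVar(fits$s2, df = fits$df)
  expect_equal(mod$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$s02, sq$var.prior, tolerance = 1e-6)
  expect_equal(mod$table$s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("null data yield nominal type-I error and BH control", {
  set.seed(77)
  n_prot <- 400
  tab <- purrr::map_dfr(seq_len(n_prot), function(i) {
    fake_replicates(rnorm(3, 0, 0.3), rnorm(3, 0, 0.3),
                    protein = sprintf("p%04d", i))
  })
  mod <- ebayes_moderate(fit_contrast(tab, cn_contrast))
  frac <- mean(mod$table$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_prot) + 0.01)
  expect_lte(mean(mod$table$significant), 0.05)
})

test_that("large effects with triplicates are detected with high power", {
  set.seed(9)
  hits <- purrr::map_lgl(1:40, function(i) {
    sgn <- sample(c(-2, 2), 1)
    tab <- dplyr::bind_rows(
      fake_replicates(rnorm(3, sgn, 0.3), rnorm(3, 0, 0.3), protein = "hit"),
      purrr::map_dfr(1:20, function(j) {
        fake_replicates(rnorm(3, 0, 0.3), rnorm(3, 0, 0.3),
                        protein = sprintf("null%02d", j))
      })
    )
    mod <- ebayes_moderate(fit_contrast(tab, cn_contrast))
    mod$table$significant[mod$table$protein_id == "hit"]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("BH adjustment matches step-up arithmetic", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  set.seed(3)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("phase report collects significant proteins per phase", {
  set.seed(15)
  make_phase_tab <- function(phase, t_h) {
    dplyr::bind_rows(
      purrr::map_dfr(1:15, function(j) {
        out <- fake_replicates(rnorm(6, 0, 0.3), rnorm(6, 0, 0.3),
                               protein = sprintf("null%02d", j),
                               phase = phase)
        out$timepoint_h <- t_h
        out
      }),
      {
        out <- fake_replicates(rnorm(6, 2, 0.3), rnorm(6, 0, 0.3),
                               protein = "light_responder", phase = phase)
        out$timepoint_h <- t_h
        out
      }
    )
  }
  tab <- dplyr::bind_rows(make_phase_tab("exponential", 9),
                          make_phase_tab("transition", 13.5),
                          make_phase_tab("stationary", 51.5))
  fit_phase <- function(ph) {
    ctr <- make_contrast(ph,
                         group_a = list(condition = "C_limited", phase = ph),
                         group_b = list(condition = "N_limited", phase = ph))
    ebayes_moderate(fit_contrast(tab, ctr))
  }
  all_ctr <- make_contrast("all_phases",
                           group_a = list(condition = "C_limited"),
                           group_b = list(condition = "N_limited"))
  fits <- list(exponential = fit_phase("exponential"),
               transition = fit_phase("transition"),
               stationary = fit_phase("stationary"),
               all_phases = ebayes_moderate(fit_contrast(tab, all_ctr)))
  rep_tab <- phase_report(fits)
  expect_true("light_responder" %in% rep_tab$protein_id)
  got <- rep_tab[rep_tab$protein_id == "light_responder", ]
  expect_equal(got$all_phases, 2, tolerance = 0.25)

  # empty report keeps the header shape
  none <- list(stationary = ebayes_moderate(
    fit_contrast(purrr::map_dfr(1:12, function(j) {
      fake_replicates(rnorm(3, 0, 10), rnorm(3, 0, 10),
                      protein = sprintf("n%02d", j))
    }), cn_contrast)))
  empty_rep <- phase_report(none)
  expect_true("stationary" %in% names(empty_rep))
})
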