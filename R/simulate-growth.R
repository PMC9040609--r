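# Growth, survival, calibration, MS1 peak-area and qPCR simulators.

# Dense sampling grid used for growth/survival curves: every 1.5 h to 15 h
# (as in the physiological sampling scheme), then daily-scale points out to
# ~170 h so that the post-stationary behaviour (OD decline, CFU collapse)
# is observable.
growth_times <- function() c(seq(0, 15, by = 1.5), 27.5, 51.5, 75.5,
                             99.5, 123.5, 147.5, 171.5)

# Deterministic growth model: exponential rise at mu_max capped at od_max
# (so ln OD is exactly linear in the exponential window), then a
# condition-specific exponential OD decline starting at od_decline_onset_h.
od_model <- function(t, g) {
  t_sat <- log(g$od_max / g$od0) / g$mu_max
  od <- ifelse(t < t_sat, g$od0 * exp(g$mu_max * t), g$od_max)
  if (!is.na(g$od_decline_onset_h) && g$od_decline_rate > 0) {
    dec <- t > g$od_decline_onset_h
    od[dec] <- g$od_max * exp(-g$od_decline_rate * (t[dec] - g$od_decline_onset_h))
  }
  od
}

cfu_model <- function(t, g, od_cells_slope) {
  t_sat <- log(g$od_max / g$od0) / g$mu_max
  cfu_sat <- g$od_max * od_cells_slope
  cfu <- ifelse(t < t_sat, g$od0 * exp(g$mu_max * t) * od_cells_slope,
                cfu_sat * exp(-g$cfu_decline_rate * pmax(0, t - t_sat)))
  if (!is.na(g$cfu_zero_h)) cfu[t >= g$cfu_zero_h] <- 0
  cfu
}

alive_model <- function(t, g) {
  t_sat <- log(g$od_max / g$od0) / g$mu_max
  # sigmoid relaxation from 1 towards the terminal alive fraction
  frac <- g$terminal_alive_frac +
    (1 - g$terminal_alive_frac) / (1 + exp((t - (t_sat + 25)) / 10))
  pmin(1, pmax(0, frac))
}

#' Simulate a growth / survival curve
#'
#' Optical density, colony-forming units and alive (membrane-intact)
#' fraction versus time for one culture. The deterministic model is
#' exponential growth at `mu_max` capped at `od_max`; the C-limited
#' parameterisation then declines exponentially in OD while retaining
#' cultivability, whereas the N-limited one holds OD but collapses in CFU
#' (zero by `cfu_zero_h`). Multiplicative lognormal noise with sd
#' `scenario$noise$od_sd` is applied to OD and CFU.
#'
#' @param scenario An `iptl_scenario`.
#' @param condition Condition name present in `scenario$growth`.
#' @param light `"light"` or `"dark"` (annotation only; the scenario growth
#'   truth is light-independent).
#' @param replicate Replicate number (annotation + noise stream).
#' @param seed Integer seed.
#' @param times Time grid in hours (default [growth_times()]).
#' @return Tibble `time_h`, `od`, `cfu_ml`, `alive_frac`, `condition`,
#'   `light`, `replicate`.
#' @export
simulate_growth <- function(scenario, condition, light = "light",
                            replicate = 1, seed = scenario$seed,
                            times = growth_times()) {
  g <- scenario$growth %>% filter(.data$condition == .env$condition)
  check_that(nrow(g) == 1, sprintf("condition \"%s\" not in scenario", condition))
  sdlog <- scenario$noise$od_sd
  with_seed(derive_seed(seed, paste("growth", condition, light, replicate)), {
    od <- od_model(times, g) * rlnorm(length(times), 0, sdlog)
    cfu <- cfu_model(times, g, scenario$od_cells_slope) *
      rlnorm(length(times), 0, sdlog)
    tibble(
      time_h = times,
      od = od,
      cfu_ml = cfu,
      alive_frac = alive_model(times, g),
      condition = condition,
      light = light,
      replicate = as.integer(replicate)
    )
  })
}

#' Simulate growth curves for the whole design
#'
#' @inheritParams simulate_growth
#' @return Row-bound [simulate_growth()] tibbles over condition x light x
#'   replicate.
#' @export
simulate_growth_all <- function(scenario, seed = scenario$seed,
                                times = growth_times()) {
  grid <- tidyr::expand_grid(condition = scenario$conditions,
                             light = scenario$lights,
                             replicate = seq_len(scenario$replicates))
  purrr::pmap_dfr(grid, function(condition, light, replicate) {
    simulate_growth(scenario, condition, light, replicate, seed, times)
  })
}

#' Simulate an OD-to-cell-density calibration data set
#'
#' Paired (OD, cells/mL) observations emulating the calibration of optical
#' density against CFU and volumetric (flow-cytometry) cell counts. Truth
#' is linear through the origin with slope `scenario$od_cells_slope`;
#' multiplicative lognormal noise of sd `scenario$noise$calib_sd` is
#' applied to the counts.
#'
#' @param scenario An `iptl_scenario`.
#' @param seed Integer seed.
#' @param n_points Number of calibration points (default 8).
#' @return Tibble `od`, `cells_ml`.
#' @export
simulate_od_calibration <- function(scenario, seed = scenario$seed,
                                    n_points = 8) {
  check_number(n_points, "n_points", lower = 3)
  with_seed(derive_seed(seed, "calibration"), {
    od <- seq(0.05, 0.9, length.out = n_points)
    tibble(
      od = od,
      cells_ml = od * scenario$od_cells_slope *
        rlnorm(n_points, 0, scenario$noise$calib_sd)
    )
  })
}

#' Simulate MS1 peak areas for the proteorhodopsin standard peptides
#'
#' For every (condition, light, replicate, proteomic timepoint) sample and
#' each of the two PR marker peptides, emits a native (endogenous,
#' light-lysine) and a heavy-standard (13C6,15N2-lysine) MS1 peak area.
#' The spiked standard amount is `stock_pmol_ul * spike_ul` (default
#' 0.5 x 0.75 = 0.375 pmol per analyzed mix); the true native amount
#' derives from the scenario's copies-per-cell trajectory and the true cell
#' density (OD model x cells-per-OD slope x harvest volume). The
#' native/standard area ratio equals the amount ratio up to multiplicative
#' lognormal noise of sd `scenario$noise$area_sd` per area.
#'
#' @param scenario An `iptl_scenario`.
#' @param seed Integer seed.
#' @return Tibble `condition`, `light`, `replicate`, `timepoint_h`,
#'   `peptide`, `native_area`, `standard_area`, plus the bookkeeping truth
#'   columns `true_native_pmol` and `true_cells`.
#' @export
simulate_pr_standard_areas <- function(scenario, seed = scenario$seed) {
  check_that(!is.null(scenario$pr_truth), "scenario must define pr_copies_per_cell truth")
  spike_pmol <- scenario$spike$stock_pmol_ul * scenario$spike$spike_ul
  avogadro <- 6.02214076e23
  grid <- tidyr::expand_grid(
    condition = scenario$conditions,
    light = scenario$lights,
    replicate = seq_len(scenario$replicates),
    timepoint_h = scenario$timepoints_h,
    peptide = PR_PEPTIDES
  ) %>%
    inner_join(scenario$pr_truth, by = c("condition", "timepoint_h"))
  g_by_cond <- split(scenario$growth, scenario$growth$condition)
  grid <- grid %>%
    mutate(
      od_true = purrr::map2_dbl(.data$condition, .data$timepoint_h,
                                function(cn, t) od_model(t, g_by_cond[[cn]])),
      true_cells = .data$od_true * scenario$od_cells_slope *
        scenario$harvest_volume_ml,
      true_native_pmol = .data$copies_per_cell * .data$true_cells /
        avogadro * 1e12
    )
  sdlog <- scenario$noise$area_sd
  with_seed(derive_seed(seed, "pr_areas"), {
    n <- nrow(grid)
    base <- rlnorm(n, log(1e6), 0.3)   # per-injection scale, cancels in ratio
    grid %>%
      mutate(
        standard_area = base * rlnorm(n, 0, sdlog),
        native_area = base * (.data$true_native_pmol / spike_pmol) *
          rlnorm(n, 0, sdlog)
      ) %>%
      select("condition", "light", "replicate", "timepoint_h", "peptide",
             "native_area", "standard_area", "true_native_pmol", "true_cells")
  })
}

#' Simulate a qPCR Ct table
#'
#' Ct values from the scenario's true transcript quantities under the
#' standard amplification model `Ct = -log_E(quantity)` plus Gaussian noise
#' (sd `scenario$noise$ct_sd`). The reference gene recA has constant true
#' quantity across all samples.
#'
#' @param scenario An `iptl_scenario`.
#' @param gene Gene name (must appear in `scenario$qpcr_truth`); default
#'   all genes of the scenario.
#' @param seed Integer seed.
#' @return Tibble `gene`, `sample_id`, `condition`, `light`, `replicate`,
#'   `timepoint_h`, `ct`, `efficiency`.
#' @export
simulate_qpcr <- function(scenario, gene = names(scenario$qpcr_efficiency),
                          seed = scenario$seed) {
  check_that(all(gene %in% unique(scenario$qpcr_truth$gene)),
             "gene not present in scenario qPCR truth")
  eff <- scenario$qpcr_efficiency[gene]
  check_that(all(eff > 1 & eff <= 2), "per-gene efficiency must lie in (1, 2]")
  tab <- tidyr::expand_grid(
    gene = gene,
    condition = scenario$conditions,
    light = scenario$lights,
    replicate = seq_len(scenario$replicates),
    timepoint_h = scenario$timepoints_h
  ) %>%
    inner_join(scenario$qpcr_truth,
               by = c("gene", "condition", "light", "timepoint_h")) %>%
    mutate(efficiency = unname(.env$eff[.data$gene]))
  with_seed(derive_seed(seed, "qpcr"), {
    tab %>%
      mutate(
        ct = -log(.data$quantity, base = .data$efficiency) +
          rnorm(n(), 0, scenario$noise$ct_sd),
        sample_id = sprintf("%s_%s_r%d_t%s", .data$condition, .data$light,
                            .data$replicate, .data$timepoint_h)
      ) %>%
      select("gene", "sample_id", "condition", "light", "replicate",
             "timepoint_h", "ct", "efficiency")
  })
}

#' Simulate a replicate-level protein expression table
#'
#' The generator's expression-level layer: draws per-replicate normalized
#' log2 sample/standard ratios directly from the scenario's expression
#' truth, bypassing spectrum simulation and matching. Each protein x sample
#' receives `n_spectra = 2 + Poisson(2)` spectra; the observed log2 ratio
#' is the truth plus Gaussian noise of sd `spectrum_sd / sqrt(n_spectra)`,
#' with a matching standard error. Useful for exercising the
#' consolidation/differential-expression layers at full design size; the
#' spectrum-level layer ([simulate_iptl_run()]) validates the same
#' quantities end to end on smaller designs.
#'
#' @param scenario An `iptl_scenario`.
#' @param seed Integer seed.
#' @return Tibble `protein_id`, `condition`, `light`, `replicate`,
#'   `timepoint_h`, `phase`, `log2_ratio`, `se`, `n_spectra`.
#' @export
simulate_expression <- function(scenario, seed = scenario$seed) {
  phases <- assign_phase(scenario$timepoints_h)
  grid <- tidyr::expand_grid(
    protein_id = scenario$proteome$protein_id,
    condition = scenario$conditions,
    light = scenario$lights,
    replicate = seq_len(scenario$replicates),
    timepoint_h = scenario$timepoints_h
  ) %>%
    left_join(phases, by = "timepoint_h") %>%
    inner_join(scenario$true_log2,
               by = c("protein_id", "condition", "light", "phase"))
  sdl <- scenario$noise$spectrum_sd
  with_seed(derive_seed(seed, "expression"), {
    grid %>%
      mutate(
        n_spectra = 2L + rpois(n(), 2),
        se = sdl / sqrt(.data$n_spectra),
        log2_ratio = .data$true_log2 + rnorm(n(), 0, .data$se)
      ) %>%
      select("protein_id", "condition", "light", "replicate", "timepoint_h",
             "phase", "log2_ratio", "se", "n_spectra")
  })
}
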