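# Scenario objects: the ground truth that drives every generator output.
#
# A scenario bundles the experimental design (conditions x light x replicate
# x timepoint), the true protein expression profiles versus the pooled
# internal standard, the true proteorhodopsin copies-per-cell trajectories,
# the growth model parameters, the qPCR transcript truths, and the noise
# levels. All simulate_* functions are pure functions of (scenario, seed).

PROTEOMIC_TIMEPOINTS <- c(7.5, 9, 10.5, 12, 13.5, 15, 27.5, 51.5, 75.5)

#' Defined media for the C- and N-limited growth conditions
#'
#' The two minimal media differ only in the maltose and ammonium chloride
#' concentrations: 2.78 mM maltose + 2 mM NH4Cl (carbon limited) and
#' 8.33 mM maltose + 1 mM NH4Cl (nitrogen limited).
#'
#' @return Tibble with `condition`, `maltose_mM`, `nh4cl_mM`, `cn_ratio`.
#' @examples
#' vibrio_media() # C/N molar ratios 16.68 and 99.96
#' @export
vibrio_media <- function() {
  tibble(
    condition = c("C_limited", "N_limited"),
    maltose_mM = c(2.78, 8.33),
    nh4cl_mM = c(2, 1)
  ) %>%
    mutate(cn_ratio = media_cn_ratio(.data$maltose_mM, .data$nh4cl_mM))
}

#' Molar C/N ratio of a maltose + ammonium medium
#'
#' Maltose contributes 12 carbon atoms per molecule; NH4Cl one nitrogen.
#'
#' @param maltose_mM Maltose concentration (mM).
#' @param nh4cl_mM Ammonium chloride concentration (mM).
#' @param carbons_per_molecule Carbons per carbon-source molecule
#'   (default 12, maltose).
#' @return Molar C:N ratio (dimensionless).
#' @examples
#' media_cn_ratio(2.78, 2) # 16.68
#' media_cn_ratio(8.33, 1) # 99.96
#' @export
media_cn_ratio <- function(maltose_mM, nh4cl_mM, carbons_per_molecule = 12) {
  check_number(maltose_mM, "maltose_mM", lower = 0)
  check_number(nh4cl_mM, "nh4cl_mM", lower = 1e-12)
  maltose_mM * carbons_per_molecule / nh4cl_mM
}

#' Construct a simulation scenario
#'
#' Low-level constructor; most users want [scenario_caim519()]. Validates
#' the design invariants (increasing timepoints, >= 2 replicates,
#' non-negative noise).
#'
#' @param proteome Toy proteome tibble ([make_toy_proteome()]).
#' @param true_log2 Tibble `protein_id`, `condition`, `light`, `phase`,
#'   `true_log2`: the true log2 sample/standard abundance ratio.
#' @param growth Tibble of growth parameters per condition (see
#'   [scenario_caim519()] for the fields).
#' @param pr_truth Tibble `condition`, `timepoint_h`, `copies_per_cell`.
#' @param qpcr_truth Tibble `gene`, `condition`, `light`, `timepoint_h`,
#'   `quantity` (true transcript quantity, arbitrary units < 1 so Ct > 0).
#' @param qpcr_efficiency Named numeric vector of per-gene amplification
#'   efficiencies in (1, 2].
#' @param timepoints_h Proteomic sampling times (strictly increasing).
#' @param replicates Biological replicates per condition x light (>= 2).
#' @param noise Named list: `spectrum_sd` (lognormal sd of fragment
#'   intensities, natural-log scale), `area_sd` (MS1 peak areas), `od_sd`
#'   (optical density), `ct_sd` (qPCR Ct, additive), `calib_sd`
#'   (cell-count calibration). All >= 0; 0 switches noise off.
#' @param od_cells_slope True cells/mL per OD unit (default 1e9).
#' @param harvest_volume_ml Culture volume harvested per proteomic sample
#'   (default 4.5 mL).
#' @param spike Heavy-standard spike description, see [standard_spike()].
#' @param spectra List of spectrum-simulation knobs: `mean_extra_spectra`
#'   (Poisson mean of spectra per peptide beyond the first),
#'   `base_intensity_meanlog`, `base_intensity_sdlog`, `noise_spectra_frac`.
#' @param seed Integer seed recorded with the scenario.
#' @return Object of class `iptl_scenario` (a named list).
#' @export
new_scenario <- function(proteome, true_log2, growth, pr_truth, qpcr_truth,
                         qpcr_efficiency,
                         timepoints_h = PROTEOMIC_TIMEPOINTS,
                         replicates = 3,
                         noise = list(spectrum_sd = 0.25, area_sd = 0.1,
                                      od_sd = 0.02, ct_sd = 0.15,
                                      calib_sd = 0.05),
                         od_cells_slope = 1e9,
                         harvest_volume_ml = 4.5,
                         spike = standard_spike(),
                         spectra = list(mean_extra_spectra = 1.7,
                                        base_intensity_meanlog = log(1e5),
                                        base_intensity_sdlog = 1,
                                        noise_spectra_frac = 0.1),
                         seed = 1) {
  check_that(all(diff(timepoints_h) > 0), "timepoints_h must be strictly increasing")
  check_number(replicates, "replicates", lower = 2)
  check_that(all(unlist(noise) >= 0), "noise sds must be >= 0")
  check_that(all(qpcr_efficiency > 1 & qpcr_efficiency <= 2),
             "qPCR efficiencies must lie in (1, 2]")
  structure(
    list(
      proteome = proteome,
      pr_id = attr(proteome, "pr_id") %||% "PR",
      conditions = unique(growth$condition),
      lights = c("light", "dark"),
      replicates = as.integer(replicates),
      timepoints_h = timepoints_h,
      true_log2 = true_log2,
      growth = growth,
      pr_truth = pr_truth,
      qpcr_truth = qpcr_truth,
      qpcr_efficiency = qpcr_efficiency,
      noise = noise,
      od_cells_slope = od_cells_slope,
      harvest_volume_ml = harvest_volume_ml,
      spike = spike,
      spectra = spectra,
      seed = as.integer(seed)
    ),
    class = "iptl_scenario"
  )
}

#' The study-matched default scenario ("caim519")
#'
#' Encodes the study conditions for the V. campbellii CAIM 519 experiments
#' as generator ground truth:
#' * triplicate C-limited and N-limited cultures under continuous light and
#'   dark, proteomic sampling at 7.5-75.5 h (9 timepoints, phases 3/4/2);
#' * growth: mu_max 0.14 / 0.15 1/h and OD_max 0.72 / 0.83 for the C- and
#'   N-limited media; post-stationary OD decline under C limitation;
#'   cultivability collapse (CFU -> 0 by ~100 h) under N limitation;
#' * proteorhodopsin: protein rising through exponential phase to a
#'   stationary plateau, maximum 5606 copies/cell (C-limited), with the
#'   stationary plateau 4.4-fold higher under C than N limitation;
#' * transcripts: PR and rpoS peaking at the exponential-stationary
#'   transition, blh with transition and late-stationary peaks, recA flat
#'   (reference gene);
#' * protein expression truth structured by condition, light and phase:
#'   ~60% null proteins, ~30% condition responders, ~10% light responders.
#'
#' @param n_proteins Size of the toy proteome (default 40).
#' @param replicates Biological replicates (default 3).
#' @param seed Integer seed; drives the proteome and the randomly drawn
#'   expression truth.
#' @param noise Optional named list overriding individual default noise
#'   components (see [new_scenario()]).
#' @return An `iptl_scenario`.
#' @examples
#' sc <- scenario_caim519(n_proteins = 10, seed = 1)
#' sc$growth
#' @export
scenario_caim519 <- function(n_proteins = 40, replicates = 3, seed = 1,
                             noise = list()) {
  proteome <- make_toy_proteome(n_proteins, mean_length = 250,
                                seed = derive_seed(seed, "proteome"))
  growth <- tibble(
    condition = c("C_limited", "N_limited"),
    mu_max = c(0.14, 0.15),
    od_max = c(0.72, 0.83),
    od0 = c(0.02, 0.02),
    od_decline_onset_h = c(50, NA),
    od_decline_rate = c(0.012, 0),
    cfu_decline_rate = c(0.004, 0.08),
    cfu_zero_h = c(NA, 99.5),
    terminal_alive_frac = c(0.85, 0.1)
  )
  # PR copies/cell trajectories: rise through exponential phase to a
  # stationary plateau; C-limited peaks at 5606; stationary-plateau means
  # (last two timepoints) in exact 4.4:1 C/N ratio.
  c_copies <- c(800, 1200, 1800, 2600, 3500, 4300, 5300, 5606, 5450)
  n_copies <- c(250, 380, 550, 750, 900, 1000, 1150,
                1274.1, sum(c(5606, 5450)) / 4.4 - 1274.1)
  pr_truth <- tibble(
    condition = rep(c("C_limited", "N_limited"), each = 9),
    timepoint_h = rep(PROTEOMIC_TIMEPOINTS, 2),
    copies_per_cell = c(c_copies, n_copies)
  )
  # transcript truths (arbitrary quantity units, all < 1 so Ct > 0)
  base <- 1e-6
  shapes <- list(
    PR   = c(0.2, 0.3, 0.6, 1.5, 3.0, 2.5, 1.2, 0.5, 0.3),
    blh  = c(0.2, 0.25, 0.4, 0.9, 1.8, 1.2, 0.8, 2.6, 1.5),
    rpoS = c(0.5, 0.8, 1.4, 2.6, 3.2, 2.4, 1.2, 0.8, 0.6),
    recA = rep(1, 9)
  )
  qpcr_truth <- purrr::imap_dfr(shapes, function(shape, gene) {
    tidyr::expand_grid(condition = c("C_limited", "N_limited"),
                       light = c("light", "dark")) %>%
      mutate(profile = purrr::pmap(list(.data$condition, .data$light),
                                   function(cond, lt) {
        f <- 1
        # dark-elevated PR transcription under C limitation (2.3-fold,
        # transition/stationary only)
        if (gene == "PR" && cond == "C_limited" && lt == "dark") {
          f <- c(rep(1, 3), rep(2.3, 6))
        }
        # N-limited transcript amplitudes modestly lower for PR
        amp <- if (gene == "PR" && cond == "N_limited") 0.5 else 1
        tibble(timepoint_h = PROTEOMIC_TIMEPOINTS,
               quantity = base * shape * f * amp)
      })) %>%
      tidyr::unnest("profile") %>%
      mutate(gene = gene, .before = 1)
  })
  efficiency <- c(PR = 1.96, blh = 1.94, rpoS = 1.98, recA = 2.0)
  true_log2 <- draw_expression_truth(proteome$protein_id,
                                     seed = derive_seed(seed, "truth"))
  default_noise <- list(spectrum_sd = 0.25, area_sd = 0.1, od_sd = 0.02,
                        ct_sd = 0.15, calib_sd = 0.05)
  noise <- utils::modifyList(default_noise, noise)
  new_scenario(proteome, true_log2, growth, pr_truth, qpcr_truth, efficiency,
               replicates = replicates, noise = noise, seed = seed)
}

# Condition/light/phase-structured expression truth. Roughly 60% of
# proteins are null (flat at the pooled-standard level), 30% respond to the
# limiting nutrient with a phase-amplified effect, 10% respond to light.
draw_expression_truth <- function(protein_ids, seed,
                                  p_condition = 0.3, p_light = 0.1) {
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      protein_id = protein_ids,
      condition = c("C_limited", "N_limited"),
      light = c("light", "dark"),
      phase = c("exponential", "transition", "stationary")
    )
    type <- sample(c("null", "condition", "light"), length(protein_ids),
                   replace = TRUE,
                   prob = c(1 - p_condition - p_light, p_condition, p_light))
    effect <- runif(length(protein_ids), 1, 3) *
      sample(c(-1, 1), length(protein_ids), replace = TRUE)
    info <- tibble(protein_id = protein_ids, type = type, effect = effect)
    phase_amp <- c(exponential = 0.7, transition = 1, stationary = 1.3)
    grid %>%
      left_join(info, by = "protein_id") %>%
      mutate(true_log2 = case_when(
        .data$type == "condition" & .data$condition == "C_limited" ~
          .data$effect * phase_amp[.data$phase] / 2,
        .data$type == "condition" & .data$condition == "N_limited" ~
          -.data$effect * phase_amp[.data$phase] / 2,
        .data$type == "light" & .data$light == "light" ~
          .data$effect * phase_amp[.data$phase] / 2,
        .data$type == "light" & .data$light == "dark" ~
          -.data$effect * phase_amp[.data$phase] / 2,
        TRUE ~ 0
      )) %>%
      select("protein_id", "condition", "light", "phase", "true_log2")
  })
}

#' Sample metadata table for a scenario
#'
#' Enumerates every LC-MS sample of the design: condition x light x
#' replicate x proteomic timepoint x peptide fraction, with the growth
#' phase of each timepoint.
#'
#' @param scenario An `iptl_scenario`.
#' @param fractions Fractions to include (default membrane + cytosolic).
#' @return Tibble with `sample_id`, `condition`, `light`, `replicate`,
#'   `timepoint_h`, `phase`, `fraction`.
#' @export
scenario_metadata <- function(scenario,
                              fractions = c("membrane", "cytosolic")) {
  phases <- assign_phase(scenario$timepoints_h)
  tidyr::expand_grid(
    condition = scenario$conditions,
    light = scenario$lights,
    replicate = seq_len(scenario$replicates),
    timepoint_h = scenario$timepoints_h,
    fraction = fractions
  ) %>%
    left_join(phases, by = "timepoint_h") %>%
    mutate(sample_id = sprintf("%s_%s_r%d_t%s_%s",
                               .data$condition, .data$light, .data$replicate,
                               .data$timepoint_h, .data$fraction)) %>%
    select("sample_id", "condition", "light", "replicate",
           "timepoint_h", "phase", "fraction")
}

#' @export
print.iptl_scenario <- function(x, ...) {
  cat("<iptl_scenario>\n")
  cat(sprintf("  proteome: %d proteins (PR entry: %s)\n",
              nrow(x$proteome), x$pr_id))
  cat(sprintf("  design: %s x {light,dark} x %d replicates x %d timepoints\n",
              paste(x$conditions, collapse = "/"), x$replicates,
              length(x$timepoints_h)))
  cat(sprintf("  noise: %s\n",
              paste(sprintf("%s=%g", names(x$noise), unlist(x$noise)),
                    collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
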