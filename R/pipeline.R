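# End-to-end orchestration: simulate -> quantify -> tables -> diffexpr ->
# PR absolute quantification -> physiology, with all outputs written as
# plain-text tables plus a machine-readable summary.

default_contrasts <- function() {
  phases <- c("exponential", "transition", "stationary")
  out <- list()
  for (ph in c(phases, list(NULL))) {
    tag <- if (is.null(ph)) "all_phases" else ph
    out[[paste0("light_vs_dark_", tag)]] <- make_contrast(
      paste0("light_vs_dark_", tag),
      group_a = list(light = "light", phase = ph),
      group_b = list(light = "dark", phase = ph)
    )
    out[[paste0("C_vs_N_", tag)]] <- make_contrast(
      paste0("C_vs_N_", tag),
      group_a = list(condition = "C_limited", phase = ph),
      group_b = list(condition = "N_limited", phase = ph)
    )
  }
  out
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates all inputs for a scenario and pushes them through every
#' analysis stage, writing CSV tables and a summary JSON to `outdir`.
#' Stages: growth simulation and physiology summaries; qPCR simulation,
#' recA-normalized relative expression and peak detection; PR
#' standard-peptide areas, OD calibration and absolute quantification
#' (copies/cell, stationary C/N fold change); spectrum-level diDO-IPTL
#' quantification (simulate, MGF round trip, match, q-value filter,
#' quantify, aggregate, fraction bookkeeping) on `quant_metadata` samples;
#' and moderated differential expression on the expression-level
#' generator layer. Reruns with the same scenario and seed are
#' byte-identical.
#'
#' @param scenario An `iptl_scenario` (default [scenario_caim519()]).
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for every stochastic stage.
#' @param quant_metadata Sample rows ([scenario_metadata()]) to run
#'   through the spectrum-level quantification chain. Default: both
#'   fractions of the first and last C-limited light timepoints of
#'   replicate 1 (a small but fraction-complete subset).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(scenario = scenario_caim519(), outdir, seed = scenario$seed,
                         quant_metadata = NULL) {
  check_that(!missing(outdir) && is.character(outdir), "outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) readr::write_csv(x, file.path(outdir, name))
  msg <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

  # --- physiology -----------------------------------------------------
  msg("growth", "simulating growth/survival curves")
  curves <- simulate_growth_all(scenario, seed)
  wr(curves, "growth_curves.csv")
  gsum <- growth_summary(curves)
  wr(gsum, "growth_summary.csv")
  surv <- survival_summary(curves)
  wr(surv, "survival_summary.csv")
  gcond <- gsum %>%
    group_by(.data$condition) %>%
    summarise(mu_max = mean(.data$mu_max), od_max = mean(.data$od_max),
              .groups = "drop")

  # --- qPCR ------------------------------------------------------------
  msg("qpcr", "simulating Ct tables and computing relative expression")
  ct <- simulate_qpcr(scenario, seed = seed)
  wr(ct, "qpcr_ct.csv")
  ref <- ct %>% filter(.data$gene == "recA")
  rel <- ct %>%
    filter(.data$gene != "recA") %>%
    group_by(.data$gene) %>%
    dplyr::group_modify(~ qpcr_relative(.x, ref)) %>%
    ungroup()
  wr(rel, "qpcr_relative.csv")
  peaks <- rel %>%
    group_by(.data$gene, .data$condition, .data$light) %>%
    dplyr::group_modify(~ detect_peaks(
      .x %>% select("timepoint_h", "replicate", value = "rel_expression"))) %>%
    ungroup()
  wr(peaks, "qpcr_peaks.csv")

  # --- PR absolute quantification -------------------------------------
  msg("pr", "absolute proteorhodopsin quantification")
  calib_data <- simulate_od_calibration(scenario, seed)
  wr(calib_data, "od_calibration.csv")
  calibration <- fit_od_calibration(calib_data)
  areas <- simulate_pr_standard_areas(scenario, seed)
  wr(areas %>% select(-"true_native_pmol", -"true_cells"), "pr_areas.csv")
  od_tab <- curves %>%
    filter(.data$time_h %in% scenario$timepoints_h) %>%
    select("condition", "light", "replicate", "time_h", "od")
  pr_tab <- pr_quantify(areas, od_tab, calibration, scenario$spike,
                        scenario$harvest_volume_ml)
  wr(pr_tab, "pr_abundance.csv")
  pr_cons <- pr_consolidate(pr_tab)
  wr(pr_cons, "pr_consolidated.csv")
  phases <- assign_phase(scenario$timepoints_h)
  fc <- condition_fold_change(pr_tab, phases)
  max_row <- pr_cons %>%
    filter(.data$condition == "C_limited") %>%
    slice(which.max(.data$mean_copies))

  # --- spectrum-level quantification chain -----------------------------
  if (is.null(quant_metadata)) {
    quant_metadata <- scenario_metadata(scenario) %>%
      filter(.data$condition == "C_limited", .data$light == "light",
             .data$replicate == 1,
             .data$timepoint_h %in% range(scenario$timepoints_h))
  }
  msg("quantify", "spectrum-level diDO-IPTL quantification of %d runs",
      nrow(quant_metadata))
  scheme <- label_scheme()
  sim <- simulate_iptl_runs(scenario, quant_metadata, seed)
  mgf_path <- file.path(outdir, "spectra.mgf")
  write_mgf(sim$spectra, mgf_path)
  spectra <- read_mgf(mgf_path)
  # peak lists round-trip through the file; reuse them with metadata intact
  psms <- purrr::map_dfr(unique(quant_metadata$fraction), function(fr) {
    cand <- build_candidates(scenario$proteome, fraction_enzymes(fr))
    match_spectra(spectra %>% filter(.data$fraction == fr), cand, scheme)
  }) %>%
    compute_qvalues()
  wr(psms %>% select(-dplyr::any_of("peaks")), "psms.csv")
  ratios <- quantify_spectra(spectra, filter_psms(psms), scheme)
  wr(ratios, "spectrum_ratios.csv")
  prot <- aggregate_proteins(ratios)
  wr(prot, "protein_sample.csv")
  fsum <- fraction_summary(prot)
  wr(fsum, "fraction_summary.csv")

  # --- expression tables + differential expression ---------------------
  msg("diffexpr", "expression tables and moderated differential expression")
  expr <- simulate_expression(scenario, seed) %>%
    group_by(.data$condition, .data$light, .data$replicate,
             .data$timepoint_h) %>%
    mutate(log2_ratio = normalize_sample(.data$log2_ratio)) %>%
    ungroup()
  wr(expr, "expression_replicates.csv")
  cons <- consolidate_expression(expr)
  wr(cons, "expression_consolidated.csv")
  wide <- cons %>%
    mutate(sample = sprintf("%s_%s_t%s", .data$condition, .data$light,
                            .data$timepoint_h)) %>%
    select("protein_id", "sample", "mean_log2") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "mean_log2")
  wr(wide, "expression_matrix.csv")
  fits <- purrr::map(default_contrasts(), function(ctr) {
    ebayes_moderate(fit_contrast(expr, ctr))
  })
  for (nm in names(fits)) {
    wr(tidy(fits[[nm]]), sprintf("diffexpr_%s.csv", nm))
  }
  sig_counts <- purrr::map_int(fits, ~ sum(.x$table$significant))
  report_ld <- phase_report(fits[grep("^light_vs_dark", names(fits))])
  wr(report_ld, "phase_report_light_vs_dark.csv")
  report_cn <- phase_report(fits[grep("^C_vs_N", names(fits))])
  wr(report_cn, "phase_report_C_vs_N.csv")

  # --- summary ----------------------------------------------------------
  summary <- list(
    seed = as.integer(seed),
    growth = as.list(setNames(
      purrr::map(seq_len(nrow(gcond)),
                 ~ list(mu_max = gcond$mu_max[.x], od_max = gcond$od_max[.x])),
      gcond$condition)),
    fraction_summary = as.list(fsum),
    pr = list(
      stationary_fold_change_C_over_N = fc$fold_change,
      fold_change_se = fc$se,
      max_copies_per_cell = max_row$mean_copies,
      max_copies_timepoint_h = max_row$timepoint_h
    ),
    significant_proteins = as.list(sig_counts)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  msg("done", "outputs in %s", outdir)
  invisible(summary)
}
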