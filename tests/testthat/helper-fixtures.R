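# Shared fixtures: small scenarios and a compact spectrum-level
# quantification chain used by several test files.

zero_noise <- list(spectrum_sd = 0, area_sd = 0, od_sd = 0, ct_sd = 0,
                   calib_sd = 0)

tiny_scenario <- function(seed = 11, n_proteins = 6, noise = list()) {
  scenario_caim519(n_proteins = n_proteins, seed = seed, noise = noise)
}

# simulate -> match -> q-filter -> quantify -> aggregate for a metadata
# subset; returns all intermediates plus the per-spectrum truth
run_quant_chain <- function(scenario, metadata, seed = scenario$seed,
                            q_max = 0.001) {
  scheme <- label_scheme()
  sim <- simulate_iptl_runs(scenario, metadata, seed)
  psms <- dplyr::bind_rows(lapply(unique(metadata$fraction), function(fr) {
    enz <- if (fr == "membrane") c("chymotrypsin", "trypsin") else "trypsin"
    cand <- build_candidates(scenario$proteome, enz)
    match_spectra(dplyr::filter(sim$spectra, fraction == fr), cand, scheme)
  }))
  psms <- compute_qvalues(psms)
  ratios <- quantify_spectra(sim$spectra, filter_psms(psms, q_max), scheme)
  list(sim = sim, psms = psms, ratios = ratios,
       proteins = aggregate_proteins(ratios))
}

# one C-limited light replicate-1 sample row per requested fraction/timepoint
quant_metadata <- function(scenario, timepoints = scenario$timepoints_h[1],
                           fractions = c("membrane", "cytosolic")) {
  md <- scenario_metadata(scenario, fractions)
  dplyr::filter(md, condition == "C_limited", light == "light",
                replicate == 1, timepoint_h %in% timepoints)
}

# build a synthetic two-channel spectrum for a peptide from given
# per-fragment channel intensities
make_pair_spectrum <- function(peptide, int_a, int_b,
                               scheme = label_scheme()) {
  fa <- theoretical_fragments(peptide, scheme, "A")
  fb <- theoretical_fragments(peptide, scheme, "B")
  n <- nrow(fa)
  tibble::tibble(
    mz = c(fa$mz, fb$mz),
    intensity = c(rep_len(int_a, n), rep_len(int_b, n))
  )
}
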