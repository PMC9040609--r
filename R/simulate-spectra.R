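# Two-channel diDO-IPTL MS2 spectrum simulation.

fraction_enzymes <- function(fraction) {
  switch(fraction,
    membrane = c("chymotrypsin", "trypsin"),  # sequential double digestion
    cytosolic = "trypsin",
    abort(sprintf("unknown fraction \"%s\"", fraction))
  )
}

#' Simulate one labeled LC-MS2 run
#'
#' Generates centroided MS2 spectra for one LC-MS sample (one condition x
#' light x replicate x timepoint x fraction): the proteome is digested with
#' the fraction's enzymes (chymotrypsin + trypsin for membrane, trypsin
#' only for cytosolic), each peptide receives `1 + Poisson(mean_extra)`
#' spectra, and each spectrum holds the full b-/y-ion series of *both*
#' label channels. Per fragment pair, a common lognormal base intensity is
#' split between the channels so that the sample/standard intensity ratio
#' equals `2^true_log2` up to per-channel lognormal noise
#' (`scenario$noise$spectrum_sd`, natural-log scale). Which channel is the
#' biological sample follows the scheme orientation for the fraction. A
#' configurable fraction of pure-noise spectra (decoy fodder with uniform
#' random peaks) is appended.
#'
#' @param scenario An `iptl_scenario`.
#' @param sample One row of [scenario_metadata()] (or any list with
#'   `sample_id`, `condition`, `light`, `replicate`, `timepoint_h`,
#'   `phase`, `fraction`).
#' @param seed Integer seed.
#' @param scheme Label scheme (default [label_scheme()]).
#' @return List with `spectra` (tibble: `spectrum_id`, `sample_id`,
#'   `fraction`, `precursor_mz`, `charge`, `peaks`) and `truth` (tibble:
#'   `spectrum_id`, `peptide`, `protein_id`, `true_log2`; noise spectra
#'   have `NA` peptide/protein and `NA` truth).
#' @export
simulate_iptl_run <- function(scenario, sample, seed = scenario$seed,
                              scheme = label_scheme()) {
  fraction <- sample$fraction
  peptides <- digest_proteome(scenario$proteome, fraction_enzymes(fraction))
  if (nrow(peptides) == 0) abort("no peptides: digest of proteome is empty")
  truth_tab <- scenario$true_log2 %>%
    filter(.data$condition == sample$condition,
           .data$light == sample$light,
           .data$phase == sample$phase)
  peptides <- peptides %>%
    inner_join(truth_tab %>% select("protein_id", "true_log2"),
               by = "protein_id")
  smp_channel <- sample_channel(scheme, fraction)
  sp <- scenario$spectra
  with_seed(derive_seed(seed, paste("iptl", sample$sample_id)), {
    n_spec <- 1L + rpois(nrow(peptides), sp$mean_extra_spectra)
    rows <- peptides[rep(seq_len(nrow(peptides)), n_spec), ]
    specs <- purrr::pmap(rows, function(protein_id, peptide, true_log2) {
      fragA <- theoretical_fragments(peptide, scheme, "A")
      fragB <- theoretical_fragments(peptide, scheme, "B")
      nf <- nrow(fragA)
      base <- rlnorm(nf, sp$base_intensity_meanlog, sp$base_intensity_sdlog)
      noiseA <- rlnorm(nf, 0, scenario$noise$spectrum_sd)
      noiseB <- rlnorm(nf, 0, scenario$noise$spectrum_sd)
      ratio <- 2^true_log2
      if (smp_channel == "A") {
        intA <- base * ratio * noiseA; intB <- base * noiseB
      } else {
        intA <- base * noiseA; intB <- base * ratio * noiseB
      }
      pk <- tibble(mz = c(fragA$mz, fragB$mz), intensity = c(intA, intB)) %>%
        arrange(.data$mz)
      list(peaks = pk,
           precursor_mz = peptide_mz(peptide, scheme, smp_channel, 2L))
    })
    n_noise <- round(sp$noise_spectra_frac * nrow(rows))
    noise_specs <- purrr::map(seq_len(n_noise), function(i) {
      npk <- 40L
      list(peaks = tibble(mz = sort(runif(npk, 150, 1500)),
                          intensity = rlnorm(npk, sp$base_intensity_meanlog,
                                             sp$base_intensity_sdlog)),
           precursor_mz = runif(1, 400, 900))
    })
    all_specs <- c(specs, noise_specs)
    ids <- sprintf("%s_scan%04d", sample$sample_id, seq_along(all_specs))
    spectra <- tibble(
      spectrum_id = ids,
      sample_id = sample$sample_id,
      fraction = fraction,
      precursor_mz = purrr::map_dbl(all_specs, "precursor_mz"),
      charge = 2L,
      peaks = purrr::map(all_specs, "peaks")
    )
    truth <- tibble(
      spectrum_id = ids,
      peptide = c(rows$peptide, rep(NA_character_, n_noise)),
      protein_id = c(rows$protein_id, rep(NA_character_, n_noise)),
      true_log2 = c(rows$true_log2, rep(NA_real_, n_noise))
    )
    list(spectra = spectra, truth = truth)
  })
}

#' Simulate labeled runs for a set of samples
#'
#' @param scenario An `iptl_scenario`.
#' @param metadata Tibble of samples ([scenario_metadata()] rows).
#' @param seed Integer seed.
#' @param scheme Label scheme.
#' @return List with row-bound `spectra` and `truth` tibbles.
#' @export
simulate_iptl_runs <- function(scenario, metadata, seed = scenario$seed,
                               scheme = label_scheme()) {
  runs <- purrr::map(seq_len(nrow(metadata)), function(i) {
    simulate_iptl_run(scenario, metadata[i, ], seed, scheme)
  })
  list(
    spectra = purrr::map_dfr(runs, "spectra"),
    truth = purrr::map_dfr(runs, "truth")
  )
}
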