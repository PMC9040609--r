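# Fragment-pair channel ratio quantification and protein-level aggregation.

#' Quantify one spectrum's sample/standard ratio
#'
#' For every fragment (b or y series, index) whose theoretical m/z is
#' observed within `tol_mz` in *both* label channels, the pair ratio is
#' the sample-channel intensity over the standard-channel intensity (the
#' channel carrying the sample is resolved from the scheme orientation for
#' the spectrum's fraction). The spectrum log2 ratio is the median of the
#' per-pair log2 ratios, which is robust against interference on a single
#' fragment; set `method = "sum"` to instead ratio the summed channel
#' intensities.
#'
#' @param peaks Tibble `mz`, `intensity` for one spectrum.
#' @param peptide Matched peptide sequence.
#' @param fraction `"membrane"` or `"cytosolic"`.
#' @param scheme Label scheme.
#' @param tol_mz Matching tolerance in Da (default 0.01).
#' @param method `"median"` (default) or `"sum"`.
#' @return One-row tibble `log2_ratio`, `n_fragment_pairs`, or `NULL` when
#'   no fragment pair is observed (spectrum dropped).
#' @export
quantify_spectrum <- function(peaks, peptide, fraction,
                              scheme = label_scheme(), tol_mz = 0.01,
                              method = c("median", "sum")) {
  method <- match.arg(method)
  fragA <- theoretical_fragments(peptide, scheme, "A")
  fragB <- theoretical_fragments(peptide, scheme, "B")
  obs <- peaks[order(peaks$mz), ]
  grab <- function(theo) {
    idx <- findInterval(theo, obs$mz)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, nrow(obs))
    pick <- ifelse(abs(theo - obs$mz[lo]) <= abs(theo - obs$mz[hi]), lo, hi)
    ok <- abs(theo - obs$mz[pick]) <= tol_mz
    ifelse(ok, obs$intensity[pick], NA_real_)
  }
  intA <- grab(fragA$mz)
  intB <- grab(fragB$mz)
  paired <- !is.na(intA) & !is.na(intB)
  if (!any(paired)) return(NULL)
  smp <- sample_channel(scheme, fraction)
  i_sample <- if (smp == "A") intA[paired] else intB[paired]
  i_standard <- if (smp == "A") intB[paired] else intA[paired]
  log2_ratio <- switch(method,
    median = median(log2(i_sample / i_standard)),
    sum = log2(sum(i_sample) / sum(i_standard))
  )
  tibble(log2_ratio = log2_ratio, n_fragment_pairs = sum(paired))
}

#' Quantify all FDR-passing spectra
#'
#' Joins filtered PSMs to their spectra and computes per-spectrum
#' sample/standard log2 ratios. Spectra with zero observed fragment pairs
#' are dropped (their ids are recorded in the `dropped` attribute).
#'
#' @param spectra Spectrum tibble.
#' @param psms Filtered target PSMs ([filter_psms()]).
#' @inheritParams quantify_spectrum
#' @return SpectrumRatio tibble: `spectrum_id`, `peptide`, `protein_id`,
#'   `fraction`, `sample_id`, `log2_ratio`, `n_fragment_pairs`.
#' @export
quantify_spectra <- function(spectra, psms, scheme = label_scheme(),
                             tol_mz = 0.01, method = "median") {
  tab <- psms %>%
    select("spectrum_id", "peptide", "protein_id") %>%
    inner_join(spectra %>% select("spectrum_id", "sample_id", "fraction",
                                  "peaks"),
               by = "spectrum_id")
  quant <- purrr::pmap(tab %>% select("peaks", "peptide", "fraction"),
                       function(peaks, peptide, fraction) {
    quantify_spectrum(peaks, peptide, fraction, scheme, tol_mz, method)
  })
  keep <- !vapply(quant, is.null, logical(1))
  out <- bind_cols(
    tab[keep, c("spectrum_id", "peptide", "protein_id", "fraction",
                "sample_id")],
    bind_rows(quant[keep])
  )
  attr(out, "dropped") <- tab$spectrum_id[!keep]
  out
}

#' Aggregate spectrum ratios to a protein x sample value
#'
#' Within each protein x sample x fraction group, peptides represented by
#' fewer than two quantified spectra are discarded first (the >= 2 IPTL
#' spectra evidence rule); the protein log2 abundance is the mean of the
#' surviving spectrum log2 ratios, with SE = sd/sqrt(n) and the spectrum
#' count reported. Groups with no surviving spectra are absent from the
#' output (not zero).
#'
#' @param spectrum_ratios Output of [quantify_spectra()].
#' @param min_spectra_per_peptide Evidence threshold (default 2).
#' @return Tibble `protein_id`, `sample_id`, `fraction`, `log2_abundance`,
#'   `se`, `n_spectra`.
#' @export
aggregate_proteins <- function(spectrum_ratios, min_spectra_per_peptide = 2) {
  spectrum_ratios %>%
    group_by(.data$protein_id, .data$sample_id, .data$fraction,
             .data$peptide) %>%
    filter(n() >= min_spectra_per_peptide) %>%
    group_by(.data$protein_id, .data$sample_id, .data$fraction) %>%
    summarise(
      log2_abundance = mean(.data$log2_ratio),
      se = if (n() > 1) sd(.data$log2_ratio) / sqrt(n()) else 0,
      n_spectra = n(),
      .groups = "drop"
    )
}
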