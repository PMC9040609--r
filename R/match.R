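# Spectrum-to-peptide matching and target-decoy q-value control.

#' Build a target + decoy candidate set from a proteome
#'
#' Targets are the fraction-appropriate digest of the proteome; decoys are
#' the digest of the full-sequence-reversed proteins. Decoy peptides that
#' collide with a target sequence are removed.
#'
#' @param proteome Tibble `protein_id`, `sequence`.
#' @param enzymes Enzymes for [digest_proteome()] (use
#'   `c("chymotrypsin","trypsin")` for membrane-fraction data).
#' @param ... Passed to [digest_proteome()].
#' @return Tibble `peptide`, `protein_id`, `is_decoy`; decoy protein ids
#'   carry a `DECOY_` prefix.
#' @export
build_candidates <- function(proteome, enzymes = "trypsin", ...) {
  targets <- digest_proteome(proteome, enzymes, ...) %>%
    mutate(is_decoy = FALSE)
  reversed <- proteome %>%
    mutate(
      protein_id = paste0("DECOY_", .data$protein_id),
      sequence = vapply(strsplit(.data$sequence, "", fixed = TRUE),
                        function(x) paste(rev(x), collapse = ""), character(1))
    )
  decoys <- digest_proteome(reversed, enzymes, ...) %>%
    mutate(is_decoy = TRUE) %>%
    filter(!.data$peptide %in% targets$peptide)
  bind_rows(targets, decoys) %>%
    select("peptide", "protein_id", "is_decoy")
}

# Sorted vector of all theoretical fragment m/z of both channels.
candidate_fragment_mz <- function(peptide, scheme) {
  sort(c(theoretical_fragments(peptide, scheme, "A")$mz,
         theoretical_fragments(peptide, scheme, "B")$mz))
}

# number of theoretical m/z matched by at least one observed peak within tol
count_matches <- function(theo, obs_sorted, tol) {
  if (tol <= 0) {
    return(sum(theo %in% obs_sorted))
  }
  idx <- findInterval(theo, obs_sorted)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(obs_sorted))
  d <- pmin(abs(theo - obs_sorted[lo]), abs(theo - obs_sorted[hi]))
  sum(d <= tol)
}

#' Match one spectrum against a candidate set
#'
#' Score of a candidate = number of its theoretical b/y fragment m/z values
#' (either label channel) matched by an observed peak within `tol_mz`. The
#' best-scoring candidate wins; ties are broken lexicographically by
#' peptide sequence, then target before decoy.
#'
#' @param peaks Tibble `mz`, `intensity` (one spectrum).
#' @param candidates Tibble from [build_candidates()].
#' @param scheme Label scheme.
#' @param tol_mz Fragment matching tolerance in Da (> 0 matches within the
#'   window; 0 demands exact coincidence). Default 0.01.
#' @param fragments Optional precomputed list of fragment m/z vectors
#'   indexed by peptide (internal fast path).
#' @return One-row tibble `peptide`, `protein_id`, `is_decoy`, `score`.
#' @export
match_spectrum <- function(peaks, candidates, scheme = label_scheme(),
                           tol_mz = 0.01, fragments = NULL) {
  check_that(nrow(candidates) > 0, "candidate list is empty")
  check_number(tol_mz, "tol_mz", lower = 0)
  obs <- sort(peaks$mz)
  if (is.null(fragments)) {
    fragments <- lapply(stats::setNames(nm = unique(candidates$peptide)),
                        candidate_fragment_mz, scheme = scheme)
  }
  score <- unname(vapply(candidates$peptide, function(p) {
    count_matches(fragments[[p]], obs, tol_mz)
  }, numeric(1)))
  ord <- order(-score, candidates$peptide, candidates$is_decoy)
  best <- ord[1]
  tibble(
    peptide = candidates$peptide[best],
    protein_id = candidates$protein_id[best],
    is_decoy = candidates$is_decoy[best],
    score = score[best]
  )
}

#' Match a table of spectra
#'
#' Vectorised wrapper around [match_spectrum()]; fragment m/z values are
#' computed once per candidate peptide.
#'
#' @param spectra Spectrum tibble (e.g. [simulate_iptl_run()] output or
#'   [read_mgf()]).
#' @inheritParams match_spectrum
#' @return PSM tibble: `spectrum_id`, `sample_id`, `fraction`, `peptide`,
#'   `protein_id`, `is_decoy`, `score`.
#' @export
match_spectra <- function(spectra, candidates, scheme = label_scheme(),
                          tol_mz = 0.01) {
  check_that(nrow(candidates) > 0, "candidate list is empty")
  check_that(!anyDuplicated(candidates$peptide),
             "candidate peptides must be unique")
  frag_list <- lapply(candidates$peptide, candidate_fragment_mz,
                      scheme = scheme)
  theo <- unlist(frag_list)
  cand_idx <- rep(seq_len(nrow(candidates)),
                  vapply(frag_list, length, integer(1)))
  # deterministic tie-break rank: score desc, peptide lexicographic,
  # target before decoy
  tie_rank <- order(order(candidates$peptide, candidates$is_decoy))
  hits <- purrr::map_dfr(spectra$peaks, function(pk) {
    obs <- sort(pk$mz)
    if (tol_mz <= 0) {
      matched <- theo %in% obs
    } else {
      idx <- findInterval(theo, obs)
      lo <- pmax(idx, 1L)
      hi <- pmin(idx + 1L, length(obs))
      d <- pmin(abs(theo - obs[lo]), abs(theo - obs[hi]))
      matched <- d <= tol_mz
    }
    score <- tabulate(cand_idx[matched], nbins = nrow(candidates))
    best <- order(-score, tie_rank)[1]
    tibble(
      peptide = candidates$peptide[best],
      protein_id = candidates$protein_id[best],
      is_decoy = candidates$is_decoy[best],
      score = score[best]
    )
  })
  bind_cols(spectra %>% select("spectrum_id", "sample_id", "fraction"), hits)
}

#' Target-decoy q-values for peptide-spectrum matches
#'
#' At each score threshold `s`, the estimated FDR is
#' `#decoys >= s / #targets >= s` (0 when no targets survive); the q-value
#' of a PSM with score `s` is the minimum estimated FDR over all
#' thresholds `<= s` (monotonisation), so q is non-increasing in score.
#'
#' @param psms PSM tibble with `score` and `is_decoy` columns.
#' @return `psms` with a `q_value` column appended (decoy rows get the
#'   q-value their score would earn a target). With no decoys present a
#'   warning is raised and all q-values are 0.
#' @export
compute_qvalues <- function(psms) {
  check_that(all(c("score", "is_decoy") %in% names(psms)),
             "psms must have score and is_decoy columns")
  if (!any(psms$is_decoy)) {
    warn("no decoy PSMs present; q-values set to 0")
    return(psms %>% mutate(q_value = 0))
  }
  thresholds <- sort(unique(psms$score))
  n_dec <- vapply(thresholds, function(s) sum(psms$is_decoy & psms$score >= s),
                  numeric(1))
  n_tgt <- vapply(thresholds, function(s) sum(!psms$is_decoy & psms$score >= s),
                  numeric(1))
  fdr <- ifelse(n_tgt == 0, 0, n_dec / n_tgt)
  # q(s) = min over thresholds t <= s of FDR(t): running min in ascending s
  q_asc <- cummin(fdr)
  psms %>%
    mutate(q_value = q_asc[findInterval(.data$score, thresholds)])
}

#' Filter PSMs at a spectrum-level q-value threshold
#'
#' Retains target PSMs with `q_value < q_max` (default 0.001, i.e. the
#' < 0.1% spectrum-level FDR operating point).
#'
#' @param psms Output of [compute_qvalues()].
#' @param q_max Strict upper bound on q (default 0.001).
#' @return Filtered tibble.
#' @export
filter_psms <- function(psms, q_max = 0.001) {
  check_number(q_max, "q_max", lower = 1e-12, upper = 1)
  psms %>% filter(!.data$is_decoy, .data$q_value < q_max)
}
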