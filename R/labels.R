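# diDO-IPTL label chemistry and fragment-ion arithmetic.
#
# The two channels of a diDO-IPTL experiment are near-isobaric at the
# precursor level but resolved in the fragment series: one channel carries a
# deuterated dimethyl group on the peptide N terminus (d4-dimethylation, via
# CD2O reductive methylation), the other carries two 18O atoms on the C
# terminus (enzyme-catalysed carboxyl oxygen exchange). b ions therefore
# separate the channels by the N-terminal mass gap and y ions by the
# C-terminal gap, with opposite channel assignment.

# Monoisotopic atomic masses (CODATA/NIST), Da.
IPTL_ATOMIC <- c(
  H   = 1.00782503207,
  D   = 2.01410177785,
  C   = 12.0,
  N   = 14.0030740048,
  O   = 15.99491461956,
  O18 = 17.99915961286,
  proton = 1.00727646688
)

# Monoisotopic residue masses, Da.
AA_MONO <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047678, W = 186.079313, Y = 163.063329, V = 99.068414
)

MASS_H2O <- 2 * IPTL_ATOMIC[["H"]] + IPTL_ATOMIC[["O"]]

#' Terminal label mass deltas for diDO-IPTL
#'
#' Computes the N- and C-terminal mass additions of the two diDO-IPTL label
#' states from first principles: light dimethylation adds 2 x CH2; heavy
#' (d4) dimethylation additionally substitutes four deuteriums for
#' hydrogens; heavy C termini carry two 18O-for-16O exchanges (light C
#' termini are unmodified).
#'
#' @param atomic_masses Named numeric vector of monoisotopic atomic masses
#'   (Da) containing at least `H`, `D`, `C`, `O`, `O18`. Defaults to the
#'   built-in CODATA values.
#' @return A named list with elements `n_term` (`light`, `heavy`) and
#'   `c_term` (`light`, `heavy`), all in Da.
#' @examples
#' label_masses()$n_term # light 28.0313, heavy 32.0564
#' @export
label_masses <- function(atomic_masses = IPTL_ATOMIC) {
  need <- c("H", "D", "C", "O", "O18")
  check_that(all(need %in% names(atomic_masses)),
             "atomic_masses must name H, D, C, O and O18")
  m <- atomic_masses
  n_light <- 2 * (m[["C"]] + 2 * m[["H"]])          # 2 x CH2 (dimethyl)
  n_heavy <- n_light + 4 * (m[["D"]] - m[["H"]])    # CHD2 methyls
  c_heavy <- 2 * (m[["O18"]] - m[["O"]])            # double 18O exchange
  list(
    n_term = c(light = n_light, heavy = n_heavy),
    c_term = c(light = 0, heavy = c_heavy)
  )
}

#' diDO-IPTL label scheme
#'
#' Bundles the terminal mass deltas with the per-fraction channel
#' orientation. Channel "A" denotes heavy-N-terminus / light-C-terminus
#' labeling; channel "B" the converse (light-N / heavy-18O-C). Membrane
#' fraction samples are labeled as channel A with the pooled internal
#' standard on channel B; cytosolic fractions are labeled the other way
#' around.
#'
#' @param atomic_masses Passed to [label_masses()].
#' @return An object of class `label_scheme`: list with `deltas`
#'   (from [label_masses()]) and `orientation`, a named list mapping
#'   fraction -> c(sample = channel, standard = channel).
#' @export
label_scheme <- function(atomic_masses = IPTL_ATOMIC) {
  structure(
    list(
      deltas = label_masses(atomic_masses),
      orientation = list(
        membrane  = c(sample = "A", standard = "B"),
        cytosolic = c(sample = "B", standard = "A")
      )
    ),
    class = "label_scheme"
  )
}

# terminal deltas for one channel
channel_deltas <- function(scheme, channel) {
  check_that(channel %in% c("A", "B"), "channel must be \"A\" or \"B\"")
  d <- scheme$deltas
  if (channel == "A") {
    c(n = d$n_term[["heavy"]], c = d$c_term[["light"]])
  } else {
    c(n = d$n_term[["light"]], c = d$c_term[["heavy"]])
  }
}

# which channel carries the biological sample in a given fraction
sample_channel <- function(scheme, fraction) {
  check_that(fraction %in% names(scheme$orientation),
             sprintf("unknown fraction \"%s\"", fraction))
  scheme$orientation[[fraction]][["sample"]]
}

#' Theoretical b/y fragment ions of a labeled peptide
#'
#' Singly charged b- and y-ion m/z values for one diDO-IPTL channel. b ions
#' carry the channel's N-terminal label delta, y ions its C-terminal delta,
#' so for a fixed peptide the two channels differ by a constant
#' +/-4.025107 Da across the b series and a constant -/+4.008490 Da across
#' the y series.
#'
#' @param peptide Amino-acid string (length >= 2, canonical residues).
#' @param scheme A [label_scheme()].
#' @param channel `"A"` (heavy-N/light-C) or `"B"` (light-N/heavy-C).
#' @return Tibble with columns `ion` ("b"/"y"), `index`, `mz`, `charge`.
#' @examples
#' theoretical_fragments("AGK", label_scheme(), "A")
#' @export
theoretical_fragments <- function(peptide, scheme = label_scheme(),
                                  channel = c("A", "B")) {
  channel <- match.arg(channel)
  res <- peptide_residues(peptide)
  n <- length(res)
  check_that(n >= 2, "peptide must have length >= 2")
  d <- channel_deltas(scheme, channel)
  cum <- cumsum(res)
  b <- cum[-n] + d[["n"]] + IPTL_ATOMIC[["proton"]]
  y <- (cum[n] - cum[-n]) + MASS_H2O + d[["c"]] + IPTL_ATOMIC[["proton"]]
  # y computed at position i covers residues (i+1)..n, i.e. ion y_(n-i)
  tibble(
    ion = rep(c("b", "y"), each = n - 1L),
    index = c(seq_len(n - 1L), rev(seq_len(n - 1L))),
    mz = c(b, y),
    charge = 1L
  )
}

# residue mass vector, with validation
peptide_residues <- function(peptide) {
  check_that(is.character(peptide) && length(peptide) == 1L && nzchar(peptide),
             "peptide must be a single non-empty string")
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, names(AA_MONO))
  if (length(bad)) abort(sprintf("non-canonical residue(s): %s",
                                 paste(unique(bad), collapse = ", ")))
  unname(AA_MONO[res])
}

#' Labeled precursor m/z
#'
#' @param peptide Amino-acid string.
#' @param scheme A [label_scheme()].
#' @param channel `"A"` or `"B"`.
#' @param charge Precursor charge (default 2; data-dependent acquisition in
#'   this workflow selects only multiply charged precursors).
#' @return Precursor m/z (Da/e).
#' @export
peptide_mz <- function(peptide, scheme = label_scheme(), channel = c("A", "B"),
                       charge = 2L) {
  channel <- match.arg(channel)
  check_number(charge, "charge", lower = 1)
  d <- channel_deltas(scheme, channel)
  m <- sum(peptide_residues(peptide)) + MASS_H2O + d[["n"]] + d[["c"]]
  (m + charge * IPTL_ATOMIC[["proton"]]) / charge
}
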