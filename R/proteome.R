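# Toy proteome generation and in-silico proteolysis.

# Approximate natural amino-acid frequencies (Swiss-Prot composition);
# K+R frequency ~11% gives tryptic peptides of typical length 6-20.
AA_FREQ <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
  E = 0.0675, Q = 0.0393, G = 0.0708, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0472,
  S = 0.0657, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687
)

# Proteorhodopsin tryptic marker peptides used for absolute quantification.
PR_PEPTIDES <- c("LWETQGVAK", "NLADVVNK")

#' Generate a toy proteome with one proteorhodopsin-like entry
#'
#' Random protein sequences drawn from natural residue frequencies, plus a
#' single proteorhodopsin-like protein that is guaranteed to yield the two
#' tryptic marker peptides LWETQGVAK and NLADVVNK used for absolute
#' quantification. The output is deterministic for a fixed seed.
#'
#' @param n_proteins Number of proteins (>= 2; one of them is the PR entry).
#' @param mean_length Mean protein length in residues.
#' @param seed Integer seed.
#' @return Tibble with columns `protein_id`, `sequence`; the PR entry id is
#'   stored in attribute `pr_id` (always `"PR"`).
#' @examples
#' prot <- make_toy_proteome(10, 200, seed = 1)
#' attr(prot, "pr_id")
#' @export
make_toy_proteome <- function(n_proteins, mean_length = 300, seed = 1) {
  check_number(n_proteins, "n_proteins", lower = 2)
  check_number(mean_length, "mean_length", lower = 30)
  with_seed(seed, {
    rand_seq <- function(len) {
      paste(sample(names(AA_FREQ), len, replace = TRUE, prob = AA_FREQ),
            collapse = "")
    }
    lens <- pmax(30L, rpois(n_proteins - 1L, mean_length))
    seqs <- vapply(lens, rand_seq, character(1))
    # PR-like entry: marker peptides inserted as clean tryptic products
    # (preceded by K/R, followed by a non-proline residue).
    pr_len <- max(30L, rpois(1L, mean_length))
    third <- max(6L, pr_len %/% 3L)
    pr_seq <- paste0(
      rand_seq(third), "R", PR_PEPTIDES[1],       # ...R | LWETQGVAK
      "A", rand_seq(third), "K", PR_PEPTIDES[2],  # ...K | NLADVVNK
      "A", rand_seq(third)
    )
    ids <- c("PR", sprintf("VC%04d", seq_len(n_proteins - 1L)))
    out <- tibble(
      protein_id = ids,
      sequence = c(pr_seq, seqs)
    )
    attr(out, "pr_id") <- "PR"
    out
  })
}

# cleavage positions (after residue i) for one enzyme
cleavage_sites <- function(res, enzyme) {
  targets <- switch(enzyme,
    trypsin = c("K", "R"),
    chymotrypsin = c("F", "W", "Y", "L", "M"),
    abort(sprintf("unknown enzyme \"%s\"", enzyme))
  )
  n <- length(res)
  if (n < 2) return(integer(0))
  idx <- which(res[-n] %in% targets)
  idx[res[idx + 1L] != "P"]   # no cleavage N-terminal to proline
}

#' In-silico proteolytic digestion
#'
#' Cleaves a protein sequence with trypsin (C-terminal to K/R), broad
#' specificity chymotrypsin (C-terminal to F/W/Y/L/M), or both applied
#' sequentially (union of cleavage sites). Cleavage is suppressed before
#' proline. Products shorter than `min_length` residues are discarded, as
#' such peptides are rarely informative in a database search.
#'
#' @param sequence Protein sequence (non-empty string).
#' @param enzymes Character vector, subset of `c("trypsin","chymotrypsin")`.
#' @param missed_cleavages Maximum number of missed cleavages (default 0).
#' @param min_length Minimum peptide length retained (default 5).
#' @return Character vector of peptides, in N-to-C order of their fully
#'   cleaved leading fragment.
#' @examples
#' digest("AAAKAAAR", "trypsin", min_length = 1) # "AAAK" "AAAR"
#' digest("AAAAKPAAAA", "trypsin")               # KP: no cleavage
#' @export
digest <- function(sequence, enzymes = "trypsin", missed_cleavages = 0,
                   min_length = 5) {
  check_that(is.character(sequence) && length(sequence) == 1L && nzchar(sequence),
             "sequence must be a single non-empty string")
  check_that(length(enzymes) >= 1 && all(enzymes %in% c("trypsin", "chymotrypsin")),
             "enzymes must be a subset of {\"trypsin\", \"chymotrypsin\"}")
  check_number(missed_cleavages, "missed_cleavages", lower = 0)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sites <- sort(unique(unlist(lapply(unique(enzymes), cleavage_sites, res = res))))
  bounds <- c(0L, sites, length(res))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  pieces <- substring(sequence, starts, ends)
  out <- pieces
  if (missed_cleavages > 0 && length(pieces) > 1) {
    for (k in seq_len(min(missed_cleavages, length(pieces) - 1L))) {
      i <- seq_len(length(pieces) - k)
      out <- c(out, vapply(i, function(j) {
        paste(pieces[j:(j + k)], collapse = "")
      }, character(1)))
    }
  }
  out[nchar(out) >= min_length]
}

#' Digest every protein of a proteome
#'
#' @param proteome Tibble with `protein_id`, `sequence` columns (e.g. from
#'   [make_toy_proteome()]).
#' @inheritParams digest
#' @param max_length Maximum peptide length retained (default 30; longer
#'   peptides fragment poorly and are excluded from simulation/matching).
#' @return Tibble with `protein_id`, `peptide`. Peptides mapping to more
#'   than one protein are dropped (non-unique evidence).
#' @export
digest_proteome <- function(proteome, enzymes = "trypsin",
                            missed_cleavages = 0, min_length = 5,
                            max_length = 30) {
  check_that(all(c("protein_id", "sequence") %in% names(proteome)),
             "proteome must have protein_id and sequence columns")
  out <- purrr::map2_dfr(proteome$protein_id, proteome$sequence, function(id, sq) {
    pep <- unique(digest(sq, enzymes, missed_cleavages, min_length))
    tibble(protein_id = id, peptide = pep[nchar(pep) <= max_length])
  })
  shared <- out %>% count(.data$peptide) %>% filter(n > 1) %>% pull(.data$peptide)
  out %>% filter(!.data$peptide %in% shared)
}

#' Write / read a proteome as FASTA
#'
#' Plain-text FASTA IO for the toy proteome. Uses Biostrings when available
#' for robust parsing; falls back to a minimal reader otherwise.
#'
#' @param proteome Tibble with `protein_id`, `sequence`.
#' @param path File path.
#' @return `write_proteome_fasta()` returns `path` invisibly;
#'   `read_proteome_fasta()` returns the proteome tibble (attribute `pr_id`
#'   set to `"PR"` when such an entry is present).
#' @export
write_proteome_fasta <- function(proteome, path) {
  lines <- as.vector(rbind(paste0(">", proteome$protein_id), proteome$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_proteome_fasta
#' @export
read_proteome_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    out <- tibble(protein_id = names(aa), sequence = unname(as.character(aa)))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    ids <- sub("^>", "", lines[hdr])
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
    out <- tibble(protein_id = ids, sequence = unname(seqs))
  }
  if ("PR" %in% out$protein_id) attr(out, "pr_id") <- "PR"
  out
}
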