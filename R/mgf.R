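# Minimal Mascot Generic Format (MGF) IO for centroided MS2 spectra.
#
# Spectra are represented as a tibble with one row per spectrum:
# spectrum_id, sample_id, fraction, precursor_mz, charge, and a `peaks`
# list-column of tibbles (mz, intensity). The TITLE line carries the
# sample and fraction ids so a file round-trips losslessly.

#' Write spectra to an MGF file
#'
#' @param spectra Spectrum tibble (see [simulate_iptl_run()]): columns
#'   `spectrum_id`, `sample_id`, `fraction`, `precursor_mz`, `charge`,
#'   `peaks` (list of tibbles with `mz`, `intensity`).
#' @param path Output file path.
#' @return `path`, invisibly. Output is byte-deterministic for identical
#'   input.
#' @export
write_mgf <- function(spectra, path) {
  need <- c("spectrum_id", "sample_id", "fraction", "precursor_mz",
            "charge", "peaks")
  check_that(all(need %in% names(spectra)), "spectra tibble is missing columns")
  blocks <- purrr::pmap(spectra[need], function(spectrum_id, sample_id,
                                                fraction, precursor_mz,
                                                charge, peaks) {
    c("BEGIN IONS",
      sprintf("TITLE=id=%s|sample=%s|fraction=%s", spectrum_id, sample_id,
              fraction),
      sprintf("PEPMASS=%.6f", precursor_mz),
      sprintf("CHARGE=%d+", charge),
      sprintf("%.6f %.4f", peaks$mz, peaks$intensity),
      "END IONS", "")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Read an MGF file
#'
#' @param path MGF file path (as written by [write_mgf()]; TITLE fields
#'   `id=`, `sample=`, `fraction=` are parsed back when present).
#' @return Spectrum tibble in the same layout [write_mgf()] consumes.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  check_that(length(begin) == length(end) && all(end > begin),
             "malformed MGF: unbalanced BEGIN/END IONS")
  purrr::map2_dfr(begin, end, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    is_hdr <- grepl("^[A-Z]+=", block)
    hdr <- block[is_hdr]
    get <- function(key) {
      v <- hdr[startsWith(hdr, paste0(key, "="))]
      if (!length(v)) NA_character_ else sub(paste0("^", key, "="), "", v[1])
    }
    title <- get("TITLE")
    fields <- c(id = NA_character_, sample = NA_character_,
                fraction = NA_character_)
    if (!is.na(title)) {
      for (part in strsplit(title, "|", fixed = TRUE)[[1]]) {
        kv <- strsplit(part, "=", fixed = TRUE)[[1]]
        if (length(kv) == 2 && kv[1] %in% names(fields)) fields[kv[1]] <- kv[2]
      }
    }
    pk <- block[!is_hdr]
    mat <- do.call(rbind, lapply(strsplit(pk, "[ \t]+"),
                                 function(x) as.numeric(x[1:2])))
    tibble(
      spectrum_id = if (is.na(fields[["id"]])) title else fields[["id"]],
      sample_id = fields[["sample"]],
      fraction = fields[["fraction"]],
      precursor_mz = as.numeric(get("PEPMASS")),
      charge = as.integer(sub("\\+$", "", get("CHARGE"))),
      peaks = list(tibble(mz = mat[, 1], intensity = mat[, 2]))
    )
  })
}
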