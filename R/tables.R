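# Expression-table construction: per-sample median normalization,
# replicate consolidation, fraction assignment, growth-phase annotation.

#' Median-zero normalization of one sample's log2 ratios
#'
#' Subtracts the median so that the set of all log2 protein abundance
#' ratios of an LC-MS sample has median exactly zero, putting abundances
#' on a per-amount-total-protein basis. Idempotent.
#'
#' @param x Numeric vector of log2 ratios (non-empty).
#' @return `x - median(x)`.
#' @examples
#' normalize_sample(c(1, 2, 4)) # -1 0 2
#' @export
normalize_sample <- function(x) {
  check_that(is.numeric(x) && length(x) >= 1, "need at least one ratio")
  x - median(x)
}

#' Median-zero normalization per LC-MS sample
#'
#' Applies [normalize_sample()] within each sample of a protein x sample
#' table. A sample here is one LC-MS analysis: fraction x condition x
#' light x replicate x timepoint.
#'
#' @param protein_table Tibble with at least `sample_id` and the value
#'   column.
#' @param value Name of the value column (default `"log2_abundance"`).
#' @return Same tibble with the value column normalized per sample.
#' @export
normalize_samples <- function(protein_table, value = "log2_abundance") {
  check_that(value %in% names(protein_table), "value column not found")
  protein_table %>%
    group_by(.data$sample_id) %>%
    mutate(across(all_of(value), normalize_sample)) %>%
    ungroup()
}

#' Consolidate biological replicates
#'
#' Mean log2 abundance across replicates with combined error
#' `sqrt(sigma_x^2 + mu_SE^2)`, where `sigma_x` is the between-replicate
#' sample standard deviation (n - 1 denominator) of the normalized log2
#' values and `mu_SE` is the mean of the per-replicate standard errors.
#' With a single replicate the value passes through with its own SE and a
#' low-confidence flag.
#'
#' @param log2_values Numeric vector of per-replicate log2 abundances.
#' @param se_values Numeric vector of per-replicate standard errors.
#' @return One-row tibble `mean_log2`, `error`, `sigma_x`, `mu_se`,
#'   `n_replicates`, `low_confidence`.
#' @examples
#' consolidate_replicates(c(0, 2), c(0, 0)) # error = sqrt(2)
#' @export
consolidate_replicates <- function(log2_values, se_values) {
  check_that(length(log2_values) == length(se_values) && length(log2_values) >= 1,
             "log2 and SE vectors must have equal positive length")
  ok <- is.finite(log2_values) & is.finite(se_values)
  log2_values <- log2_values[ok]; se_values <- se_values[ok]
  check_that(length(log2_values) >= 1, "no finite replicate values")
  n <- length(log2_values)
  if (n == 1) {
    return(tibble(mean_log2 = log2_values, error = se_values,
                  sigma_x = NA_real_, mu_se = se_values,
                  n_replicates = 1L, low_confidence = TRUE))
  }
  sigma_x <- sd(log2_values)
  mu_se <- mean(se_values)
  tibble(
    mean_log2 = mean(log2_values),
    error = sqrt(sigma_x^2 + mu_se^2),
    sigma_x = sigma_x,
    mu_se = mu_se,
    n_replicates = as.integer(n),
    low_confidence = FALSE
  )
}

#' Assign each protein to a single peptide fraction
#'
#' Proteins quantified in only one of the membrane / cytosolic fractions
#' keep that fraction; proteins quantified in both are assigned to the
#' fraction with the greater total number of quantified spectra, with ties
#' going to the cytosolic fraction.
#'
#' @param protein_table Tibble with `protein_id`, `fraction`, `n_spectra`
#'   (one row per protein x sample x fraction, e.g.
#'   [aggregate_proteins()] output).
#' @return Tibble `protein_id`, `fraction_assigned`, `n_membrane`,
#'   `n_cytosolic`.
#' @export
assign_fraction <- function(protein_table) {
  wide <- protein_table %>%
    group_by(.data$protein_id, .data$fraction) %>%
    summarise(n_spectra = sum(.data$n_spectra), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "fraction", values_from = "n_spectra",
                       values_fill = 0)
  if (!"membrane" %in% names(wide)) wide$membrane <- 0
  if (!"cytosolic" %in% names(wide)) wide$cytosolic <- 0
  wide %>%
    mutate(
      n_membrane = .data$membrane,
      n_cytosolic = .data$cytosolic,
      fraction_assigned = if_else(.data$n_membrane > .data$n_cytosolic,
                                  "membrane", "cytosolic")
    ) %>%
    select("protein_id", "fraction_assigned", "n_membrane", "n_cytosolic")
}

#' Growth-phase designation of proteomic timepoints
#'
#' For the canonical 9-timepoint design the first 3 timepoints are
#' exponential phase, the next 4 transition phase and the final 2
#' stationary phase. Other counts are split proportionally (3:4:2),
#' keeping at least one timepoint per phase and labels non-decreasing in
#' time.
#'
#' @param timepoints Sorted numeric vector of >= 3 timepoints.
#' @return Tibble `timepoint_h`, `phase` (character:
#'   exponential/transition/stationary).
#' @examples
#' assign_phase(c(7.5, 9, 10.5, 12, 13.5, 15, 27.5, 51.5, 75.5))
#' @export
assign_phase <- function(timepoints) {
  n <- length(timepoints)
  check_that(n >= 3, "need at least 3 timepoints to designate phases")
  check_that(!is.unsorted(timepoints, strictly = TRUE),
             "timepoints must be strictly increasing")
  if (n == 9) {
    sizes <- c(3L, 4L, 2L)
  } else {
    n_exp <- max(1L, round(n * 3 / 9))
    n_stat <- max(1L, round(n * 2 / 9))
    sizes <- c(n_exp, n - n_exp - n_stat, n_stat)
    check_that(all(sizes >= 1), "too few timepoints for a 3-phase split")
  }
  tibble(
    timepoint_h = timepoints,
    phase = rep(c("exponential", "transition", "stationary"), times = sizes)
  )
}

#' Fraction bookkeeping summary
#'
#' Counts proteins quantified only in the membrane fraction, only in the
#' cytosolic fraction, and in both, together with the single-fraction
#' assignment of the "both" group. The partition identity
#' `membrane_only + cytosolic_only + both = total` always holds, and the
#' assigned counts partition `both`.
#'
#' @param protein_table Tibble with `protein_id`, `fraction`, `n_spectra`.
#' @return One-row tibble `membrane_only`, `cytosolic_only`, `both`,
#'   `total`, `assigned_membrane`, `assigned_cytosolic`.
#' @export
fraction_summary <- function(protein_table) {
  if (nrow(protein_table) == 0) {
    return(tibble(membrane_only = 0L, cytosolic_only = 0L, both = 0L,
                  total = 0L, assigned_membrane = 0L, assigned_cytosolic = 0L))
  }
  pres <- protein_table %>%
    distinct(.data$protein_id, .data$fraction) %>%
    group_by(.data$protein_id) %>%
    summarise(
      in_membrane = "membrane" %in% .data$fraction,
      in_cytosolic = "cytosolic" %in% .data$fraction,
      .groups = "drop"
    )
  assigned <- assign_fraction(protein_table)
  both_ids <- pres$protein_id[pres$in_membrane & pres$in_cytosolic]
  tibble(
    membrane_only = sum(pres$in_membrane & !pres$in_cytosolic),
    cytosolic_only = sum(pres$in_cytosolic & !pres$in_membrane),
    both = length(both_ids),
    total = nrow(pres),
    assigned_membrane = sum(assigned$fraction_assigned == "membrane" &
                              assigned$protein_id %in% both_ids),
    assigned_cytosolic = sum(assigned$fraction_assigned == "cytosolic" &
                               assigned$protein_id %in% both_ids)
  )
}

#' Replicate-level expression table
#'
#' Full preprocessing up to (but not including) replicate consolidation:
#' per-sample median-zero normalization, single-fraction assignment per
#' protein (dropping the non-assigned fraction's values), and growth-phase
#' annotation. This replicate-level table is the input for differential
#' expression, where per-replicate values keep the variance estimable.
#'
#' @param protein_table [aggregate_proteins()] output.
#' @param metadata [scenario_metadata()]-shaped sample table.
#' @return Tibble `protein_id`, `condition`, `light`, `replicate`,
#'   `timepoint_h`, `phase`, `fraction`, `log2_abundance`, `se`,
#'   `n_spectra`.
#' @export
expression_replicates <- function(protein_table, metadata) {
  normalized <- normalize_samples(protein_table)
  assigned <- assign_fraction(protein_table)
  normalized %>%
    inner_join(assigned %>% select("protein_id", "fraction_assigned"),
               by = "protein_id") %>%
    filter(.data$fraction == .data$fraction_assigned) %>%
    inner_join(metadata %>% select("sample_id", "condition", "light",
                                   "replicate", "timepoint_h", "phase"),
               by = "sample_id") %>%
    select("protein_id", "condition", "light", "replicate", "timepoint_h",
           "phase", "fraction", "log2_abundance", "se", "n_spectra")
}

#' Consolidated expression table
#'
#' Collapses the replicate-level table over biological replicates per
#' protein x condition x light x timepoint using
#' [consolidate_replicates()] (mean log2 with
#' `sqrt(sigma_x^2 + mu_SE^2)` error).
#'
#' @param replicate_table [expression_replicates()] output (or the
#'   [simulate_expression()] layout with `log2_ratio`/`se` columns).
#' @return Tibble `protein_id`, `condition`, `light`, `timepoint_h`,
#'   `phase`, `mean_log2`, `error`, `sigma_x`, `mu_se`, `n_replicates`,
#'   `low_confidence`, `total_spectra`.
#' @export
consolidate_expression <- function(replicate_table) {
  value_col <- if ("log2_abundance" %in% names(replicate_table)) {
    "log2_abundance"
  } else {
    "log2_ratio"
  }
  replicate_table %>%
    group_by(.data$protein_id, .data$condition, .data$light,
             .data$timepoint_h, .data$phase) %>%
    summarise(
      stats = list(consolidate_replicates(.data[[value_col]], .data$se)),
      total_spectra = sum(.data$n_spectra),
      .groups = "drop"
    ) %>%
    tidyr::unnest("stats")
}
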