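# Absolute proteorhodopsin quantification from heavy-standard peptide
# peak areas: area ratio -> pmol -> copies/cell -> condition fold change.

AVOGADRO <- 6.02214076e23

#' Heavy-standard spike description
#'
#' The synthetic 13C6,15N2-lysine PR peptide standards are stocked at
#' 0.5 pmol/uL and 0.75 uL of stock is added to 7.25 uL of unlabeled
#' membrane-fraction sample, i.e. 0.375 pmol of each standard per analyzed
#' mix. The injected share of the mix is applied identically to native and
#' standard species, so it cancels in every ratio.
#'
#' @param stock_pmol_ul Stock concentration (pmol/uL, default 0.5).
#' @param spike_ul Spiked stock volume (uL, default 0.75).
#' @param sample_ul Sample volume the spike is added to (uL, default 7.25).
#' @return List with the three fields plus `spike_pmol`.
#' @export
standard_spike <- function(stock_pmol_ul = 0.5, spike_ul = 0.75,
                           sample_ul = 7.25) {
  check_number(stock_pmol_ul, "stock_pmol_ul", lower = 1e-12)
  check_number(spike_ul, "spike_ul", lower = 1e-12)
  check_number(sample_ul, "sample_ul", lower = 1e-12)
  list(stock_pmol_ul = stock_pmol_ul, spike_ul = spike_ul,
       sample_ul = sample_ul, spike_pmol = stock_pmol_ul * spike_ul)
}

#' Trapezoidal peak-area integration
#'
#' Integrates an extracted-ion chromatogram over the provided window by
#' the trapezoid rule. Additive over any split of the window.
#'
#' @param xic Tibble/data frame with `time`, `intensity` columns, times
#'   strictly increasing, >= 2 points.
#' @return Peak area (intensity x time units).
#' @examples
#' integrate_peak(data.frame(time = 0:2, intensity = c(0, 2, 0))) # 2
#' @export
integrate_peak <- function(xic) {
  check_that(all(c("time", "intensity") %in% names(xic)),
             "xic needs time and intensity columns")
  t <- xic$time; y <- xic$intensity
  check_that(length(t) >= 2, "need at least 2 points")
  check_that(!is.unsorted(t, strictly = TRUE), "times must be strictly increasing")
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Native peptide amount from a native/standard area ratio
#'
#' `native pmol = (native_area / standard_area) * spiked pmol`.
#'
#' @param native_area,standard_area MS1 peak areas (vectors recycle).
#' @param spike A [standard_spike()].
#' @return Native amount(s) in pmol.
#' @examples
#' amount_from_ratio(1, 1) # 0.375 pmol
#' @export
amount_from_ratio <- function(native_area, standard_area,
                              spike = standard_spike()) {
  check_number(native_area, "native_area", lower = 0)
  if (any(standard_area <= 0)) abort("standard not detected (standard_area <= 0)")
  native_area / standard_area * spike$spike_pmol
}

#' Fit an OD to cell-density calibration
#'
#' Ordinary least squares of cells/mL against optical density on paired
#' calibration observations (CFU and volumetric counts).
#'
#' @param calibration Tibble with `od`, `cells_ml` (>= 3 points).
#' @return Object of class `od_calibration`: list with `slope`,
#'   `intercept`, `model` (the `lm` fit).
#' @export
fit_od_calibration <- function(calibration) {
  check_that(all(c("od", "cells_ml") %in% names(calibration)),
             "calibration needs od and cells_ml columns")
  check_that(nrow(calibration) >= 3, "calibration needs >= 3 points")
  fit <- lm(cells_ml ~ od, data = calibration)
  slope <- unname(coef(fit)[["od"]])
  check_that(slope > 0, "calibration slope must be positive")
  structure(list(slope = slope, intercept = unname(coef(fit)[[1]]),
                 model = fit),
            class = "od_calibration")
}

#' @export
print.od_calibration <- function(x, ...) {
  cat(sprintf("<od_calibration> cells/mL = %.4g * OD + %.4g (n = %d)\n",
              x$slope, x$intercept, nrow(x$model$model)))
  invisible(x)
}

#' Cells analyzed from optical density
#'
#' Linear calibration prediction of cell density, scaled by the harvested
#' culture volume.
#'
#' @param od Optical density value(s), >= 0.
#' @param calibration An [fit_od_calibration()] object.
#' @param volume_ml Harvested culture volume (default 4.5 mL).
#' @return Number of cells analyzed.
#' @export
cells_from_od <- function(od, calibration, volume_ml = 4.5) {
  check_number(od, "od", lower = 0)
  check_that(inherits(calibration, "od_calibration"),
             "calibration must come from fit_od_calibration()")
  check_number(volume_ml, "volume_ml", lower = 1e-12)
  (calibration$intercept + calibration$slope * od) * volume_ml
}

#' Protein copies per cell
#'
#' `copies/cell = amount (mol) x Avogadro / cells`.
#'
#' @param amount_mol Molar amount of protein analyzed.
#' @param n_cells Number of cells analyzed (> 0).
#' @return Copies per cell.
#' @examples
#' copies_per_cell(1e-18, 6.022e5) # ~1
#' @export
copies_per_cell <- function(amount_mol, n_cells) {
  check_number(amount_mol, "amount_mol", lower = 0)
  if (any(n_cells <= 0)) abort("n_cells must be > 0")
  amount_mol * AVOGADRO / n_cells
}

#' Absolute PR quantification for a table of samples
#'
#' Per sample: native/standard area ratios of the two marker peptides are
#' averaged, converted to pmol via the spike, and to copies/cell via the
#' OD-derived cell count.
#'
#' @param areas Peak-area tibble (layout of
#'   [simulate_pr_standard_areas()]: one row per sample x peptide with
#'   `native_area`, `standard_area`, `condition`, `light`, `replicate`,
#'   `timepoint_h`).
#' @param od_table Tibble `condition`, `light`, `replicate`, `time_h`,
#'   `od` (e.g. [simulate_growth_all()] output restricted to the
#'   proteomic timepoints).
#' @param calibration An [fit_od_calibration()] object.
#' @param spike A [standard_spike()].
#' @param volume_ml Harvested volume per sample (default 4.5 mL).
#' @return Tibble `condition`, `light`, `replicate`, `timepoint_h`,
#'   `mean_ratio`, `pmol`, `cells`, `copies_per_cell`.
#' @export
pr_quantify <- function(areas, od_table, calibration,
                        spike = standard_spike(), volume_ml = 4.5) {
  od_cols <- od_table %>%
    rename(timepoint_h = "time_h") %>%
    select("condition", "light", "replicate", "timepoint_h", "od")
  areas %>%
    mutate(ratio = .data$native_area / .data$standard_area) %>%
    group_by(.data$condition, .data$light, .data$replicate,
             .data$timepoint_h) %>%
    summarise(mean_ratio = mean(.data$ratio), .groups = "drop") %>%
    inner_join(od_cols, by = c("condition", "light", "replicate",
                               "timepoint_h")) %>%
    mutate(
      pmol = .data$mean_ratio * spike$spike_pmol,
      cells = cells_from_od(.data$od, calibration, volume_ml),
      copies_per_cell = copies_per_cell(.data$pmol * 1e-12, .data$cells)
    ) %>%
    select("condition", "light", "replicate", "timepoint_h", "mean_ratio",
           "pmol", "cells", "copies_per_cell")
}

#' Consolidate PR quantification over replicate cultures
#'
#' Mean and standard deviation of copies/cell per condition x timepoint
#' (replicates and light regimes pooled; the generator truth is
#' light-independent and the biological light effect on PR protein was
#' modest).
#'
#' @param pr_table [pr_quantify()] output.
#' @return Tibble `condition`, `timepoint_h`, `mean_copies`, `sd_copies`,
#'   `mean_pmol`, `n`.
#' @export
pr_consolidate <- function(pr_table) {
  pr_table %>%
    group_by(.data$condition, .data$timepoint_h) %>%
    summarise(
      mean_copies = mean(.data$copies_per_cell),
      sd_copies = sd(.data$copies_per_cell),
      mean_pmol = mean(.data$pmol),
      n = n(),
      .groups = "drop"
    )
}

#' Stationary-phase PR fold change between conditions
#'
#' Ratio of stationary-phase mean PR abundance, numerator condition over
#' denominator condition, on a per-cell basis (proportional to the
#' per-amount-total-protein basis under constant protein content per
#' cell). The error is propagated from the replicate standard deviations
#' of the two stationary means.
#'
#' @param pr_table [pr_quantify()] output covering both conditions.
#' @param phases Phase map of the proteomic timepoints
#'   ([assign_phase()] output); stationary timepoints define the plateau.
#' @param numerator,denominator Condition names (defaults C over N).
#' @return One-row tibble `fold_change`, `se`, `numerator_mean`,
#'   `denominator_mean`, `n_numerator`, `n_denominator`.
#' @export
condition_fold_change <- function(pr_table,
                                  phases = assign_phase(sort(unique(pr_table$timepoint_h))),
                                  numerator = "C_limited",
                                  denominator = "N_limited") {
  stat_t <- phases$timepoint_h[phases$phase == "stationary"]
  check_that(length(stat_t) >= 2, "need >= 2 stationary timepoints")
  stat <- pr_table %>% filter(.data$timepoint_h %in% stat_t)
  num <- stat %>% filter(.data$condition == numerator)
  den <- stat %>% filter(.data$condition == denominator)
  check_that(nrow(num) > 0 && nrow(den) > 0,
             "both conditions need stationary observations")
  m_num <- mean(num$copies_per_cell)
  m_den <- mean(den$copies_per_cell)
  if (m_den == 0) abort("denominator stationary mean is zero")
  fc <- m_num / m_den
  # first-order error propagation from replicate scatter of the two means
  se <- fc * sqrt(var(num$copies_per_cell) / nrow(num) / m_num^2 +
                    var(den$copies_per_cell) / nrow(den) / m_den^2)
  tibble(
    fold_change = fc, se = se,
    numerator_mean = m_num, denominator_mean = m_den,
    n_numerator = nrow(num), n_denominator = nrow(den)
  )
}
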