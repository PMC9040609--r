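# Growth-curve, survival and transcript analytics.

#' Maximum specific growth rate from an OD time series
#'
#' Maximum over sliding windows of `window` consecutive points of the
#' least-squares slope of ln(OD) versus time. Windows containing
#' non-positive OD values are skipped.
#'
#' @param curve Tibble with `time_h` and `od` columns.
#' @param window Points per sliding window (default 3).
#' @return mu_max in 1/h.
#' @examples
#' tt <- seq(0, 10, 0.5)
#' growth_rate(data.frame(time_h = tt, od = 0.1 * exp(0.14 * tt))) # 0.14
#' @export
growth_rate <- function(curve, window = 3) {
  check_that(all(c("time_h", "od") %in% names(curve)),
             "curve needs time_h and od columns")
  check_number(window, "window", lower = 2)
  n <- nrow(curve)
  check_that(sum(curve$od > 0) >= window, "not enough positive-OD points")
  slopes <- c()
  for (i in seq_len(n - window + 1)) {
    idx <- i:(i + window - 1)
    od <- curve$od[idx]
    if (any(od <= 0)) next
    t <- curve$time_h[idx]
    slopes <- c(slopes, unname(coef(lm(log(od) ~ t))[["t"]]))
  }
  check_that(length(slopes) >= 1, "no valid window with positive OD")
  max(slopes)
}

#' Maximum optical density of a curve
#'
#' @param curve Tibble with an `od` column (non-empty).
#' @return Maximum OD over the series.
#' @export
od_max <- function(curve) {
  check_that("od" %in% names(curve) && nrow(curve) >= 1, "curve must be non-empty")
  max(curve$od)
}

#' Colony-forming units per mL from spot plating
#'
#' `CFU/mL = colonies x dilution_factor / spot_volume_mL`.
#'
#' @param colonies Colony count (>= 0).
#' @param dilution_factor Dilution factor of the plated suspension (>= 0).
#' @param spot_volume_ml Plated spot volume in mL (> 0).
#' @return CFU per mL.
#' @examples
#' cfu_from_spots(15, 1e5, 0.01) # 1.5e8
#' @export
cfu_from_spots <- function(colonies, dilution_factor, spot_volume_ml) {
  check_number(colonies, "colonies", lower = 0)
  check_number(dilution_factor, "dilution_factor", lower = 0)
  if (any(spot_volume_ml <= 0)) abort("spot_volume_ml must be > 0")
  colonies * dilution_factor / spot_volume_ml
}

#' Efficiency-corrected relative expression from qPCR Ct values
#'
#' Calibrator-free relative quantification of a target gene against the
#' reference gene (recA): `E_t^(-Ct_t) / E_r^(-Ct_r)`, computed per
#' sample. Target and reference tables must cover the same samples.
#'
#' @param target,reference Tibbles with `sample_id`, `ct`, `efficiency`
#'   columns (e.g. [simulate_qpcr()] output split by gene).
#' @return `target` with `rel_expression` appended.
#' @export
qpcr_relative <- function(target, reference) {
  need <- c("sample_id", "ct", "efficiency")
  check_that(all(need %in% names(target)) && all(need %in% names(reference)),
             "target and reference need sample_id, ct, efficiency columns")
  check_that(setequal(target$sample_id, reference$sample_id),
             "target and reference cover different samples")
  ref <- reference %>%
    select("sample_id", ref_ct = "ct", ref_eff = "efficiency")
  target %>%
    inner_join(ref, by = "sample_id") %>%
    mutate(rel_expression = .data$efficiency^(-.data$ct) /
             .data$ref_eff^(-.data$ref_ct)) %>%
    select(-"ref_ct", -"ref_eff")
}

#' Significant local maxima in a replicated time series
#'
#' A timepoint is reported as a peak when (a) its replicate mean exceeds
#' the means of both neighbouring timepoints (boundary points use their
#' single neighbour), (b) its mean exceeds the mid-exponential reference
#' level, and (c) a two-sided Welch t-test of its replicate values against
#' the reference timepoint's values gives p < `alpha`.
#'
#' @param series Tibble with `timepoint_h`, `replicate`, `value` columns.
#' @param reference_time Reference timepoint (default 9 h,
#'   mid-exponential); must be present in the series.
#' @param alpha Significance level (default 0.05); `alpha = 0` returns no
#'   peaks.
#' @return Tibble of peaks: `timepoint_h`, `mean_value`, `p_value`.
#' @export
detect_peaks <- function(series, reference_time = 9, alpha = 0.05) {
  check_that(all(c("timepoint_h", "replicate", "value") %in% names(series)),
             "series needs timepoint_h, replicate, value columns")
  times <- sort(unique(series$timepoint_h))
  check_that(length(times) >= 3, "need >= 3 timepoints")
  check_that(reference_time %in% times, "reference time absent from series")
  ref_values <- series$value[series$timepoint_h == reference_time]
  check_that(length(ref_values) >= 2, "need >= 2 replicates at the reference time")
  means <- series %>%
    group_by(.data$timepoint_h) %>%
    summarise(mean_value = mean(.data$value), n = n(), .groups = "drop") %>%
    arrange(.data$timepoint_h)
  check_that(all(means$n >= 2), "need >= 2 replicates at every timepoint")
  out <- purrr::map_dfr(seq_len(nrow(means)), function(i) {
    m <- means$mean_value[i]
    left_ok <- i == 1 || m > means$mean_value[i - 1]
    right_ok <- i == nrow(means) || m > means$mean_value[i + 1]
    if (!(left_ok && right_ok)) return(NULL)
    if (m <= mean(ref_values)) return(NULL)
    vals <- series$value[series$timepoint_h == means$timepoint_h[i]]
    p <- tryCatch(t.test(vals, ref_values)$p.value, error = function(e) NA_real_)
    tibble(timepoint_h = means$timepoint_h[i], mean_value = m, p_value = p)
  })
  if (nrow(out) == 0) return(tibble(timepoint_h = numeric(0),
                                    mean_value = numeric(0),
                                    p_value = numeric(0)))
  out %>% filter(!is.na(.data$p_value), .data$p_value < alpha)
}

#' Stationary-phase survival summary
#'
#' Per culture: the onset of OD decline (first time OD drops below 90% of
#' the maximum after the maximum), the first time CFU reaches zero (NA if
#' cultivability is retained), and the terminal alive fraction.
#'
#' @param curves [simulate_growth_all()]-shaped tibble (`condition`,
#'   `light`, `replicate`, `time_h`, `od`, `cfu_ml`, `alive_frac`).
#' @return Tibble `condition`, `light`, `replicate`,
#'   `od_decline_onset_h`, `cfu_zero_h`, `terminal_alive_frac`.
#' @export
survival_summary <- function(curves) {
  curves %>%
    group_by(.data$condition, .data$light, .data$replicate) %>%
    arrange(.data$time_h, .by_group = TRUE) %>%
    summarise(
      od_decline_onset_h = {
        i_max <- which.max(.data$od)
        after <- which(.data$od < 0.9 * max(.data$od) &
                         seq_along(.data$od) > i_max)
        if (length(after)) .data$time_h[after[1]] else NA_real_
      },
      cfu_zero_h = {
        z <- which(.data$cfu_ml == 0)
        if (length(z)) .data$time_h[z[1]] else NA_real_
      },
      terminal_alive_frac = .data$alive_frac[n()],
      .groups = "drop"
    )
}

#' Growth summary per culture
#'
#' @param curves [simulate_growth_all()]-shaped tibble.
#' @param window Sliding-window size for [growth_rate()].
#' @return Tibble `condition`, `light`, `replicate`, `mu_max`, `od_max`.
#' @export
growth_summary <- function(curves, window = 3) {
  curves %>%
    group_by(.data$condition, .data$light, .data$replicate) %>%
    arrange(.data$time_h, .by_group = TRUE) %>%
    summarise(
      mu_max = growth_rate(dplyr::pick("time_h", "od"), window),
      od_max = max(.data$od),
      .groups = "drop"
    )
}
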