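# Moderated differential expression with within-phase pooling.
#
# Contrasts compare two sample groups (e.g. light vs dark within a
# condition, or C vs N limitation) within one growth phase or across all
# phases; replicate x timepoint values within the phase are treated as
# exchangeable observations. Per-protein residual variances are shrunk
# toward a global prior by an empirical-Bayes method-of-moments fit on the
# log-variance distribution, giving a moderated t with d0 + dg degrees of
# freedom.

#' Define a pairwise contrast
#'
#' @param name Contrast label.
#' @param group_a,group_b Named lists of sample selectors; recognised
#'   fields are `condition`, `light` and `phase` (each a character vector;
#'   omitted fields match everything; `phase = NULL` pools all phases).
#' @return Object of class `iptl_contrast`.
#' @examples
#' make_contrast("light_vs_dark_C_stationary",
#'               group_a = list(condition = "C_limited", light = "light",
#'                              phase = "stationary"),
#'               group_b = list(condition = "C_limited", light = "dark",
#'                              phase = "stationary"))
#' @export
make_contrast <- function(name, group_a, group_b) {
  check_that(is.character(name) && nzchar(name), "contrast needs a name")
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "iptl_contrast")
}

select_group <- function(tab, sel) {
  for (field in c("condition", "light", "phase")) {
    if (!is.null(sel[[field]])) {
      tab <- tab %>% filter(.data[[field]] %in% sel[[field]])
    }
  }
  tab
}

#' Fit a two-group contrast per protein
#'
#' Effect = mean(A) - mean(B) in log2 units; the residual variance is the
#' pooled two-group sample variance with `n_A + n_B - 2` degrees of
#' freedom. Proteins with fewer than two observations in either group are
#' skipped.
#'
#' @param replicate_table Replicate-level expression table
#'   ([expression_replicates()] or [simulate_expression()]).
#' @param contrast An [make_contrast()] object.
#' @return Tibble `protein_id`, `effect`, `s2`, `df`, `n_a`, `n_b`, of
#'   class `contrast_fit` with the contrast stored as an attribute.
#' @export
fit_contrast <- function(replicate_table, contrast) {
  check_that(inherits(contrast, "iptl_contrast"), "contrast must come from make_contrast()")
  value_col <- if ("log2_abundance" %in% names(replicate_table)) {
    "log2_abundance"
  } else {
    "log2_ratio"
  }
  a <- select_group(replicate_table, contrast$group_a) %>% mutate(group = "A")
  b <- select_group(replicate_table, contrast$group_b) %>% mutate(group = "B")
  check_that(nrow(a) > 0 && nrow(b) > 0, "contrast selects an empty group")
  out <- bind_rows(a, b) %>%
    group_by(.data$protein_id) %>%
    summarise(
      n_a = sum(.data$group == "A"),
      n_b = sum(.data$group == "B"),
      effect = mean(.data[[value_col]][.data$group == "A"]) -
        mean(.data[[value_col]][.data$group == "B"]),
      s2 = {
        va <- .data[[value_col]][.data$group == "A"]
        vb <- .data[[value_col]][.data$group == "B"]
        if (length(va) >= 2 && length(vb) >= 2) {
          ((length(va) - 1) * var(va) + (length(vb) - 1) * var(vb)) /
            (length(va) + length(vb) - 2)
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    ) %>%
    filter(.data$n_a >= 2, .data$n_b >= 2) %>%
    mutate(df = .data$n_a + .data$n_b - 2L)
  attr(out, "contrast") <- contrast
  class(out) <- c("contrast_fit", class(out))
  out
}

# Newton solve of trigamma(y) = x (vectorised); Inf for x <= 0.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-protein variances
#'
#' Method-of-moments fit of the scaled-F model on the log-variance
#' distribution: with `z = log(s2)`, `var(z) - trigamma(df/2)` estimates
#' `trigamma(d0/2)`, giving the prior degrees of freedom `d0` (infinite
#' when the observed spread is no larger than expected under equal true
#' variances), and the prior variance `s0^2` follows from `mean(z)`. Each
#' protein's posterior variance is `(d0*s0^2 + df*s2) / (d0 + df)` and the
#' moderated t uses `d0 + df` degrees of freedom. When every variance is
#' zero an ordinary t-test is impossible and the function falls back to
#' unmoderated statistics with a warning.
#'
#' @param fits A [fit_contrast()] table (>= 10 proteins with finite
#'   variances for a stable moments fit).
#' @param d0 Optional prior df override (e.g. `Inf` to shrink fully,
#'   `0` for ordinary t-statistics).
#' @return Object of class `moderated_fit`: list with `table` (per-protein
#'   tibble: `protein_id`, `effect`, `s2`, `df`, `s2_post`, `t`,
#'   `p_value`, `p_adj`, `significant`), `d0`, `s02`, `contrast`.
#' @export
ebayes_moderate <- function(fits, d0 = NULL) {
  s2 <- fits$s2
  df <- fits$df
  check_that(length(s2) >= 1, "no fitted proteins")
  usable <- is.finite(s2) & s2 > 0
  if (!any(usable)) {
    warn("all residual variances are zero; falling back to ordinary t")
    d0 <- 0; s02 <- NA_real_
  } else {
    if (sum(usable) < 10) {
      warn("fewer than 10 proteins with positive variance; moments fit is unstable")
    }
    z <- log(s2[usable])
    e_z <- mean(z); v_z <- var(z)
    if (v_z < 1e-12) {
      # degenerate case: identical observed variances carry no scatter to
      # fit a finite prior df against; the common value is its own prior
      # and the shrinkage map has it as an exact fixed point
      if (is.null(d0)) d0 <- Inf
      s02 <- exp(e_z)
    } else {
      if (is.null(d0)) {
        mean_tri_g <- mean(trigamma(df[usable] / 2))
        excess <- v_z - mean_tri_g
        d0 <- if (!is.finite(excess) || excess <= 0) Inf else 2 * trigamma_inverse(excess)
      }
      mean_dig_g <- mean(digamma(df[usable] / 2) - log(df[usable] / 2))
      if (is.finite(d0) && d0 > 0) {
        s02 <- exp(e_z - mean_dig_g + digamma(d0 / 2) - log(d0 / 2))
      } else {
        s02 <- exp(e_z - mean_dig_g)
      }
    }
  }
  s2_post <- if (d0 == 0) {
    s2
  } else if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  se <- sqrt(s2_post * (1 / fits$n_a + 1 / fits$n_b))
  t_stat <- fits$effect / se
  df_total <- df + d0
  p <- 2 * pt(-abs(t_stat), df = df_total)
  tab <- fits %>%
    as_tibble() %>%
    mutate(
      s2_post = s2_post,
      t = t_stat,
      p_value = p,
      p_adj = bh_fdr(p),
      significant = .data$p_adj < 0.05
    )
  structure(
    list(table = tab, d0 = d0, s02 = s02,
         contrast = attr(fits, "contrast")),
    class = "moderated_fit"
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' proteins are called significantly differential at adjusted p < 0.05.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (same length/order).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p) {
  check_number(p, "p", lower = 0, upper = 1, allow_na = TRUE)
  p.adjust(p, method = "BH")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> contrast: %s\n",
              if (!is.null(x$contrast)) x$contrast$name else "<unnamed>"))
  cat(sprintf("  %d proteins; prior df d0 = %s, prior variance s0^2 = %.4g\n",
              nrow(x$table), format(x$d0, digits = 4), x$s02))
  cat(sprintf("  significant (BH < 0.05): %d\n", sum(x$table$significant)))
  invisible(x)
}

#' Tidy a moderated differential-expression fit
#'
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @return The per-protein results tibble (effect, variances, moderated t,
#'   p, BH-adjusted p, significance flag).
#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' One-row summary of a moderated fit
#'
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @return Tibble with `contrast`, `n_proteins`, `d0`, `s02`,
#'   `n_significant`.
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(
    contrast = if (!is.null(x$contrast)) x$contrast$name else NA_character_,
    n_proteins = nrow(x$table),
    d0 = x$d0,
    s02 = x$s02,
    n_significant = sum(x$table$significant)
  )
}

#' Per-phase differential-expression report
#'
#' Combines moderated fits of the same comparison across growth phases
#' (and optionally an all-phases fit) into one wide table: one row per
#' protein significant in at least one phase, with its log2 fold change in
#' each phase where it is significant (NA elsewhere).
#'
#' @param fits Named list of `moderated_fit` objects; names become the
#'   report columns (e.g. `exponential`, `transition`, `stationary`,
#'   `all_phases`).
#' @return Tibble `protein_id` plus one effect column per phase.
#' @export
phase_report <- function(fits) {
  check_that(length(fits) >= 1 && all(vapply(fits, inherits, logical(1),
                                             "moderated_fit")),
             "fits must be a named list of moderated_fit objects")
  check_that(!is.null(names(fits)) && all(nzchar(names(fits))),
             "fits must be named by phase")
  long <- purrr::imap_dfr(fits, function(f, phase_name) {
    f$table %>%
      filter(.data$significant) %>%
      select("protein_id", "effect") %>%
      mutate(phase = phase_name)
  })
  if (nrow(long) == 0) {
    out <- tibble(protein_id = character(0))
    for (nm in names(fits)) out[[nm]] <- numeric(0)
    return(out)
  }
  long %>%
    tidyr::pivot_wider(names_from = "phase", values_from = "effect") %>%
    arrange(.data$protein_id)
}
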