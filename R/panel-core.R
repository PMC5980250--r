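#' Per-sample fatty-acid group sums
#'
#' Sums a set of fatty acids within each sample of a panel, with explicit
#' handling of left-censored (below limit-of-detection) members. Quantified
#' members contribute their value; below-LOD members contribute 0 under the
#' `"zero"` policy or `lod / 2` under the `"half_lod"` policy; members missing
#' from a sample contribute 0 and are counted in `n_missing` so that partial
#' sums are never silent.
#'
#' @param panel A long panel tibble as produced by [generate_panel()] or
#'   [read_panel()]: columns `sample_id`, `farm_id`, `region`, `year`,
#'   `month`, `fat_pct`, `total_fa`, `code`, `value`, `status` (one of
#'   `"quantified"`, `"below_lod"`, `"missing"`).
#' @param members Character vector of fatty-acid codes to sum (must exist in
#'   `registry`).
#' @param lod_policy `"zero"` (censored members add nothing) or `"half_lod"`
#'   (censored members add `lod / 2`).
#' @param lod Limit of detection in g/100 g milk; default 0.001.
#' @param registry Fatty-acid registry, see [fa_registry()].
#' @return A tibble with one row per sample: `sample_id`, `total`,
#'   `n_quantified`, `n_below_lod`, `n_missing`.
#' @examples
#' panel <- generate_panel(synthetic_config(seed = 1))$panel
#' sum_fa_group(panel, fa_family_members("omega3"))
#' @export
sum_fa_group <- function(panel, members,
                         lod_policy = c("zero", "half_lod"),
                         lod = LOD_DEFAULT,
                         registry = fa_registry()) {
  lod_policy <- match.arg(lod_policy)
  check_fa_codes(members, registry)
  check_panel(panel)
  ids <- dplyr::distinct(panel, .data$sample_id)
  rows <- panel |>
    dplyr::filter(.data$code %in% members) |>
    tidyr::complete(sample_id = ids$sample_id, code = members,
                    fill = list(status = "missing")) |>
    dplyr::mutate(
      contrib = dplyr::case_when(
        .data$status == "quantified" ~ .data$value,
        .data$status == "below_lod" & lod_policy == "half_lod" ~ lod / 2,
        TRUE ~ 0
      )
    )
  rows |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      total = sum(.data$contrib),
      n_quantified = sum(.data$status == "quantified"),
      n_below_lod = sum(.data$status == "below_lod"),
      n_missing = sum(.data$status == "missing"),
      .groups = "drop"
    )
}

#' Omega-6/omega-3 ratio triple
#'
#' Computes the three ratios reported for milk fat: LA/ALA, total
#' omega-6 / total omega-3, and its reciprocal. Vectorised over its inputs.
#'
#' @param omega6_total,omega3_total Group totals, g/100 g milk.
#' @param la,ala Linoleic and alpha-linolenic acid, g/100 g milk.
#' @return A tibble with columns `la_ala`, `w6_w3`, `w3_w6`.
#' @examples
#' compute_fa_ratios(0.0525, 0.0565, 0.0447, 0.0441)
#' @export
compute_fa_ratios <- function(omega6_total, omega3_total, la, ala) {
  bad <- function(x, which) {
    if (any(!is.finite(x) | x <= 0)) {
      abort(paste0("non-positive denominator for ratio '", which, "'"),
            class = "lactofat_domain_error")
    }
  }
  bad(ala, "la_ala")
  bad(omega3_total, "w6_w3")
  bad(omega6_total, "w3_w6")
  bad(la, "la_ala")
  tibble::tibble(
    la_ala = la / ala,
    w6_w3 = omega6_total / omega3_total,
    w3_w6 = omega3_total / omega6_total
  )
}

#' Censoring-aware panel summary statistics
#'
#' Summarises one or more fatty acids over a panel using the quantified-only
#' convention of the reference laboratory: samples below the limit of
#' detection reduce `n` and never enter the mean, so means of heavily censored
#' acids are means of the quantified upper part of the distribution (and are
#' therefore elevated relative to the all-sample mean; see
#' [estimate_censored_mean()] for the complementary estimate). Acids with no
#' quantified observations are reported explicitly with `n = 0` and `NA`
#' statistics, never as a silent zero.
#'
#' @inheritParams sum_fa_group
#' @param codes Fatty-acid codes to summarise; default all codes in the panel.
#' @param unit `"g_per_100g"` (as stored) or `"pct_of_total_fa"`, in which
#'   case each sample's value is `100 * value / total_fa` before aggregation.
#' @return A tibble with one row per code: `code`, `unit`, `mean`, `n`, `sd`,
#'   `cv` (percent), `se`.
#' @examples
#' panel <- generate_panel(synthetic_config(seed = 1))$panel
#' summarize_fa(panel, c("ala", "la", "cla"))
#' @export
summarize_fa <- function(panel, codes = NULL,
                         unit = c("g_per_100g", "pct_of_total_fa")) {
  unit <- match.arg(unit)
  check_panel(panel)
  if (nrow(panel) == 0) {
    abort("panel is empty", class = "lactofat_domain_error")
  }
  codes <- codes %||% unique(panel$code)
  absent <- setdiff(codes, unique(panel$code))
  if (length(absent) > 0) {
    abort(paste0("code(s) not present in panel: ",
                 paste(absent, collapse = ", ")),
          class = "lactofat_key_error")
  }
  x <- panel |>
    dplyr::filter(.data$code %in% codes) |>
    dplyr::mutate(
      obs = dplyr::if_else(
        rep(unit == "pct_of_total_fa", dplyr::n()),
        100 * .data$value / .data$total_fa,
        .data$value
      )
    )
  x |>
    dplyr::group_by(code = factor(.data$code, levels = codes)) |>
    dplyr::summarise(
      n = sum(.data$status == "quantified"),
      mean = mean(.data$obs[.data$status == "quantified"]),
      sd = stats::sd(.data$obs[.data$status == "quantified"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      code = as.character(.data$code),
      unit = unit,
      mean = dplyr::if_else(.data$n == 0, NA_real_, .data$mean),
      cv = 100 * .data$sd / .data$mean,
      se = .data$sd / sqrt(.data$n)
    ) |>
    dplyr::select("code", "unit", "mean", "n", "sd", "cv", "se")
}

#' All-sample mean of a left-censored fatty acid
#'
#' The quantified-only mean of a censored acid describes only the samples at
#' or above the limit of detection. This estimator reconstitutes the
#' all-sample mean by assigning each unquantified sample a fixed imputed
#' value (conventionally half the LOD):
#' `(n_quantified * mean_quantified + (n_total - n_quantified) * imputed) / n_total`.
#'
#' @param n_total Total number of samples.
#' @param n_quantified Number of samples at or above the LOD.
#' @param mean_quantified Mean of the quantified samples, g/100 g milk.
#' @param lod Limit of detection, g/100 g milk.
#' @param imputed_value Value assumed for each unquantified sample; must not
#'   exceed `lod`. Default `lod / 2`.
#' @return The estimated all-sample mean, g/100 g milk.
#' @examples
#' # DHA in the grassmilk panel: 249 of 1162 samples quantified
#' cens <- grassmilk_dha_censoring()
#' estimate_censored_mean(cens$n_total, cens$n_quantified, cens$mean_quantified)
#' @export
estimate_censored_mean <- function(n_total, n_quantified, mean_quantified,
                                   lod = LOD_DEFAULT,
                                   imputed_value = lod / 2) {
  if (n_total <= 0) {
    abort("n_total must be positive", class = "lactofat_domain_error")
  }
  if (n_quantified > n_total) {
    abort("n_quantified cannot exceed n_total",
          class = "lactofat_domain_error")
  }
  if (imputed_value > lod) {
    abort("imputed_value must not exceed the LOD",
          class = "lactofat_domain_error")
  }
  if (n_quantified == 0) {
    return(imputed_value)
  }
  (n_quantified * mean_quantified +
     (n_total - n_quantified) * imputed_value) / n_total
}

#' Tukey-fence outlier screening
#'
#' Flags observations of the given fatty acids outside the box-plot fence
#' `[Q1 - k * IQR, Q3 + k * IQR]` computed over quantified values, and returns
#' a cleaned copy of the panel with flagged values set to missing. The input
#' panel is never modified. The default `k = 3`, `side = "high"` codifies the
#' removal of rare, severe, high outliers typical of laboratory panels;
#' groups with identical values everywhere (zero IQR) are never flagged, and
#' codes with fewer than four quantified observations are skipped with a
#' warning record rather than screened.
#'
#' @inheritParams sum_fa_group
#' @param codes Fatty-acid codes to screen.
#' @param k Fence multiplier, > 0.
#' @param side Which fence(s) to apply: `"high"`, `"low"` or `"both"`.
#' @return A list with `panel` (cleaned copy), `flagged` (tibble `sample_id`,
#'   `code`, `value`, `fence_low`, `fence_high`) and `skipped` (tibble of
#'   codes not screened and why).
#' @examples
#' panel <- generate_panel(synthetic_config(seed = 1))$panel
#' scr <- screen_outliers(panel, "cla")
#' scr$flagged
#' @export
screen_outliers <- function(panel, codes, k = 3,
                            side = c("high", "low", "both")) {
  side <- match.arg(side)
  if (k <= 0) abort("k must be positive", class = "lactofat_domain_error")
  check_panel(panel)
  flagged <- list()
  skipped <- list()
  out <- panel
  for (cd in codes) {
    q <- out$code == cd & out$status == "quantified"
    vals <- out$value[q]
    if (sum(q) < 4) {
      skipped[[cd]] <- tibble::tibble(
        code = cd, reason = "fewer than 4 quantified observations")
      next
    }
    qs <- stats::quantile(vals, c(0.25, 0.75), names = FALSE)
    iqr <- qs[2] - qs[1]
    if (iqr == 0) {
      # all mass in one value: fence collapses, flagging is meaningless
      next
    }
    lo <- if (side %in% c("low", "both")) qs[1] - k * iqr else -Inf
    hi <- if (side %in% c("high", "both")) qs[2] + k * iqr else Inf
    bad <- q & (out$value < lo | out$value > hi)
    if (any(bad)) {
      flagged[[cd]] <- tibble::tibble(
        sample_id = out$sample_id[bad], code = cd,
        value = out$value[bad], fence_low = lo, fence_high = hi)
      out$value[bad] <- NA_real_
      out$status[bad] <- "missing"
    }
  }
  list(
    panel = out,
    flagged = if (length(flagged)) dplyr::bind_rows(flagged) else
      tibble::tibble(sample_id = character(), code = character(),
                     value = double(), fence_low = double(),
                     fence_high = double()),
    skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
      tibble::tibble(code = character(), reason = character())
  )
}

#' Grouped (regional / yearly / monthly) panel means
#'
#' Arithmetic group means of quantified values over any subset of the
#' `region`, `year`, `month` grouping variables. These are descriptive means,
#' not mixed-model least-squares means; with the balanced sampling designs of
#' the synthetic generator the two coincide in expectation.
#'
#' @inheritParams summarize_fa
#' @param code A single fatty-acid code.
#' @param groupers Subset of `c("region", "year", "month")`.
#' @return A tibble with the grouping columns plus `mean`, `n`, `sd`, `cv`,
#'   `se`. Groups with no quantified observations are omitted and listed in
#'   the `"dropped_groups"` attribute.
#' @seealso [high_low_months()] for the seasonal high/low summary.
#' @examples
#' panel <- generate_panel(synthetic_config(seed = 1))$panel
#' monthly_regional_means(panel, "cla", "month")
#' @export
monthly_regional_means <- function(panel, code, groupers = "month",
                                   unit = c("g_per_100g", "pct_of_total_fa")) {
  unit <- match.arg(unit)
  check_panel(panel)
  if (nrow(panel) == 0) {
    abort("panel is empty", class = "lactofat_domain_error")
  }
  groupers <- match.arg(groupers, c("region", "year", "month"),
                        several.ok = TRUE)
  cd <- code
  x <- panel |>
    dplyr::filter(.data$code == cd) |>
    dplyr::mutate(
      obs = dplyr::if_else(
        rep(unit == "pct_of_total_fa", dplyr::n()),
        100 * .data$value / .data$total_fa,
        .data$value
      )
    )
  all_groups <- dplyr::distinct(x, dplyr::pick(dplyr::all_of(groupers)))
  stats <- x |>
    dplyr::filter(.data$status == "quantified") |>
    dplyr::group_by(dplyr::pick(dplyr::all_of(groupers))) |>
    dplyr::summarise(
      mean = mean(.data$obs),
      n = dplyr::n(),
      sd = stats::sd(.data$obs),
      .groups = "drop"
    ) |>
    dplyr::mutate(cv = 100 * .data$sd / .data$mean,
                  se = .data$sd / sqrt(.data$n))
  dropped <- dplyr::anti_join(all_groups, stats, by = groupers)
  attr(stats, "dropped_groups") <- dropped
  attr(stats, "code") <- cd
  stats
}

#' @rdname monthly_regional_means
#' @description `high_low_months()` reduces a monthly means table to the
#'   seasonal high and low: the months attaining the maximum and minimum mean
#'   and their ratio. A single-month table returns ratio 1.
#' @param monthly A means table from [monthly_regional_means()] with a
#'   `month` column (any additional grouping is averaged over first).
#' @export
high_low_months <- function(monthly) {
  if (!"month" %in% names(monthly)) {
    abort("'monthly' must contain a month column",
          class = "lactofat_domain_error")
  }
  by_month <- monthly |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(mean = mean(.data$mean), .groups = "drop")
  hi <- which.max(by_month$mean)
  lo <- which.min(by_month$mean)
  tibble::tibble(
    high_month = by_month$month[hi], high_mean = by_month$mean[hi],
    low_month = by_month$month[lo], low_mean = by_month$mean[lo],
    ratio = by_month$mean[hi] / by_month$mean[lo]
  )
}

# Internal: validate the long panel schema.
check_panel <- function(panel) {
  required <- c("sample_id", "code", "value", "status")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(paste0("panel is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lactofat_schema_error")
  }
  bad <- setdiff(unique(panel$status),
                 c("quantified", "below_lod", "missing"))
  if (length(bad) > 0) {
    abort(paste0("unknown status value(s): ", paste(bad, collapse = ", ")),
          class = "lactofat_schema_error")
  }
  invisible(panel)
}
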