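# Fatty acids reported by the servings calculator, in output order.
SERVING_FAS <- c("ala", "la", "epa", "dpa", "dha")

#' Daily fatty-acid content of dairy servings
#'
#' Converts a daily dairy food basket into mg/day of ALA, LA, EPA, DPA and
#' DHA: for each food, `daily_weight_g * fat_fraction * 0.933 g FA/g fat *
#' (profile amount / profile total FA) * 1000`. DHA uses the censoring-aware
#' all-sample estimate from [estimate_censored_mean()] (about 0.0006 g/100 g
#' for the grassmilk panel) rather than the elevated quantified-only mean;
#' pass `dha_censoring = NULL` to use the profile's tabulated DHA instead.
#'
#' The carried `la_ala_ratio` column reproduces the source panel's printed
#' per-sample ratio summary (0.954 for grassmilk), which is invariant under
#' scaling of amounts; the ratio of the computed LA and ALA milligrams is a
#' slightly different number and is always recomputable from the output.
#'
#' @param servings A servings tibble, see [dairy_servings()]: columns `food`,
#'   `daily_portions`, `serving_equivalents`, `daily_weight_g`,
#'   `fat_fraction`.
#' @param profiles Long milk profile table.
#' @param label Milk profile label supplying the fatty-acid composition.
#' @param constants See [energy_constants()] (only `fa_g_per_g_dairy_fat` is
#'   used).
#' @param dha_censoring Censoring summary list for DHA (default
#'   [grassmilk_dha_censoring()]), or `NULL`.
#' @return A tibble with one row per food: `source`, `serving_equivalents`,
#'   `weight_g`, the five acids in mg/day, `epa_dpa`, `epa_dpa_dha`,
#'   `la_ala_ratio`.
#' @examples
#' serving_fa_content(dairy_servings(), milk_fa_profiles(), "grassmilk")
#' @export
serving_fa_content <- function(servings, profiles = milk_fa_profiles(),
                               label = "grassmilk",
                               constants = energy_constants(),
                               dha_censoring = grassmilk_dha_censoring()) {
  if (any(servings$daily_weight_g <= 0)) {
    abort("daily_weight_g must be positive", class = "lactofat_domain_error")
  }
  total <- profile_amount(profiles, label, "total_fa")
  amounts <- purrr::map_dbl(SERVING_FAS,
                            \(it) profile_amount(profiles, label, it))
  names(amounts) <- SERVING_FAS
  if (!is.null(dha_censoring)) {
    amounts[["dha"]] <- estimate_censored_mean(
      dha_censoring$n_total, dha_censoring$n_quantified,
      dha_censoring$mean_quantified)
  }
  carried_ratio <- profile_amount(profiles, label, "w6_w3")
  fat_g <- servings$daily_weight_g * servings$fat_fraction
  fa_mg <- outer(fat_g * constants$fa_g_per_g_dairy_fat,
                 amounts / total * 1000)
  colnames(fa_mg) <- SERVING_FAS
  out <- tibble::as_tibble(fa_mg)
  out <- dplyr::bind_cols(
    tibble::tibble(source = servings$food,
                   serving_equivalents = servings$serving_equivalents,
                   weight_g = servings$daily_weight_g),
    out
  )
  out$epa_dpa <- out$epa + out$dpa
  out$epa_dpa_dha <- out$epa_dpa + out$dha
  out$la_ala_ratio <- carried_ratio
  out
}

#' @rdname serving_fa_content
#' @description `daily_totals()` sums the basket into one intake row (the
#'   "recommended 3 dairy servings" row).
#' @export
daily_totals <- function(servings, profiles = milk_fa_profiles(),
                         label = "grassmilk",
                         constants = energy_constants(),
                         dha_censoring = grassmilk_dha_censoring()) {
  if (nrow(servings) == 0) {
    abort("servings basket is empty", class = "lactofat_domain_error")
  }
  per_food <- serving_fa_content(servings, profiles, label, constants,
                                 dha_censoring)
  per_food |>
    dplyr::summarise(
      source = paste0(label, "_dairy_totals"),
      serving_equivalents = sum(.data$serving_equivalents),
      weight_g = sum(.data$weight_g),
      dplyr::across(dplyr::all_of(c(SERVING_FAS, "epa_dpa", "epa_dpa_dha")),
                    sum),
      la_ala_ratio = .data$la_ala_ratio[1]
    )
}

#' Scale an intake row to actual consumption
#'
#' Linearly rescales every fatty-acid amount of an intake row from its
#' current daily weight to an actual (e.g. per-capita) daily weight. Ratios
#' are unchanged by construction.
#'
#' @param row A one-row intake tibble from [daily_totals()] or
#'   [fish_intake_row()].
#' @param actual_weight_g Actual daily intake weight, g/day.
#' @return The rescaled intake row.
#' @examples
#' daily_totals(dairy_servings()) |> scale_per_capita(270)
#' @export
scale_per_capita <- function(row, actual_weight_g) {
  if (row$weight_g <= 0) {
    abort("intake row weight must be positive",
          class = "lactofat_domain_error")
  }
  f <- actual_weight_g / row$weight_g
  row |>
    dplyr::mutate(
      dplyr::across(dplyr::any_of(c(SERVING_FAS, "epa_dpa", "epa_dpa_dha")),
                    \(x) x * f),
      weight_g = actual_weight_g,
      source = paste0(.data$source, "_per_capita")
    )
}

#' @rdname serving_fa_content
#' @description `fish_intake_row()` converts [fish_profile()] into an intake
#'   row comparable with the dairy totals.
#' @param fish A fish composition row, see [fish_profile()].
#' @export
fish_intake_row <- function(fish = fish_profile()) {
  tibble::tibble(
    source = fish$source,
    serving_equivalents = NA_real_,
    weight_g = fish$weight_g,
    ala = fish$ala, la = fish$la,
    epa = fish$epa, dpa = fish$dpa, dha = fish$dha,
    epa_dpa = fish$epa + fish$dpa,
    epa_dpa_dha = fish$epa + fish$dpa + fish$dha,
    la_ala_ratio = fish$la_ala_ratio
  )
}

#' Dairy-versus-fish fatty-acid supply ratios
#'
#' Head-to-head comparison of two intake rows (typically per-capita dairy
#' and per-capita fish): the ratio of dairy to fish supply for each acid and
#' for the long-chain sums. Acids the fish row does not supply are reported
#' as `NA` (undefined), never as infinity.
#'
#' @param dairy,fish One-row intake tibbles on the same units (mg/day).
#' @return A tibble: `quantity`, `dairy_mg`, `fish_mg`, `ratio`.
#' @examples
#' d <- daily_totals(dairy_servings()) |> scale_per_capita(270)
#' f <- fish_intake_row() |> scale_per_capita(9.12)
#' dairy_vs_fish(d, f)
#' @export
dairy_vs_fish <- function(dairy, fish) {
  qs <- c(SERVING_FAS, "epa_dpa", "epa_dpa_dha")
  tibble::tibble(
    quantity = qs,
    dairy_mg = purrr::map_dbl(qs, \(q) dairy[[q]]),
    fish_mg = purrr::map_dbl(qs, \(q) fish[[q]])
  ) |>
    dplyr::mutate(
      ratio = dplyr::if_else(.data$fish_mg > 0,
                             .data$dairy_mg / .data$fish_mg, NA_real_)
    )
}
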