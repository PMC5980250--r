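#' Built-in representative milk fatty-acid profiles
#'
#' Year-round mean compositions (g/100 g milk) of U.S. retail conventional
#' milk, retail organic milk, and raw grass-fed ("grassmilk") bulk-tank milk,
#' the three dairy fat sources compared throughout the package. Conventional
#' and organic values are 12-month retail means; grassmilk values are the
#' 3-year, 1,163-sample bulk-tank means. `item` mixes individual fatty-acid
#' codes (see [fa_registry()]) with group totals (`*_total`) and three
#' panel-level ratio summaries.
#'
#' The ratio rows (`la_ala`, `w6_w3`, `w3_w6`) are *means of per-sample
#' ratios*, the convention used in the source panels; the ratio of the
#' tabulated mean amounts is a different (slightly smaller) number and can be
#' recomputed with [compute_fa_ratios()]. Both conventions are legitimate and
#' the package never silently swaps one for the other.
#'
#' `frac_quantified` records the share of panel samples at or above the
#' 0.001 g/100 g quantification limit; DHA is heavily left-censored in all
#' three milks (2/160 conventional, 4/218 organic, 249/1162 grassmilk
#' samples), which is why conventional and organic DHA means are `NA` and why
#' grassmilk DHA work uses the censoring-aware estimate from
#' [estimate_censored_mean()] (see [grassmilk_dha_censoring()]).
#'
#' @return A long tibble with columns `label`, `item`, `amount`, `n`, `sd`,
#'   `frac_quantified`.
#' @examples
#' milk_fa_profiles() |> dplyr::filter(item %in% c("la", "ala", "total_fa"))
#' @export
milk_fa_profiles <- function() {
  tribble_long <- function(label, items, amounts, n = NA_real_, sd = NA_real_,
                           frac = NA_real_) {
    tibble::tibble(label = label, item = items, amount = amounts,
                   n = n, sd = sd, frac_quantified = frac)
  }
  items <- c("total_fa", "saturated_total", "14:0", "16:0", "18:0",
             "mono_total", "18:1", "omega3_total", "ala", "epa", "dpa", "dha",
             "omega6_total", "la", "pufa_total", "trans_total", "cla",
             "la_ala", "w6_w3", "w3_w6")
  conv <- tribble_long("conventional", items,
    c(3.098, 2.043, 0.3274, 0.8995, 0.3559, 0.7944, 0.7074,
      0.0198, 0.0159, 0.0025, 0.0037, NA,
      0.0948, 0.0856, 0.1147, 0.1281, 0.0192,
      6.272, 5.774, 0.219),
    n = 160)
  conv$frac_quantified[conv$item == "dha"] <- 2 / 160
  org <- tribble_long("organic", items,
    c(3.108, 2.116, 0.3490, 0.9344, 0.3434, 0.7410, 0.6505,
      0.0321, 0.0255, 0.0033, 0.0044, NA,
      0.0711, 0.0639, 0.1037, 0.1254, 0.0227,
      2.568, 2.276, 0.456),
    n = 218)
  org$frac_quantified[org$item == "dha"] <- 4 / 218
  grass <- tribble_long("grassmilk", items,
    c(3.585, 2.399, 0.3997, 1.116, 0.3738, 0.8352, 0.7258,
      0.0565, 0.0441, 0.00413, 0.00543, 0.00106,
      0.0525, 0.0447, 0.1088, 0.1934, 0.0498,
      1.042, 0.954, 1.083),
    n = c(1161, 1163, 1160, 1162, 1163, 1163, 1163,
          1161, 1163, 1157, 1158, 249,
          1163, 1156, 1161, 1163, 1163,
          1156, 1154, 1154),
    sd = c(0.48, 0.39, 0.07, 0.24, 0.08, 0.12, 0.12,
           0.013, 0.011, 0.0010, 0.0012, 0.0005,
           0.012, 0.010, 0.022, 0.06, 0.019,
           0.21, 0.18, 0.20))
  grass$frac_quantified[grass$item == "dha"] <- 249 / 1162
  dplyr::bind_rows(conv, org, grass)
}

#' @rdname milk_fa_profiles
#' @description `grassmilk_dha_censoring()` returns the DHA censoring summary
#'   of the grassmilk bulk-tank panel (total samples, quantified samples,
#'   quantified-only mean), the inputs the censoring-aware DHA estimate is
#'   computed from.
#' @export
grassmilk_dha_censoring <- function() {
  list(n_total = 1162, n_quantified = 249, mean_quantified = 0.00106)
}

# Look up one amount in a long profile table.
profile_amount <- function(profiles, label, item) {
  hit <- profiles$amount[profiles$label == label & profiles$item == item]
  if (length(hit) == 0) {
    abort(paste0("profile '", label, "' has no item '", item, "'"),
          class = "lactofat_key_error")
  }
  hit[[1]]
}

#' Default dairy serving basket and fish composition
#'
#' `dairy_servings()` returns the four-food daily basket that supplies the
#' recommended 3 dairy servings: 1.5 cups whole milk (244 g/cup, 3.25% fat),
#' 1.5 oz cheddar (33.14% fat), 6 oz low-fat fruit yogurt (1.41% fat) and a
#' half-cup of vanilla ice cream (11.1% fat). Ice cream counts no dairy
#' serving equivalents but still contributes weight and fat.
#'
#' `fish_profile()` returns the mean daily fatty-acid supply of the
#' recommended 8 oz/week of fish (32.4 g/day), averaged over seven commonly
#' consumed species, in mg/day, together with the carried LA/ALA ratio of the
#' source data.
#'
#' @return A tibble (`dairy_servings`) or a one-row tibble (`fish_profile`).
#' @examples
#' dairy_servings()
#' fish_profile()
#' @export
dairy_servings <- function() {
  tibble::tribble(
    ~food,            ~daily_portions, ~serving_equivalents, ~daily_weight_g, ~fat_fraction,
    "whole_milk",     1.5,             1.5,                  366.0,           0.0325,
    "cheddar_cheese", 1.0,             1.0,                  42.53,           0.3314,
    "lowfat_yogurt",  1.0,             0.5,                  170.1,           0.0141,
    "ice_cream",      1.0,             0.0,                  66.0,            0.111
  )
}

#' @rdname dairy_servings
#' @export
fish_profile <- function() {
  tibble::tibble(
    source = "fish_mean_7_species",
    weight_g = 32.4,
    ala = 19.6, la = 138,
    epa = 89.4, dpa = 37.2, dha = 155,
    la_ala_ratio = 6.5
  )
}

#' @rdname dairy_servings
#' @description `per_capita_intakes()` returns the U.S. per-capita daily
#'   consumption weights used to scale the recommended baskets: 270 g/day of
#'   dairy products and 9.12 g/day of finfish.
#' @export
per_capita_intakes <- function() {
  c(dairy_g = 270, fish_g = 9.12)
}
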