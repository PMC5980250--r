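#' Energy and conversion constants for the diet model
#'
#' Fixed constants of the dietary fatty-acid model: energy density of dairy
#' fat (8.79 kcal/g) and nondairy fat (8.90 kcal/g), the fatty-acid content
#' of dairy fat (0.933 g FA per g fat), and the modelled total energy intake
#' (2,100 kcal/day, a moderately active 19- to 30-year-old woman).
#'
#' @return A named list.
#' @export
energy_constants <- function() {
  list(
    kcal_per_g_dairy_fat = 8.79,
    kcal_per_g_nondairy_fat = 8.90,
    fa_g_per_g_dairy_fat = 0.933,
    total_energy_kcal = 2100
  )
}

#' Nondairy fat compositions
#'
#' LA and ALA content of the nondairy share of dietary fat, per 100 g of
#' fat, for two food baskets: `typical_LA` (eight common foods, soy-oil
#' heavy; LA/ALA 12.6) and `low_LA` (three of the eight replaced by low-LA
#' analogues such as canola-oil margarine; LA/ALA 5.07).
#'
#' @return A tibble with columns `label`, `la_per_100g_fat`,
#'   `ala_per_100g_fat`.
#' @export
nondairy_fat_profiles <- function() {
  tibble::tribble(
    ~label,       ~la_per_100g_fat, ~ala_per_100g_fat,
    "typical_LA", 23.23,            1.841,
    "low_LA",     13.84,            2.731
  )
}

#' Daily energy allocated to dairy and nondairy fat
#'
#' The kcal/day of dairy fat and nondairy fat for each (fat fraction, dairy
#' level) cell of the scenario grid. Dairy fat energy follows servings —
#' 313 kcal/day at the recommended 3 servings, 1.5 times that (469.5) at 4.5
#' servings — and is constant across fat levels. At 33% of energy from fat
#' the allocations are the model's reference values (nondairy 380 and 221.1
#' kcal); at other fat levels nondairy fat absorbs the remainder,
#' `fat_fraction * total_energy - dairy_kcal`, floored at zero. The (20%
#' fat, high dairy) cell is energy-deficient — 4.5 servings of full-fat dairy
#' alone exceed 20% of 2,100 kcal — and is flagged `energy_deficit`.
#'
#' @param constants See [energy_constants()].
#' @return A tibble: `fat_fraction`, `dairy_level`, `dairy_kcal`,
#'   `nondairy_kcal`, `energy_deficit`.
#' @export
kcal_allocations <- function(constants = energy_constants()) {
  grid <- tidyr::expand_grid(
    fat_fraction = c(0.20, 0.33, 0.45),
    dairy_level = c("moderate", "high")
  )
  grid |>
    dplyr::mutate(
      dairy_kcal = dplyr::if_else(.data$dairy_level == "moderate",
                                  313, 469.5),
      nondairy_raw = dplyr::case_when(
        .data$fat_fraction == 0.33 & .data$dairy_level == "moderate" ~ 380,
        .data$fat_fraction == 0.33 & .data$dairy_level == "high" ~ 221.1,
        TRUE ~ .data$fat_fraction * constants$total_energy_kcal -
          .data$dairy_kcal
      ),
      energy_deficit = .data$nondairy_raw < 0,
      nondairy_kcal = pmax(.data$nondairy_raw, 0)
    ) |>
    dplyr::select(-"nondairy_raw")
}

#' Fatty-acid intake from dairy fat
#'
#' Converts a daily dairy-fat energy intake into grams of LA and ALA:
#' `kcal / 8.79` grams of dairy fat, times the milk profile's share of the
#' acid in total fatty acids, times 0.933 g FA per g fat.
#'
#' @param dairy_fat_kcal Dairy fat energy, kcal/day (>= 0).
#' @param profiles Long profile table, see [milk_fa_profiles()].
#' @param label Dairy profile label.
#' @param constants See [energy_constants()].
#' @return A one-row tibble: `la_g`, `ala_g`.
#' @examples
#' dairy_fa_intake(313, milk_fa_profiles(), "grassmilk")
#' @export
dairy_fa_intake <- function(dairy_fat_kcal, profiles, label,
                            constants = energy_constants()) {
  if (dairy_fat_kcal < 0) {
    abort("dairy_fat_kcal must be >= 0", class = "lactofat_domain_error")
  }
  total <- profile_amount(profiles, label, "total_fa")
  if (total <= 0) {
    abort("profile total_fa must be positive",
          class = "lactofat_domain_error")
  }
  fat_g <- dairy_fat_kcal / constants$kcal_per_g_dairy_fat
  fa_g <- fat_g * constants$fa_g_per_g_dairy_fat
  tibble::tibble(
    la_g = fa_g * profile_amount(profiles, label, "la") / total,
    ala_g = fa_g * profile_amount(profiles, label, "ala") / total
  )
}

#' Fatty-acid intake from nondairy fat
#'
#' `kcal / 8.90` grams of nondairy fat times the per-100 LA and ALA content
#' of the nondairy composition.
#'
#' @param nondairy_fat_kcal Nondairy fat energy, kcal/day (>= 0).
#' @param label `"typical_LA"` or `"low_LA"` (row of
#'   [nondairy_fat_profiles()]).
#' @param constants See [energy_constants()].
#' @return A one-row tibble: `la_g`, `ala_g`.
#' @examples
#' nondairy_fa_intake(380, "typical_LA")
#' @export
nondairy_fa_intake <- function(nondairy_fat_kcal, label,
                               constants = energy_constants()) {
  if (nondairy_fat_kcal < 0) {
    abort("nondairy_fat_kcal must be >= 0", class = "lactofat_domain_error")
  }
  prof <- nondairy_fat_profiles()
  row <- prof[prof$label == label, ]
  if (nrow(row) == 0) {
    abort(paste0("unknown nondairy profile '", label, "'"),
          class = "lactofat_key_error")
  }
  fat_g <- nondairy_fat_kcal / constants$kcal_per_g_nondairy_fat
  tibble::tibble(
    la_g = fat_g * row$la_per_100g_fat / 100,
    ala_g = fat_g * row$ala_per_100g_fat / 100
  )
}

#' Evaluate one diet scenario
#'
#' Sums the dairy and nondairy LA and ALA contributions for one (fat
#' fraction, dairy level, dairy profile, nondairy profile) cell and computes
#' the total LA/ALA ratio and its change from the baseline.
#'
#' @param fat_fraction Fraction of total energy from fat (0.20, 0.33, 0.45).
#' @param dairy_level `"moderate"` (3 servings/day) or `"high"` (4.5).
#' @param dairy_label Dairy profile label in `profiles`.
#' @param nondairy_label `"typical_LA"` or `"low_LA"`.
#' @param profiles Long milk profile table.
#' @param constants See [energy_constants()].
#' @param baseline_ratio Ratio that `delta_from_baseline` is measured from;
#'   default the computed baseline (moderate conventional dairy, typical-LA
#'   nondairy fat, 33% fat), see [baseline_la_ala_ratio()].
#' @param allocations Energy allocation table, see [kcal_allocations()].
#' @return A one-row tibble with the scenario descriptors, the four
#'   component intakes (g/day), `la_total`, `ala_total`, `la_ala_ratio` and
#'   `delta_from_baseline` (baseline minus scenario ratio; positive is an
#'   improvement).
#' @examples
#' evaluate_scenario(0.33, "moderate", "grassmilk", "typical_LA")
#' @export
evaluate_scenario <- function(fat_fraction, dairy_level, dairy_label,
                              nondairy_label,
                              profiles = milk_fa_profiles(),
                              constants = energy_constants(),
                              baseline_ratio = NULL,
                              allocations = kcal_allocations(constants)) {
  cell <- allocations[allocations$fat_fraction == fat_fraction &
                        allocations$dairy_level == dairy_level, ]
  if (nrow(cell) != 1) {
    abort(paste0("no energy allocation for fat_fraction = ", fat_fraction,
                 ", dairy_level = ", dairy_level),
          class = "lactofat_config_error")
  }
  dairy <- dairy_fa_intake(cell$dairy_kcal, profiles, dairy_label, constants)
  other <- nondairy_fa_intake(cell$nondairy_kcal, nondairy_label, constants)
  la_total <- dairy$la_g + other$la_g
  ala_total <- dairy$ala_g + other$ala_g
  if (ala_total <= 0) {
    abort("total ALA is zero: LA/ALA ratio undefined",
          class = "lactofat_domain_error")
  }
  ratio <- la_total / ala_total
  baseline_ratio <- baseline_ratio %||%
    baseline_la_ala_ratio(profiles, constants, allocations)
  tibble::tibble(
    fat_fraction = fat_fraction, dairy_level = dairy_level,
    dairy_profile = dairy_label, nondairy_profile = nondairy_label,
    dairy_kcal = cell$dairy_kcal, nondairy_kcal = cell$nondairy_kcal,
    energy_deficit = cell$energy_deficit,
    la_dairy = dairy$la_g, ala_dairy = dairy$ala_g,
    la_other = other$la_g, ala_other = other$ala_g,
    la_total = la_total, ala_total = ala_total,
    la_ala_ratio = ratio,
    delta_from_baseline = baseline_ratio - ratio
  )
}

#' @rdname evaluate_scenario
#' @description `baseline_la_ala_ratio()` computes (never hard-codes) the
#'   reference ratio: 33% of energy from fat, recommended 3 dairy servings of
#'   conventional milk, typical-LA nondairy fat.
#' @export
baseline_la_ala_ratio <- function(profiles = milk_fa_profiles(),
                                  constants = energy_constants(),
                                  allocations = kcal_allocations(constants)) {
  cell <- allocations[allocations$fat_fraction == 0.33 &
                        allocations$dairy_level == "moderate", ]
  dairy <- dairy_fa_intake(cell$dairy_kcal, profiles, "conventional",
                           constants)
  other <- nondairy_fa_intake(cell$nondairy_kcal, "typical_LA", constants)
  (dairy$la_g + other$la_g) / (dairy$ala_g + other$ala_g)
}

#' The full 36-scenario diet grid
#'
#' Evaluates every combination of 3 fat fractions, 2 dairy levels, 3 dairy
#' profiles and 2 nondairy compositions (36 scenarios) in a deterministic
#' order, with every delta measured against the single computed baseline.
#'
#' @inheritParams evaluate_scenario
#' @param dairy_labels Dairy profile labels (default the three built-in
#'   milks).
#' @param nondairy_labels Nondairy composition labels.
#' @param fat_fractions Fat energy fractions.
#' @param dairy_levels Dairy serving levels.
#' @return A `diet_grid` tibble (36 rows with defaults); the baseline ratio
#'   is stored in the `"baseline_ratio"` attribute.
#' @examples
#' grid <- build_scenario_grid()
#' glance(grid)
#' @export
build_scenario_grid <- function(profiles = milk_fa_profiles(),
                                constants = energy_constants(),
                                dairy_labels = c("conventional", "organic",
                                                 "grassmilk"),
                                nondairy_labels = c("typical_LA", "low_LA"),
                                fat_fractions = c(0.20, 0.33, 0.45),
                                dairy_levels = c("moderate", "high"),
                                allocations = kcal_allocations(constants)) {
  baseline <- baseline_la_ala_ratio(profiles, constants, allocations)
  cells <- tidyr::expand_grid(
    nondairy_profile = nondairy_labels,
    fat_fraction = fat_fractions,
    dairy_level = dairy_levels,
    dairy_profile = dairy_labels
  )
  out <- purrr::pmap(cells, function(nondairy_profile, fat_fraction,
                                     dairy_level, dairy_profile) {
    evaluate_scenario(fat_fraction, dairy_level, dairy_profile,
                      nondairy_profile, profiles, constants,
                      baseline_ratio = baseline,
                      allocations = allocations)
  }) |> dplyr::bind_rows()
  attr(out, "baseline_ratio") <- baseline
  class(out) <- c("diet_grid", class(out))
  out
}

#' @export
tidy.diet_grid <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "diet_grid")
  attr(out, "baseline_ratio") <- NULL
  out
}

#' @export
glance.diet_grid <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x),
    baseline_ratio = attr(x, "baseline_ratio"),
    min_ratio = min(x$la_ala_ratio),
    max_ratio = max(x$la_ala_ratio),
    max_reduction_pct = 100 * max(x$delta_from_baseline) /
      attr(x, "baseline_ratio")
  )
}

#' @export
autoplot.diet_grid <- function(object, ...) {
  df <- tidy(object)
  df$dairy_profile <- factor(df$dairy_profile,
                             levels = unique(df$dairy_profile))
  df$cell <- paste0(100 * df$fat_fraction, "% fat, ", df$dairy_level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell,
                                   y = .data$delta_from_baseline,
                                   fill = .data$dairy_profile)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$nondairy_profile)) +
    ggplot2::labs(x = NULL, y = "Decrease in dietary LA/ALA vs baseline",
                  fill = "Dairy fat") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
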