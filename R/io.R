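# Mapping between on-disk status codes and in-memory status values.
STATUS_TO_DISK <- c(quantified = "Q", below_lod = "LOD", missing = "NA")
STATUS_FROM_DISK <- setNames(names(STATUS_TO_DISK), STATUS_TO_DISK)

#' Read and write panel CSV files
#'
#' The panel CSV dialect is wide: one row per sample with metadata columns
#' `sample_id, farm_id, region, year, month, fat_pct, total_fa`, then one
#' column pair per fatty acid — `<code>` (numeric, empty when not
#' quantified) and `<code>_status` (`Q`, `LOD` or `NA`). Writing then
#' reading a panel is the identity; numbers are serialised at full
#' precision.
#'
#' `read_panel()` validates the schema (missing required columns are listed
#' by name) and every row: unknown status codes and quantified values below
#' the LOD are schema errors reporting the offending data rows. An empty
#' file with a valid header yields an empty panel with a warning.
#'
#' @param path File path.
#' @param lod Quantification limit used for validation.
#' @return `read_panel()`: a long panel tibble; `write_panel()`: `path`,
#'   invisibly.
#' @examples
#' p <- generate_panel(synthetic_config(seed = 1))$panel
#' f <- tempfile(fileext = ".csv")
#' write_panel(p, f)
#' identical(read_panel(f), p)
#' @export
read_panel <- function(path, lod = LOD_DEFAULT) {
  wide <- readr::read_csv(path, show_col_types = FALSE,
                          na = character(),
                          col_types = readr::cols(.default = "c"))
  meta <- c("sample_id", "farm_id", "region", "year", "month",
            "fat_pct", "total_fa")
  missing_cols <- setdiff(meta, names(wide))
  if (length(missing_cols) > 0) {
    abort(paste0("panel file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "lactofat_schema_error")
  }
  status_cols <- grep("_status$", names(wide), value = TRUE)
  codes <- sub("_status$", "", status_cols)
  no_value <- codes[!codes %in% names(wide)]
  if (length(no_value) > 0) {
    abort(paste0("status column(s) without a value column: ",
                 paste(no_value, collapse = ", ")),
          class = "lactofat_schema_error")
  }
  if (nrow(wide) == 0) {
    warn("panel file has a header but no rows")
    return(tibble::tibble(
      sample_id = character(), farm_id = character(), region = character(),
      year = integer(), month = integer(), fat_pct = double(),
      total_fa = double(), code = character(), value = double(),
      status = character()))
  }
  wide <- dplyr::mutate(wide, .row = dplyr::row_number())
  long_val <- wide |>
    dplyr::select(dplyr::all_of(c(meta, ".row")), dplyr::all_of(codes)) |>
    tidyr::pivot_longer(dplyr::all_of(codes), names_to = "code",
                        values_to = "value_chr")
  long_st <- wide |>
    dplyr::select(".row", dplyr::all_of(status_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(status_cols), names_to = "code",
                        values_to = "status_chr") |>
    dplyr::mutate(code = sub("_status$", "", .data$code))
  long <- dplyr::left_join(long_val, long_st, by = c(".row", "code"))
  bad_status <- long$.row[!long$status_chr %in% names(STATUS_FROM_DISK)]
  if (length(bad_status) > 0) {
    abort(paste0("malformed status in data row(s): ",
                 paste(sort(unique(bad_status)), collapse = ", ")),
          class = "lactofat_schema_error")
  }
  out <- long |>
    dplyr::mutate(
      status = unname(STATUS_FROM_DISK[.data$status_chr]),
      value = suppressWarnings(as.numeric(.data$value_chr)),
      year = as.integer(.data$year), month = as.integer(.data$month),
      fat_pct = as.numeric(.data$fat_pct),
      total_fa = as.numeric(.data$total_fa)
    )
  below <- out$.row[out$status == "quantified" &
                      (is.na(out$value) | out$value < lod)]
  if (length(below) > 0) {
    abort(paste0("quantified value missing or below LOD in data row(s): ",
                 paste(sort(unique(below)), collapse = ", ")),
          class = "lactofat_schema_error")
  }
  out |>
    dplyr::select("sample_id", "farm_id", "region", "year", "month",
                  "fat_pct", "total_fa", "code", "value", "status")
}

#' @rdname read_panel
#' @param panel A long panel tibble.
#' @export
write_panel <- function(panel, path) {
  check_panel(panel)
  wide <- panel |>
    dplyr::mutate(status = unname(STATUS_TO_DISK[.data$status])) |>
    tidyr::pivot_wider(names_from = "code",
                       values_from = c("value", "status"),
                       names_glue = "{code}{ifelse(.value == 'status', '_status', '')}")
  code_order <- unique(panel$code)
  cols <- c("sample_id", "farm_id", "region", "year", "month",
            "fat_pct", "total_fa",
            as.vector(rbind(code_order, paste0(code_order, "_status"))))
  readr::write_csv(wide[, cols], path, na = "")
  invisible(path)
}

#' @rdname read_panel
#' @description `read_fa_registry()` reads a registry CSV with columns
#'   `code, shorthand, family` and validates it.
#' @export
read_fa_registry <- function(path) {
  reg <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  validate_fa_registry(reg)
  tibble::as_tibble(reg)
}

#' @rdname read_panel
#' @description `read_profiles()` / `write_profiles()` round-trip long
#'   profile tables (`label, item, amount, n, sd, frac_quantified`).
#' @export
read_profiles <- function(path) {
  prof <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            label = "c", item = "c", .default = "d"))
  required <- c("label", "item", "amount")
  missing_cols <- setdiff(required, names(prof))
  if (length(missing_cols) > 0) {
    abort(paste0("profile file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "lactofat_schema_error")
  }
  for (col in c("n", "sd", "frac_quantified")) {
    if (!col %in% names(prof)) prof[[col]] <- NA_real_
  }
  prof
}

#' @rdname read_panel
#' @param profiles A long profile table.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_csv(profiles, path, na = "")
  invisible(path)
}

#' Pipeline configuration and runner
#'
#' `run_pipeline()` executes the whole analysis chain — synthetic panel (or
#' a panel read from disk), censoring-aware summaries, fat-standardised
#' comparison table, 36-scenario diet grid, servings-versus-fish calculator
#' — and writes one CSV per stage plus a JSON manifest into `out_dir`. All
#' outputs are deterministic functions of the configuration (including the
#' seed): rerunning with the same config reproduces identical files and an
#' identical manifest hash. Progress is logged to stderr; results never mix
#' with logs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the synthetic panel.
#' @param dairy_profile Milk profile label for the diet and servings stages.
#' @param panel_path Optional path to an existing panel CSV; when `NULL` a
#'   synthetic panel is generated.
#' @param synthetic Named list of overrides passed to [synthetic_config()].
#' @param per_capita Named vector with `dairy_g` and `fish_g` daily weights.
#' @return `pipeline_config()`: a config list. `run_pipeline()`: the
#'   manifest, invisibly.
#' @examples
#' cfg <- pipeline_config(out_dir = tempfile(), seed = 1)
#' man <- run_pipeline(cfg)
#' man$row_counts
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            dairy_profile = "grassmilk",
                            panel_path = NULL,
                            synthetic = list(),
                            per_capita = per_capita_intakes()) {
  list(out_dir = out_dir, seed = as.integer(seed),
       dairy_profile = dairy_profile, panel_path = panel_path,
       synthetic = synthetic, per_capita = per_capita)
}

#' @rdname pipeline_config
#' @param config A config list from [pipeline_config()] or the path of a
#'   YAML file holding the same fields.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    config$per_capita <- unlist(config$per_capita) %||% per_capita_intakes()
  }
  profiles <- milk_fa_profiles()
  if (!config$dairy_profile %in% unique(profiles$label)) {
    abort(paste0("unknown dairy profile label '", config$dairy_profile, "'"),
          class = "lactofat_config_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[lactofat] stage ", name)
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            class = "lactofat_pipeline_error", parent = e)
    })
  }

  panel <- stage("panel", {
    if (is.null(config$panel_path)) {
      cfg <- do.call(synthetic_config,
                     c(list(seed = config$seed), config$synthetic))
      sim <- generate_panel(cfg)
      write_panel(sim$panel, file.path(config$out_dir, "panel.csv"))
      sim$panel
    } else {
      read_panel(config$panel_path)
    }
  })

  fa_summary <- stage("summarize", {
    s <- dplyr::bind_rows(summarize_fa(panel),
                          summarize_fa(panel, unit = "pct_of_total_fa"))
    readr::write_csv(s, file.path(config$out_dir, "fa_summary.csv"), na = "")
    s
  })

  comparison <- stage("compare", {
    profs <- dplyr::bind_rows(profiles,
                              adjust_total_fa(profiles, "grassmilk"))
    cmp <- build_comparison_table(
      profs,
      pairs = list(c("conventional", "grassmilk_adjusted"),
                   c("organic", "grassmilk_adjusted")),
      items = setdiff(unique(profiles$item), RATIO_ITEMS))
    readr::write_csv(tidy(cmp), file.path(config$out_dir, "comparison.csv"),
                     na = "")
    cmp
  })

  grid <- stage("diet_grid", {
    g <- build_scenario_grid(profiles)
    readr::write_csv(tidy(g), file.path(config$out_dir, "diet_grid.csv"),
                     na = "")
    g
  })

  servings_tbl <- stage("servings", {
    per_food <- serving_fa_content(dairy_servings(), profiles,
                                   config$dairy_profile)
    totals <- daily_totals(dairy_servings(), profiles, config$dairy_profile)
    dairy_pc <- scale_per_capita(totals, config$per_capita[["dairy_g"]])
    fish <- fish_intake_row()
    fish_pc <- scale_per_capita(fish, config$per_capita[["fish_g"]])
    tbl <- dplyr::bind_rows(per_food, totals, dairy_pc, fish, fish_pc)
    readr::write_csv(tbl, file.path(config$out_dir, "servings.csv"),
                     na = "")
    tbl
  })

  manifest <- list(
    package = "lactofat",
    version = as.character(utils::packageVersion("lactofat")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    row_counts = list(
      panel = nrow(panel), fa_summary = nrow(fa_summary),
      comparison = nrow(comparison), diet_grid = nrow(grid),
      servings = nrow(servings_tbl))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Seasonal means plot
#'
#' Line plot of monthly group means with standard-error ribbons, one line
#' per region/year group if present.
#'
#' @param monthly A means table from [monthly_regional_means()] containing a
#'   `month` column.
#' @return A ggplot object.
#' @export
plot_seasonal_means <- function(monthly) {
  if (!"month" %in% names(monthly)) {
    abort("'monthly' must contain a month column",
          class = "lactofat_domain_error")
  }
  extra <- intersect(c("region", "year"), names(monthly))
  df <- monthly
  df$grp <- if (length(extra)) {
    interaction(df[extra], drop = TRUE)
  } else {
    factor("all")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$mean,
                                   colour = .data$grp, group = .data$grp)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se,
                                      fill = .data$grp),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(x = "Month", colour = NULL, fill = NULL,
                  y = paste0("Mean ", attr(monthly, "code") %||% "value")) +
    ggplot2::theme_minimal()
}
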