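test_that("generation is a pure function of config and seed", {
  cfg <- synthetic_config(seed = 42)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$calibration, b$truth$calibration)
  # byte-identical CSV round
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_panel(a$panel, fa); write_panel(b$panel, fb)
  expect_identical(readLines(fa), readLines(fb))
  # a different seed changes the draw
  c2 <- generate_panel(synthetic_config(seed = 43))
  expect_false(identical(a$panel$value, c2$panel$value))
})

test_that("the default design matches the emulated study structure", {
  sim <- generate_panel(synthetic_config(seed = 1))
  p <- sim$panel
  samples <- dplyr::distinct(p, sample_id, region, farm_id, year, month)
  expect_equal(nrow(samples), 1166)  # ~1,163 bulk-tank samples
  expect_equal(dplyr::n_distinct(samples$farm_id), 34)
  expect_setequal(unique(samples$region),
                  c("California", "Mideast", "Midwest", "Northeast"))
  # the Mideast enters in June 2016 only
  me <- samples[samples$region == "Mideast", ]
  expect_true(all(me$year == 2016 & me$month >= 6))
})

test_that("no quantified value sits below the quantification limit", {
  sim <- generate_panel(synthetic_config(seed = 2))
  q <- sim$panel[sim$panel$status == "quantified", ]
  expect_true(all(q$value >= 0.001))
  b <- sim$panel[sim$panel$status == "below_lod", ]
  expect_true(all(is.na(b$value)))
  expect_gt(nrow(b), 0)
})

test_that("a noiseless configuration reproduces the target means exactly", {
  fa <- tibble::tibble(code = c("ala", "la"), mean = c(0.0441, 0.0447),
                       cv_pct = 0, amplitude = 0, peak_month = NA)
  offs <- dplyr::mutate(default_region_offsets(), omega3 = 0, omega6 = 0)
  cfg <- synthetic_config(seed = 9, fa_params = fa, region_offsets = offs,
                          outlier_rate = 0)
  sim <- generate_panel(cfg)
  expect_equal(unique(sim$panel$value[sim$panel$code == "ala"]), 0.0441)
  expect_equal(unique(sim$panel$value[sim$panel$code == "la"]), 0.0447)
})

test_that("heavily censored acids censor at the configured rate", {
  sim <- generate_panel(synthetic_config(seed = 4))
  s <- summarize_fa(sim$panel, "dha")
  n_total <- dplyr::n_distinct(sim$panel$sample_id)
  frac <- s$n / n_total
  # oracle: lognormal cdf at the LOD under the generating parameters
  expected <- sim$truth$calibration$expected_quantified_frac[
    sim$truth$calibration$code == "dha"]
  expect_equal(frac, expected, tolerance = 0.05 / expected)
  # the study quantified ~21% of DHA measurements
  expect_lt(abs(frac - 0.21), 0.05)
  # and the quantified-only mean is elevated above the latent mean
  expect_gt(s$mean, 0.00077)
})

test_that("panel means are unbiased for the generating means over seeds", {
  errs <- purrr::map_dbl(1:20, function(s) {
    sim <- generate_panel(synthetic_config(seed = s, outlier_rate = 0))
    summarize_fa(sim$panel, "ala")$mean - 0.04409
  })
  se20 <- sd(errs) / sqrt(20)
  expect_lt(abs(mean(errs)), 2 * se20)
})

test_that("recovery report checks means, seasonality and regions", {
  sim <- generate_panel(synthetic_config(seed = 1))
  rep <- recovery_report(sim$panel, sim$truth)
  expect_setequal(unique(rep$check),
                  c("annual_mean", "seasonal_peak_month",
                    "seasonal_high_low_ratio", "omega3_region_structure"))
  headline <- rep[rep$code %in% c("ala", "la", "epa", "dpa", "cla"), ]
  expect_true(all(headline$pass))
  expect_true(rep$pass[rep$check == "omega3_region_structure"])

  # CLA seasonality: September peak, high/low ratio near 2.05
  cla_peak <- rep[rep$check == "seasonal_peak_month" & rep$code == "cla", ]
  expect_equal(cla_peak$estimated, 9)
  cla_ratio <- rep[rep$check == "seasonal_high_low_ratio" &
                     rep$code == "cla", ]
  expect_equal(cla_ratio$estimated, 2.05, tolerance = 0.1)

  # a flat seasonal signal is recovered as a ratio near one
  fa_flat <- tibble::tibble(code = "cla", mean = 0.0498, cv_pct = 10,
                            amplitude = 0, peak_month = NA)
  flat <- generate_panel(synthetic_config(seed = 5, fa_params = fa_flat,
                                          outlier_rate = 0))
  hl <- high_low_months(monthly_regional_means(flat$panel, "cla", "month"))
  expect_equal(hl$ratio, 1, tolerance = 0.05)

  # mismatched panel/truth pairs are refused
  other <- generate_panel(synthetic_config(seed = 6,
                                           n_farms = c(Midwest = 2)))
  expect_error(recovery_report(other$panel, sim$truth),
               class = "lactofat_domain_error")
})

test_that("injected outliers are high-side and screenable", {
  cfg <- synthetic_config(seed = 8, outlier_rate = 0.002)
  sim <- generate_panel(cfg)
  expect_gt(nrow(sim$truth$outliers), 0)
  # screening the affected, well-quantified acids recovers most of them
  cal <- sim$truth$calibration
  good <- cal$code[cal$expected_quantified_frac > 0.99]
  out_good <- dplyr::semi_join(sim$truth$outliers,
                               tibble::tibble(code = good), by = "code")
  scr <- screen_outliers(sim$panel, unique(out_good$code))
  found <- dplyr::inner_join(scr$flagged, out_good,
                             by = c("sample_id", "code"))
  expect_gte(nrow(found), 0.8 * nrow(out_good))
})
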