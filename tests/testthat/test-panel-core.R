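test_that("group sums handle quantified, censored and missing members", {
  # single representative sample carrying the study-table omega-3 means
  p <- toy_panel(purrr::map(as.list(OMEGA3_TABLE_MEANS), \(v) v))
  s <- sum_fa_group(p, names(OMEGA3_TABLE_MEANS))
  expect_equal(s$total, sum(OMEGA3_TABLE_MEANS))
  expect_equal(s$total, 0.059633, tolerance = 1e-6)
  expect_equal(s$n_quantified, 7)

  # all members censored: zero under the zero policy, 7 * LOD/2 otherwise
  p0 <- toy_panel(purrr::map(as.list(OMEGA3_TABLE_MEANS), \(v) NA_real_))
  expect_equal(sum_fa_group(p0, names(OMEGA3_TABLE_MEANS))$total, 0)
  expect_equal(
    sum_fa_group(p0, names(OMEGA3_TABLE_MEANS), lod_policy = "half_lod")$total,
    7 * 0.0005)

  # three-member toy group, half-LOD policy: 0.010 + 0.0005 + 0.002
  p3 <- toy_panel(list(ala = 0.010, epa = NA_real_, dpa = 0.002))
  expect_equal(sum_fa_group(p3, c("ala", "epa", "dpa"),
                            lod_policy = "half_lod")$total, 0.0125)

  # a member absent from the panel is reported missing, contributes zero
  s_miss <- sum_fa_group(p3, c("ala", "epa", "dpa", "dha"))
  expect_equal(s_miss$n_missing, 1)
  expect_equal(s_miss$total, 0.012)

  expect_error(sum_fa_group(p3, c("ala", "nonsense")),
               class = "lactofat_key_error")
})

test_that("ratio triple follows the definitions and names bad denominators", {
  r <- compute_fa_ratios(0.0525, 0.0565, 0.0447, 0.0441)
  expect_equal(r$la_ala, 0.0447 / 0.0441)
  expect_equal(r$la_ala, 1.0136, tolerance = 1e-4)
  expect_equal(compute_fa_ratios(0.05, 0.05, 0.04, 0.04)$w6_w3, 1)
  expect_equal(compute_fa_ratios(0.05, 0.05, 0.04, 0.04)$w3_w6, 1)
  r2 <- compute_fa_ratios(0.06, 0.04, 0.05, 0.05)
  expect_equal(r2$w6_w3, 1.5)
  expect_equal(r2$w3_w6, 2 / 3)
  expect_error(compute_fa_ratios(0.06, 0.04, 0.05, 0), "la_ala",
               class = "lactofat_domain_error")
  expect_error(compute_fa_ratios(0.06, 0, 0.05, 0.04), "w6_w3",
               class = "lactofat_domain_error")

  # reciprocal pair multiplies to one exactly, whatever the inputs
  set.seed(11)
  w6 <- runif(200, 0.01, 0.2); w3 <- runif(200, 0.01, 0.2)
  rr <- compute_fa_ratios(w6, w3, w6, w3)
  expect_equal(rr$w6_w3 * rr$w3_w6, rep(1, 200))
})

test_that("panel summaries use the quantified-only convention", {
  p <- toy_panel(list(ala = c(0.04, 0.05, 0.06)))
  s <- summarize_fa(p, "ala")
  expect_equal(s$mean, 0.05)
  expect_equal(s$sd, 0.01)
  expect_equal(s$cv, 20)
  expect_equal(s$se, 0.01 / sqrt(3))

  # censored samples reduce n and never enter the mean
  p2 <- toy_panel(list(dha = c(NA, NA, 0.002)))
  s2 <- summarize_fa(p2, "dha")
  expect_equal(s2$n, 1)
  expect_equal(s2$mean, 0.002)

  # zero quantified observations: explicit NA result, not a silent zero
  p3 <- toy_panel(list(dha = c(NA_real_, NA_real_)))
  s3 <- summarize_fa(p3, "dha")
  expect_equal(s3$n, 0)
  expect_true(is.na(s3$mean))

  # percent-of-total divides by each sample's own total
  p4 <- toy_panel(list(ala = c(0.04, 0.05)), total_fa = c(4, 5))
  s4 <- summarize_fa(p4, "ala", unit = "pct_of_total_fa")
  expect_equal(s4$mean, 1)

  expect_error(summarize_fa(p[0, ]), class = "lactofat_domain_error")
  expect_error(summarize_fa(p, "not_a_code"), class = "lactofat_key_error")
})

test_that("summaries agree with a loop-based oracle on random panels", {
  set.seed(202)
  for (i in 1:5) {
    n <- sample(20:1000, 1)
    vals <- exp(rnorm(n, log(0.04), 0.3))
    vals[runif(n) < 0.15] <- NA  # censored
    p <- toy_panel(list(ala = vals), total_fa = runif(n, 3, 4))
    for (unit in c("g_per_100g", "pct_of_total_fa")) {
      got <- summarize_fa(p, "ala", unit = unit)
      want <- oracle_summary(p, "ala", unit)
      expect_equal(got$mean, want$mean)
      expect_equal(got$n, want$n)
      expect_equal(got$sd, want$sd)
      expect_equal(got$cv, want$cv)
      expect_equal(got$se, want$se)
    }
  }
})

test_that("censored-mean estimator reconstitutes the all-sample mean", {
  # the study's DHA case: 249 of 1162 quantified at mean 0.00106
  est <- estimate_censored_mean(1162, 249, 0.00106, imputed_value = 0.0005)
  expect_equal(est, (249 * 0.00106 + 913 * 0.0005) / 1162)
  expect_equal(round(est, 4), 6e-4)

  expect_equal(estimate_censored_mean(100, 100, 0.002), 0.002)
  expect_equal(estimate_censored_mean(100, 0, NaN, imputed_value = 4e-4),
               4e-4)
  expect_error(estimate_censored_mean(0, 0, 1), class = "lactofat_domain_error")
  expect_error(estimate_censored_mean(10, 11, 1), class = "lactofat_domain_error")
  expect_error(estimate_censored_mean(10, 5, 0.002, imputed_value = 0.002),
               class = "lactofat_domain_error")

  # censoring monotonicity: quantified-only mean dominates the estimate
  # whenever the imputed value sits below the quantified mean
  set.seed(7)
  for (i in 1:20) {
    nt <- sample(10:2000, 1); nq <- sample(1:nt, 1)
    mq <- runif(1, 0.0011, 0.01)
    expect_lte(estimate_censored_mean(nt, nq, mq), mq)
  }
})

test_that("high-fence screening flags severe outliers and is idempotent", {
  # mirrors the study's removed trans-18:3 = 0.075 observation
  p <- toy_panel(list(`t18:2` = c(0.001, 0.0012, 0.0011, 0.0013, 0.075)))
  scr <- screen_outliers(p, "t18:2")
  expect_equal(scr$flagged$value, 0.075)
  expect_equal(scr$flagged$sample_id, "T005")
  cleaned <- scr$panel
  expect_equal(cleaned$status[cleaned$sample_id == "T005"], "missing")
  # input panel untouched
  expect_equal(p$status[p$sample_id == "T005"], "quantified")
  # idempotence: re-screening the cleaned panel flags nothing
  expect_equal(nrow(screen_outliers(cleaned, "t18:2")$flagged), 0)

  # identical values: zero IQR, no flags
  pid <- toy_panel(list(ala = rep(0.04, 6)))
  expect_equal(nrow(screen_outliers(pid, "ala")$flagged), 0)

  # brute-force fence check: normal draws plus a spike at mean + 10 sd
  set.seed(99)
  x <- rnorm(100, 10, 1)
  xx <- c(x, 10 + 10 * 1)
  pn <- toy_panel(list(ala = xx), total_fa = 50)
  got <- screen_outliers(pn, "ala", k = 1.5)
  q <- quantile(xx, c(0.25, 0.75), names = FALSE)
  brute <- which(xx > q[2] + 1.5 * (q[2] - q[1]))
  expect_true(sprintf("T%03d", 101) %in% got$flagged$sample_id)
  expect_setequal(got$flagged$sample_id, sprintf("T%03d", brute))

  # too few quantified observations: refuses, records, leaves panel intact
  p4 <- toy_panel(list(ala = c(0.04, 0.05, 0.06)))
  scr4 <- screen_outliers(p4, "ala")
  expect_equal(nrow(scr4$skipped), 1)
  expect_identical(scr4$panel, p4)

  expect_error(screen_outliers(p, "t18:2", k = 0),
               class = "lactofat_domain_error")
})

test_that("grouped means and the seasonal high/low summary are correct", {
  # two months with means 0.06 and 0.03: ratio 2
  p <- toy_panel(list(cla = c(0.05, 0.07, 0.02, 0.04)),
                 month = c(9, 9, 4, 4))
  m <- monthly_regional_means(p, "cla", "month")
  expect_equal(sort(m$mean), c(0.03, 0.06))
  hl <- high_low_months(m)
  expect_equal(hl$ratio, 2)
  expect_equal(hl$high_month, 9)
  expect_equal(hl$low_month, 4)

  # single month: one group, ratio 1
  p1 <- toy_panel(list(cla = c(0.05, 0.06)), month = 7)
  hl1 <- high_low_months(monthly_regional_means(p1, "cla", "month"))
  expect_equal(hl1$ratio, 1)

  # a group with no quantified values is omitted and reported
  p2 <- toy_panel(list(cla = c(0.05, NA)), month = c(1, 2))
  m2 <- monthly_regional_means(p2, "cla", "month")
  expect_equal(nrow(m2), 1)
  expect_equal(attr(m2, "dropped_groups")$month, 2)
})

test_that("percent-of-total closure holds on a full synthetic sample", {
  sim <- generate_panel(synthetic_config(seed = 3, outlier_rate = 0))
  pct <- summarize_fa(sim$panel, unit = "pct_of_total_fa")
  # per-sample: quantified percentages must sum to ~100 (censored minors
  # account for the small gap)
  per_sample <- sim$panel |>
    dplyr::filter(.data$status == "quantified") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(tot = sum(100 * .data$value / .data$total_fa))
  expect_true(all(abs(per_sample$tot - 100) < 0.2))
})
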