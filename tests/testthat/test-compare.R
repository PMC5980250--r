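test_that("fat standardisation rescales amounts and preserves ratios", {
  profs <- milk_fa_profiles()
  adj <- adjust_total_fa(profs, "grassmilk")  # target = mean(3.098, 3.108)
  expect_equal(adj$amount[adj$item == "total_fa"], 3.103)
  expect_equal(adj$amount[adj$item == "omega3_total"],
               0.0565 * 3.103 / 3.585)
  expect_equal(round(adj$amount[adj$item == "omega3_total"], 4), 0.0489)
  # carried panel ratios unchanged in the adjusted column
  expect_equal(adj$amount[adj$item == "la_ala"], 1.042)
  expect_equal(adj$amount[adj$item == "w6_w3"], 0.954)

  # adjusting to the profile's own total is the identity
  same <- adjust_total_fa(profs, "grassmilk", target_total = 3.585)
  expect_equal(same$amount, profs$amount[profs$label == "grassmilk"])

  # toy linear scaling halves amounts, leaves computed LA/ALA at 1
  toy <- tibble::tibble(label = "toy",
                        item = c("total_fa", "la", "ala"),
                        amount = c(4, 0.04, 0.04),
                        n = NA_real_, sd = NA_real_,
                        frac_quantified = NA_real_)
  tadj <- adjust_total_fa(toy, "toy", target_total = 2)
  expect_equal(tadj$amount[tadj$item == "la"], 0.02)
  expect_equal(tadj$amount[tadj$item == "la"] /
                 tadj$amount[tadj$item == "ala"], 1)

  expect_error(adjust_total_fa(profs, "no_such_milk"),
               class = "lactofat_key_error")
  expect_error(adjust_total_fa(toy, "toy", target_total = -1),
               class = "lactofat_domain_error")
})

test_that("scale invariance of ratios holds for arbitrary targets", {
  profs <- milk_fa_profiles()
  set.seed(5)
  for (target in runif(10, 0.5, 8)) {
    adj <- adjust_total_fa(profs, "grassmilk", target_total = target)
    for (lbl_pair in list(c("la", "ala"), c("omega6_total", "omega3_total"))) {
      before <- profile_ratio(profs, "grassmilk", lbl_pair)
      after <- profile_ratio(adj, "grassmilk_adjusted", lbl_pair)
      expect_equal(after, before)
    }
  }
})

test_that("percent differences match the comparison-table conventions", {
  expect_equal(round(percent_difference(0.0198, 0.0489)), 147)
  expect_equal(percent_difference(0.0856, 0.0387),
               100 * (0.0387 - 0.0856) / 0.0856)
  expect_equal(format_pct_diff(percent_difference(0.0856, 0.0387)), -55)
  expect_equal(percent_difference(3, 3), 0)
  # display rounding: one decimal below 10 in magnitude, integer above
  expect_equal(format_pct_diff(c(8.34, -9.96, 12.6, -54.79)),
               c(8.3, -10, 13, -55))
  expect_error(percent_difference(0, 1), class = "lactofat_domain_error")

  # antisymmetry: (1 + d1/100)(1 + d2/100) = 1
  set.seed(21)
  a <- runif(50, 0.01, 2); b <- runif(50, 0.01, 2)
  d1 <- percent_difference(a, b); d2 <- percent_difference(b, a)
  expect_equal((1 + d1 / 100) * (1 + d2 / 100), rep(1, 50))
})

test_that("summary-statistic Welch test matches t.test on real vectors", {
  ht <- welch_t_from_summary(10, 2, 16, 12, 2, 16)
  expect_equal(unname(ht$statistic), -2.8284271, tolerance = 1e-6)
  expect_equal(unname(ht$parameter), 30)
  expect_equal(ht$p.value, 0.0083, tolerance = 1e-2)

  # equal means: t = 0, p = 1
  ht0 <- welch_t_from_summary(5, 1, 10, 5, 2, 12)
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)

  # oracle: construct vectors with exactly the requested summaries and
  # compare against stats::t.test
  make_vec <- function(m, s, n) {
    z <- scale(rnorm(n))  # mean 0, sd 1 exactly
    m + s * as.numeric(z)
  }
  set.seed(31)
  for (i in 1:5) {
    m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5)
    s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    x <- make_vec(m1, s1, n1); y <- make_vec(m2, s2, n2)
    ref <- stats::t.test(x, y)
    got <- welch_t_from_summary(mean(x), sd(x), n1, mean(y), sd(y), n2)
    expect_equal(unname(got$statistic), unname(ref$statistic))
    expect_equal(unname(got$parameter), unname(ref$parameter))
    expect_equal(got$p.value, ref$p.value)
  }

  # with equal sds and ns, Welch reduces to Student's t
  x <- make_vec(1, 1.5, 12); y <- make_vec(2, 1.5, 12)
  got <- welch_t_from_summary(mean(x), sd(x), 12, mean(y), sd(y), 12)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(unname(got$statistic), unname(ref$statistic))
  expect_equal(unname(got$parameter), 22)

  # the conventional-vs-grassmilk omega-3 contrast is overwhelming at any
  # plausible spread for the conventional panel
  p <- welch_t_from_summary(0.0198, 0.006, 160,
                            0.0489, 0.013, 1161)$p.value
  expect_lt(p, 1e-5)

  expect_error(welch_t_from_summary(1, 0, 5, 2, 0, 5),
               class = "lactofat_domain_error")
  expect_error(welch_t_from_summary(1, 1, 1, 2, 1, 5),
               class = "lactofat_domain_error")
})

test_that("comparison table reproduces the milk-type contrasts", {
  profs <- dplyr::bind_rows(milk_fa_profiles(),
                            adjust_total_fa(milk_fa_profiles(), "grassmilk"))
  items <- c("omega3_total", "cla", "la", "dha")
  tab <- build_comparison_table(
    profs,
    pairs = list(c("conventional", "grassmilk_adjusted"),
                 c("organic", "grassmilk_adjusted")),
    items = items)
  conv <- tab[tab$reference == "conventional", ]
  expect_equal(conv$pct_diff_display[conv$item == "omega3_total"], 147)
  expect_equal(conv$pct_diff_display[conv$item == "cla"], 125)
  expect_equal(conv$pct_diff_display[conv$item == "la"], -55)
  org <- tab[tab$reference == "organic", ]
  expect_equal(org$pct_diff_display[org$item == "omega3_total"], 52)

  # DHA suppressed: both retail panels quantified DHA in < 5% of samples
  expect_true(all(tab$suppressed[tab$item == "dha"]))
  expect_true(all(is.na(tab$pct_diff[tab$item == "dha"])))

  # deterministic row order follows the item list, pair by pair
  expect_equal(tab$item, rep(items, 2))

  # Welch columns populated where both sides carry n and sd
  expect_true(all(is.na(conv$p_value[!conv$suppressed])))  # conv has no sd
  gg <- build_comparison_table(profs, list(c("grassmilk",
                                             "grassmilk_adjusted")),
                               items = "ala")
  expect_false(is.na(gg$p_value))

  expect_equal(nrow(build_comparison_table(profs,
                                           list(c("organic", "grassmilk")),
                                           items = character())), 0)
  expect_error(build_comparison_table(profs, list(c("organic", "oatmilk")),
                                      items = "ala"),
               class = "lactofat_key_error")

  # broom-style accessors
  g <- glance(tab)
  expect_equal(g$n_rows, 8)
  expect_equal(g$n_suppressed, 2)
  expect_s3_class(autoplot(tab), "ggplot")
})
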