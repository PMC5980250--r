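# Items in a profile table that are ratios of amounts: invariant under
# linear rescaling of the profile, so fat standardisation carries them over.
RATIO_ITEMS <- c("la_ala", "w6_w3", "w3_w6")

#' Fat-standardise a milk profile
#'
#' Linearly rescales every amount of one profile so that its total fatty-acid
#' content equals a target, making cross-milk comparisons fat-basis-neutral.
#' By default the target is the mean total of the reference profiles (the
#' convention used when comparing raw grass-fed milk, ~3.6% fatty acids,
#' against retail milks standardised near 3.1%). Ratio items and quantified
#' fractions are carried unchanged — rescaling cannot alter a ratio — and
#' standard deviations scale with the amounts.
#'
#' @param profiles A long profile table, see [milk_fa_profiles()].
#' @param label Label of the profile to adjust.
#' @param target_total Target total fatty acids, g/100 g milk. Default: mean
#'   `total_fa` of `reference_labels`.
#' @param reference_labels Labels whose mean total defines the default
#'   target; default all labels other than `label`.
#' @param new_label Label for the adjusted profile.
#' @return A long tibble holding only the adjusted profile's rows.
#' @examples
#' adjust_total_fa(milk_fa_profiles(), "grassmilk")
#' @export
adjust_total_fa <- function(profiles, label, target_total = NULL,
                            reference_labels = NULL,
                            new_label = paste0(label, "_adjusted")) {
  prof <- profiles[profiles$label == label, ]
  if (nrow(prof) == 0) {
    abort(paste0("unknown profile label '", label, "'"),
          class = "lactofat_key_error")
  }
  own_total <- profile_amount(profiles, label, "total_fa")
  if (is.null(target_total)) {
    reference_labels <- reference_labels %||%
      setdiff(unique(profiles$label), label)
    totals <- purrr::map_dbl(reference_labels,
                             \(l) profile_amount(profiles, l, "total_fa"))
    target_total <- mean(totals)
  }
  if (!is.finite(own_total) || own_total <= 0 || target_total <= 0) {
    abort("profile totals must be positive", class = "lactofat_domain_error")
  }
  scale <- target_total / own_total
  prof |>
    dplyr::mutate(
      is_ratio = .data$item %in% RATIO_ITEMS,
      amount = dplyr::if_else(.data$is_ratio, .data$amount,
                              .data$amount * scale),
      sd = dplyr::if_else(.data$is_ratio, .data$sd, .data$sd * scale),
      label = new_label
    ) |>
    dplyr::select(-"is_ratio")
}

#' Percent difference relative to a reference
#'
#' `100 * (comparison - reference) / reference`, vectorised. Raw values are
#' returned at full precision; [format_pct_diff()] applies the conventional
#' mixed display precision (one decimal below 10 in magnitude, integer
#' above).
#'
#' @param reference,comparison Numeric vectors; `reference` must be nonzero.
#' @return Percent difference(s).
#' @examples
#' percent_difference(0.0198, 0.0489)
#' format_pct_diff(percent_difference(0.0198, 0.0489))
#' @export
percent_difference <- function(reference, comparison) {
  if (any(reference == 0, na.rm = TRUE)) {
    abort("reference value of zero: percent difference undefined",
          class = "lactofat_domain_error")
  }
  100 * (comparison - reference) / reference
}

#' @rdname percent_difference
#' @param x Percent differences to format.
#' @export
format_pct_diff <- function(x) {
  dplyr::if_else(abs(x) >= 10, round(x), round(x, 1))
}

#' Welch's two-sample t test from summary statistics
#'
#' Unequal-variance t test computed from means, standard deviations and
#' counts (the raw observations being unavailable), with Welch-Satterthwaite
#' degrees of freedom and a two-tailed p value.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return An object of class `"htest"` (so `broom::tidy()` applies), with
#'   `statistic`, `parameter` (df) and `p.value`.
#' @examples
#' welch_t_from_summary(10, 2, 16, 12, 2, 16)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(n1, n2) < 2)) {
    abort("both groups need n >= 2", class = "lactofat_domain_error")
  }
  if (any(c(sd1, sd2) < 0) || (sd1 == 0 && sd2 == 0)) {
    abort("standard deviations must be >= 0 and not both zero",
          class = "lactofat_domain_error")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(
    list(
      statistic = c(t = tstat),
      parameter = c(df = df),
      p.value = p,
      estimate = c(mean1 = mean1, mean2 = mean2),
      method = "Welch two-sample t test from summary statistics",
      alternative = "two.sided",
      data.name = "summary statistics"
    ),
    class = "htest"
  )
}

#' Pairwise milk-type comparison table
#'
#' Builds the fat-standardised comparison table: for each requested pair of
#' profile labels and each item, the two amounts, their percent difference
#' (raw and display-rounded), and — where both profiles carry summary `n` and
#' `sd` — a Welch t test. Items whose quantified fraction falls below
#' `min_frac_quantified` on either side are reported with a suppressed
#' difference (`suppressed = TRUE`, `NA` percent difference), mirroring the
#' refusal to compare means of almost entirely censored acids.
#'
#' @inheritParams adjust_total_fa
#' @param pairs A list of length-2 character vectors `c(reference,
#'   comparison)`.
#' @param items Item codes to compare, in output order. Empty input gives an
#'   empty table.
#' @param min_frac_quantified Suppression threshold on `frac_quantified`.
#' @return A `milk_comparison` tibble: `item`, `reference`, `comparison`,
#'   `value_ref`, `value_cmp`, `pct_diff`, `pct_diff_display`, `t`, `df`,
#'   `p_value`, `suppressed`.
#' @examples
#' profs <- dplyr::bind_rows(milk_fa_profiles(),
#'                           adjust_total_fa(milk_fa_profiles(), "grassmilk"))
#' build_comparison_table(profs,
#'   pairs = list(c("conventional", "grassmilk_adjusted")),
#'   items = c("omega3_total", "la", "cla"))
#' @export
build_comparison_table <- function(profiles, pairs, items,
                                   min_frac_quantified = 0.05) {
  labels <- unique(profiles$label)
  for (p in pairs) {
    unknown <- setdiff(p, labels)
    if (length(unknown) > 0) {
      abort(paste0("unknown profile label(s): ",
                   paste(unknown, collapse = ", ")),
            class = "lactofat_key_error")
    }
  }
  rows <- purrr::map(pairs, function(p) {
    purrr::map(items, function(it) {
      a <- profiles[profiles$label == p[1] & profiles$item == it, ]
      b <- profiles[profiles$label == p[2] & profiles$item == it, ]
      if (nrow(a) == 0 || nrow(b) == 0) {
        abort(paste0("item '", it, "' absent from pair ",
                     p[1], " / ", p[2]),
              class = "lactofat_key_error")
      }
      suppressed <- isTRUE(a$frac_quantified[1] < min_frac_quantified) ||
        isTRUE(b$frac_quantified[1] < min_frac_quantified)
      pd <- if (suppressed || is.na(a$amount[1]) || is.na(b$amount[1]))
        NA_real_ else percent_difference(a$amount[1], b$amount[1])
      have_test <- !suppressed &&
        all(is.finite(c(a$n[1], a$sd[1], b$n[1], b$sd[1]))) &&
        a$n[1] >= 2 && b$n[1] >= 2
      if (have_test) {
        ht <- welch_t_from_summary(a$amount[1], a$sd[1], a$n[1],
                                   b$amount[1], b$sd[1], b$n[1])
        tt <- unname(ht$statistic); dfree <- unname(ht$parameter)
        pv <- ht$p.value
      } else {
        tt <- NA_real_; dfree <- NA_real_; pv <- NA_real_
      }
      tibble::tibble(
        item = it, reference = p[1], comparison = p[2],
        value_ref = a$amount[1], value_cmp = b$amount[1],
        pct_diff = pd, pct_diff_display = format_pct_diff(pd),
        t = tt, df = dfree, p_value = pv, suppressed = suppressed
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(
      item = character(), reference = character(), comparison = character(),
      value_ref = double(), value_cmp = double(), pct_diff = double(),
      pct_diff_display = double(), t = double(), df = double(),
      p_value = double(), suppressed = logical())
  }
  class(rows) <- c("milk_comparison", class(rows))
  rows
}

#' @export
tidy.milk_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "milk_comparison")
  out
}

#' @export
glance.milk_comparison <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x),
    n_pairs = nrow(dplyr::distinct(x, .data$reference, .data$comparison)),
    n_suppressed = sum(x$suppressed),
    n_tested = sum(!is.na(x$p_value))
  )
}

#' @export
autoplot.milk_comparison <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$pct_diff))
  df$pair <- paste(df$reference, "→", df$comparison)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$item, levels = rev(unique(object$item))),
    y = .data$pct_diff, fill = .data$pct_diff > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair)) +
    ggplot2::labs(x = NULL, y = "% difference vs reference") +
    ggplot2::theme_minimal()
}
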