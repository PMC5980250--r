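# Build a small long-format panel in code. `values` is a named list mapping
# fatty-acid code -> numeric vector (one element per sample); NA means
# below-LOD. `missing` marks (sample index, code) cells as missing.
toy_panel <- function(values, total_fa = 3.585, fat_pct = 4.2,
                      region = "Midwest", year = 2014, month = 1,
                      farm_id = NULL) {
  n <- length(values[[1]])
  stopifnot(all(lengths(values) == n))
  ids <- sprintf("T%03d", seq_len(n))
  month <- rep_len(month, n)
  region <- rep_len(region, n)
  year <- rep_len(year, n)
  farm_id <- farm_id %||% rep("farmA", n)
  purrr::imap(values, function(v, cd) {
    tibble::tibble(
      sample_id = ids, farm_id = rep_len(farm_id, n), region = region,
      year = year, month = month, fat_pct = fat_pct,
      total_fa = total_fa, code = cd, value = v,
      status = ifelse(is.na(v), "below_lod", "quantified")
    )
  }) |> dplyr::bind_rows()
}

# Independent loop-based summary oracle: plain arithmetic over quantified
# observations, no dplyr.
oracle_summary <- function(panel, code, unit = "g_per_100g") {
  obs <- c()
  for (i in seq_len(nrow(panel))) {
    if (panel$code[i] == code && panel$status[i] == "quantified") {
      v <- panel$value[i]
      if (unit == "pct_of_total_fa") v <- 100 * v / panel$total_fa[i]
      obs <- c(obs, v)
    }
  }
  n <- length(obs)
  m <- sum(obs) / n
  s <- sqrt(sum((obs - m)^2) / (n - 1))
  list(mean = m, n = n, sd = s, cv = 100 * s / m, se = s / sqrt(n))
}

# Ratio of two items within one profile of a long profile table.
profile_ratio <- function(profiles, label, pair) {
  num <- profiles$amount[profiles$label == label & profiles$item == pair[1]]
  den <- profiles$amount[profiles$label == label & profiles$item == pair[2]]
  num / den
}

# The seven omega-3 panel means of the source study's summary table, used in
# several group-sum tests.
OMEGA3_TABLE_MEANS <- c(
  ala = 0.04409, sda = 0.002636, etr_n3 = 0.001139, epa = 0.004132,
  dtr_n3 = 0.00114, dpa = 0.005432, dha = 0.001064
)
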