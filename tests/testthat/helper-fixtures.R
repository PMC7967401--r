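# Shared test builders. Everything is generated in code; fixed seeds make
# the stochastic checks reproducible.

months_n <- function(n, start = "2004-01") {
  month_seq(start, index_to_ym_(ym_to_index_(start) + n - 1))
}

# thin wrappers around the package internals used only for month arithmetic
ym_to_index_ <- function(ym) {
  y <- as.integer(substr(ym, 1, 4)); m <- as.integer(substr(ym, 6, 7))
  y * 12L + (m - 1L)
}
index_to_ym_ <- function(idx) sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)

imputed_series <- function(values, topic_id = "x", start = "2004-01",
                           region = "world") {
  topic_series(topic_id, months_n(length(values), start), values,
               region = region, imputed = TRUE)
}

raw_series <- function(tokens, topic_id = "x", start = "2004-01") {
  topic_series(topic_id, months_n(length(tokens), start), tokens,
               imputed = FALSE)
}

# Brute-force Seasonal Mann-Kendall S: enumerate every within-season pair.
brute_force_seasonal_S <- function(x, period) {
  S <- 0
  for (g in seq_len(period)) {
    xg <- x[seq(g, length(x), by = period)]
    for (i in seq_len(length(xg) - 1)) {
      for (j in seq(i + 1, length(xg))) {
        S <- S + sign(xg[j] - xg[i])
      }
    }
  }
  S
}

# GT interest-over-time CSV text from a value matrix.
gt_csv <- function(months, ..., preamble = TRUE) {
  cols <- list(...)
  header <- paste(c("Month", names(cols)), collapse = ",")
  rows <- vapply(seq_along(months), function(i) {
    paste(c(months[i], vapply(cols, function(v) as.character(v[i]),
                              character(1))), collapse = ",")
  }, character(1))
  txt <- c(header, rows)
  if (preamble) txt <- c("Category: All categories", "", txt)
  paste(txt, collapse = "\n")
}
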