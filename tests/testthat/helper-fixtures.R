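# Shared fixtures: a reference site and small in-code weather series.

terai_site <- function() site_meta("synthetic-terai", latitude = 26.4,
                                   elevation = 80)

# Small hand-written series with all five variables, n rows from a fixed
# deterministic table (no RNG) — used where synthetic realism is not needed.
tiny_series <- function(n = 6) {
  stopifnot(n <= 8)
  df <- data.frame(
    date = as.Date("2005-03-01") + 0:7,
    tmin = c(14, 15, 13, 16, 17, 15, 14, 16),
    tmax = c(27, 29, 26, 30, 31, 28, 27, 29),
    ws = c(1.1, 0.8, 2.3, 1.5, 0.4, 1.9, 1.2, 0.9),
    rh = c(60, 72, 55, 64, 80, 58, 66, 70),
    sr = c(18, 15, 20, 17, 12, 19, 16, 14)
  )
  weather_series(df[seq_len(n), ], terai_site())
}

write_tiny_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
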