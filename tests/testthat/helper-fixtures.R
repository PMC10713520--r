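# Shared fixtures: all built in code at test time.

# Write a small tab-delimited export with WoS field tags and return its path.
write_export_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- c("AU", "SO", "DT", "PY", "C1", "TC", "DI", "PG")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, collapse = "\t", FUN.VALUE = character(1)))
  writeLines(lines, path)
  path
}

# A 6-city, 4-country in-memory gazetteer written to CSV.
write_tiny_gazetteer <- function(path = tempfile(fileext = ".csv"),
                                 extra = NULL) {
  df <- data.frame(
    city = c("Helsinki", "Turku", "London", "London", "Boston", "Paris"),
    country = c("Finland", "Finland", "UK", "Canada", "USA", "France"),
    lat = c(60.17, 60.45, 51.51, 42.98, 42.36, 48.86),
    lng = c(24.94, 22.27, -0.13, -81.25, -71.06, 2.35),
    pop = c(653835, 192962, 8982000, 383822, 692600, 2148271),
    capital = c(1, 0, 1, 0, 0, 1))
  if (!is.null(extra)) df <- rbind(df, extra)
  write.csv(df, path, row.names = FALSE)
  path
}

# Minimal record/geo tibbles for functions that only need a few columns.
make_records_tbl <- function(journal, year, total_citations,
                             record_id = sprintf("r%04d", seq_along(year))) {
  tibble::tibble(record_id = record_id, journal = journal, year = year,
                 total_citations = total_citations)
}

make_geos_tbl <- function(record_id, country, city = NA_character_,
                          resolution = "country") {
  tibble::tibble(record_id = record_id, country = country, city = city,
                 resolution = resolution)
}

# Primary-country geolocations straight from synthetic address strings
# (bypasses the gazetteer for speed in simulation-heavy tests).
fast_geos <- function(records) {
  tibble::tibble(
    record_id = rep(records$record_id, lengths(records$addresses)),
    country = vapply(strsplit(unlist(records$addresses), ", "),
                     function(tok) tok[length(tok)], character(1)),
    city = NA_character_,
    resolution = "country")
}

# Adjusted Rand index by pair counting (independent of any clustering
# package).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
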