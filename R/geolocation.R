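# Offline geolocation of corresponding-author addresses: gazetteer loading,
# country canonicalization, continent mapping, population join.

# Canonical country spellings are the short forms used throughout the
# package's aggregate tables ("USA", "UK", ...). The alias table folds the
# spellings that occur in affiliation strings (including the constituent
# countries of the UK, which publication databases report separately).
country_alias_table <- c(
  "UNITED STATES" = "USA", "UNITED STATES OF AMERICA" = "USA",
  "U.S.A." = "USA", "U.S." = "USA", "US" = "USA", "USA" = "USA",
  "UNITED KINGDOM" = "UK", "GREAT BRITAIN" = "UK", "UK" = "UK",
  "ENGLAND" = "UK", "SCOTLAND" = "UK", "WALES" = "UK",
  "NORTHERN IRELAND" = "UK",
  "PEOPLES R CHINA" = "China", "PEOPLE'S REPUBLIC OF CHINA" = "China",
  "CHINA" = "China", "HONG KONG" = "China",
  "SOUTH KOREA" = "South Korea", "REPUBLIC OF KOREA" = "South Korea",
  "KOREA, REPUBLIC OF" = "South Korea", "KOREA" = "South Korea",
  "HOLLAND" = "Netherlands", "THE NETHERLANDS" = "Netherlands",
  "NETHERLANDS" = "Netherlands",
  "UNITED ARAB EMIRATES" = "UAE", "RUSSIAN FEDERATION" = "Russia",
  "CZECH REPUBLIC" = "Czechia",
  "CANADA" = "Canada", "FRANCE" = "France", "GERMANY" = "Germany",
  "AUSTRALIA" = "Australia", "SWITZERLAND" = "Switzerland",
  "SWEDEN" = "Sweden", "DENMARK" = "Denmark", "ITALY" = "Italy",
  "JAPAN" = "Japan", "SPAIN" = "Spain", "BELGIUM" = "Belgium",
  "NORWAY" = "Norway", "SOUTH AFRICA" = "South Africa",
  "NEW ZEALAND" = "New Zealand", "ISRAEL" = "Israel", "BRAZIL" = "Brazil",
  "FINLAND" = "Finland", "AUSTRIA" = "Austria", "INDIA" = "India",
  "SINGAPORE" = "Singapore", "IRELAND" = "Ireland", "THAILAND" = "Thailand",
  "KENYA" = "Kenya", "GREECE" = "Greece", "PAKISTAN" = "Pakistan",
  "SAUDI ARABIA" = "Saudi Arabia", "BANGLADESH" = "Bangladesh",
  "PORTUGAL" = "Portugal", "RUSSIA" = "Russia", "MEXICO" = "Mexico",
  "ARGENTINA" = "Argentina", "CHILE" = "Chile", "COLOMBIA" = "Colombia",
  "NIGERIA" = "Nigeria", "EGYPT" = "Egypt", "ETHIOPIA" = "Ethiopia",
  "UGANDA" = "Uganda", "TANZANIA" = "Tanzania", "GHANA" = "Ghana",
  "TURKEY" = "Turkey", "IRAN" = "Iran", "POLAND" = "Poland",
  "HUNGARY" = "Hungary", "CZECHIA" = "Czechia", "ICELAND" = "Iceland",
  "MALAYSIA" = "Malaysia", "INDONESIA" = "Indonesia",
  "PHILIPPINES" = "Philippines", "VIETNAM" = "Vietnam", "TAIWAN" = "Taiwan",
  "UAE" = "UAE", "QATAR" = "Qatar", "KUWAIT" = "Kuwait"
)

continent_table <- c(
  USA = "Americas", Canada = "Americas", Brazil = "Americas",
  Mexico = "Americas", Argentina = "Americas", Chile = "Americas",
  Colombia = "Americas",
  UK = "Europe", France = "Europe", Germany = "Europe",
  Netherlands = "Europe", Switzerland = "Europe", Sweden = "Europe",
  Denmark = "Europe", Italy = "Europe", Spain = "Europe",
  Belgium = "Europe", Norway = "Europe", Finland = "Europe",
  Austria = "Europe", Ireland = "Europe", Greece = "Europe",
  Portugal = "Europe", Poland = "Europe", Hungary = "Europe",
  Czechia = "Europe", Iceland = "Europe", Russia = "Europe",
  China = "Asia", Japan = "Asia", `South Korea` = "Asia", India = "Asia",
  Singapore = "Asia", Thailand = "Asia", Pakistan = "Asia",
  `Saudi Arabia` = "Asia", Bangladesh = "Asia", Israel = "Asia",
  Turkey = "Asia", Iran = "Asia", Malaysia = "Asia", Indonesia = "Asia",
  Philippines = "Asia", Vietnam = "Asia", Taiwan = "Asia", UAE = "Asia",
  Qatar = "Asia", Kuwait = "Asia",
  `South Africa` = "Africa", Kenya = "Africa", Nigeria = "Africa",
  Egypt = "Africa", Ethiopia = "Africa", Uganda = "Africa",
  Tanzania = "Africa", Ghana = "Africa",
  Australia = "Oceania", `New Zealand` = "Oceania"
)

#' Canonicalize country names
#'
#' Folds common spelling variants onto one canonical short form ("United
#' States" to "USA"; "England", "Scotland", "Wales" and "Northern Ireland"
#' to "UK"). Unknown names pass through verbatim with a warning so that no
#' address is silently lost; [is_canonical_country()] identifies them.
#'
#' @param name Character vector of country names.
#' @param warn Warn on unrecognized names.
#' @return Character vector of canonical names (unrecognized entries
#'   verbatim).
#' @export
#' @examples
#' normalize_country(c("United States", "England"))
normalize_country <- function(name, warn = TRUE) {
  if (any(is.na(name)) || any(!nzchar(name))) abort("empty country name")
  key <- toupper(trimws(name))
  hit <- country_alias_table[key]
  unknown <- is.na(hit)
  if (any(unknown) && warn) {
    warn(paste0("unrecognized country name(s) kept verbatim: ",
                paste(unique(name[unknown]), collapse = ", ")))
  }
  hit[unknown] <- trimws(name[unknown])
  unname(hit)
}

#' @rdname normalize_country
#' @export
is_canonical_country <- function(name) {
  name %in% unname(country_alias_table)
}

#' Map canonical countries to continents
#'
#' Static lookup; the Americas are a single continent (North and South
#' America merged), giving the five-level scheme Africa, Americas, Asia,
#' Europe, Oceania.
#'
#' @param country Canonical country names.
#' @return Character vector of continent labels.
#' @export
#' @examples
#' map_continent(c("Brazil", "China", "New Zealand"))
map_continent <- function(country) {
  hit <- continent_table[country]
  if (anyNA(hit)) {
    abort(paste0("no continent mapping for: ",
                 paste(unique(country[is.na(hit)]), collapse = ", ")))
  }
  unname(hit)
}

#' Load an offline gazetteer
#'
#' Reads a CSV with columns `city,country,lat,lng,pop,capital`, canonicalizes
#' country names, rejects rows with out-of-range coordinates (with a
#' warning), and collapses duplicate (city, country) pairs to the
#' highest-population entry.
#'
#' @param path CSV path; defaults to the gazetteer bundled with the package
#'   (a curated table of about 200 cities in the countries most active in
#'   medical publishing, with approximate coordinates and populations).
#' @return A tibble of class `gazetteer`.
#' @export
load_gazetteer <- function(path = default_gazetteer_path()) {
  gz <- readr::read_csv(path, col_types = "ccddid", progress = FALSE)
  required <- c("city", "country", "lat", "lng", "pop", "capital")
  missing <- setdiff(required, names(gz))
  if (length(missing) > 0) {
    abort(paste0("gazetteer is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- is.na(gz$lat) | is.na(gz$lng) |
    abs(gz$lat) > 90 | abs(gz$lng) > 180
  if (any(bad)) {
    warn(paste0(sum(bad), " gazetteer row(s) rejected for out-of-range ",
                "coordinates (rows ", paste(which(bad), collapse = ", "), ")"))
    gz <- gz[!bad, , drop = FALSE]
  }
  gz$country <- normalize_country(gz$country, warn = FALSE)
  gz <- gz |>
    dplyr::arrange(dplyr::desc(.data$pop)) |>
    dplyr::distinct(.data$city, .data$country, .keep_all = TRUE) |>
    dplyr::arrange(.data$country, .data$city)
  structure(gz, class = c("gazetteer", class(tibble::tibble())))
}

#' @rdname load_gazetteer
#' @export
default_gazetteer_path <- function() {
  system.file("extdata", "gazetteer.csv", package = "geobib", mustWork = TRUE)
}

#' Resolve one address string against a gazetteer
#'
#' Splits the address on commas, strips punctuation, and matches the
#' rightmost token that canonicalizes to a country known to the gazetteer or
#' the continent table; the city is then the longest token that is a
#' (case-insensitive) gazetteer city of that country. Resolution level is
#' `"city"` when both match, `"country"` when only the country does, and
#' `"unresolved"` otherwise. Purely deterministic for a fixed gazetteer; no
#' network access.
#'
#' @param address Raw address string.
#' @param gz A [load_gazetteer()] table.
#' @return One-row tibble: `city`, `country`, `lat`, `lng`, `resolution`.
#' @export
#' @examples
#' gz <- load_gazetteer()
#' geolocate_address("Helsinki University Hospital, Helsinki, Finland", gz)
geolocate_address <- function(address, gz) {
  if (is.na(address) || !nzchar(address)) abort("empty address")
  unresolved <- tibble::tibble(city = NA_character_, country = NA_character_,
                               lat = NA_real_, lng = NA_real_,
                               resolution = "unresolved")
  tokens <- trimws(strsplit(address, "[,;]")[[1]])
  tokens <- gsub("[.]", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) return(unresolved)
  known <- unique(c(gz$country, names(continent_table)))
  country <- NA_character_
  for (tok in rev(tokens)) {
    cand <- suppressWarnings(normalize_country(tok, warn = FALSE))
    if (cand %in% known) {
      country <- cand
      break
    }
  }
  if (is.na(country)) return(unresolved)
  cities <- gz[gz$country == country, , drop = FALSE]
  hit <- cities[match(toupper(tokens), toupper(cities$city)), , drop = FALSE]
  hit <- hit[!is.na(hit$city), , drop = FALSE]
  if (nrow(hit) == 0) {
    return(tibble::tibble(city = NA_character_, country = country,
                          lat = NA_real_, lng = NA_real_,
                          resolution = "country"))
  }
  best <- hit[which.max(nchar(hit$city)), , drop = FALSE]
  tibble::tibble(city = best$city, country = country,
                 lat = best$lat, lng = best$lng, resolution = "city")
}

#' Geolocate every address of every record
#'
#' Applies [geolocate_address()] to each (record, address) pair and reports
#' the pipeline-level resolution rate as an attribute.
#'
#' @param records A `wos_records` tibble.
#' @param gz A gazetteer.
#' @return Tibble with one row per (record, address): `record_id`,
#'   `address`, `city`, `country`, `lat`, `lng`, `resolution`; attribute
#'   `resolution_rate` is the fraction of addresses resolved at city or
#'   country level.
#' @export
geolocate_records <- function(records, gz) {
  pairs <- tibble::tibble(
    record_id = rep(records$record_id, lengths(records$addresses)),
    address = unlist(records$addresses, use.names = FALSE)
  )
  geo <- purrr::map(pairs$address, geolocate_address, gz = gz)
  geo <- dplyr::bind_rows(geo)
  out <- dplyr::bind_cols(pairs, geo)
  attr(out, "resolution_rate") <- mean(out$resolution != "unresolved")
  out
}

#' Attach national populations
#'
#' Accepts either a long-format table (`country,population`) or a World
#' Bank style wide table (one column per year) with `population_year`
#' selecting the column. Countries absent from the table are kept with
#' `population = NA` and flagged, so normalized metrics can exclude them
#' explicitly.
#'
#' @param countries Canonical country names to look up.
#' @param table Data frame, or path to a CSV.
#' @param population_year Year column to use for wide-format tables; ignored
#'   for long format.
#' @return Tibble: `country`, `continent`, `population`, `population_missing`.
#' @export
join_population <- function(countries, table = default_population_path(),
                            population_year = NULL) {
  if (length(countries) == 0) {
    return(tibble::tibble(country = character(), continent = character(),
                          population = numeric(),
                          population_missing = logical()))
  }
  if (is.character(table)) {
    table <- readr::read_csv(table, col_types = readr::cols(), progress = FALSE)
  }
  if (!"country" %in% names(table)) {
    abort("population table must have a 'country' column")
  }
  if ("population" %in% names(table)) {
    pop_col <- "population"
  } else {
    year_cols <- names(table)[grepl("^[0-9]{4}$", names(table))]
    if (length(year_cols) == 0) {
      abort("population table has neither a 'population' column nor year columns")
    }
    if (is.null(population_year)) population_year <- max(as.integer(year_cols))
    pop_col <- as.character(population_year)
    if (!pop_col %in% year_cols) {
      abort(paste0("population year ", population_year, " not in table"))
    }
  }
  canon <- normalize_country(table$country, warn = FALSE)
  pop <- as.numeric(table[[pop_col]])[match(countries, canon)]
  if (anyNA(pop)) {
    warn(paste0("no population for: ",
                paste(countries[is.na(pop)], collapse = ", "),
                " (excluded from normalized metrics)"))
  }
  tibble::tibble(
    country = countries,
    continent = unname(continent_table[countries]),
    population = pop,
    population_missing = is.na(pop)
  )
}

#' @rdname join_population
#' @export
default_population_path <- function() {
  system.file("extdata", "country_populations.csv", package = "geobib",
              mustWork = TRUE)
}
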