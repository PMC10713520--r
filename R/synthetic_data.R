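# Synthetic publication records and citation networks with controllable
# geographic structure: country sampling weights, per-country temporal
# drifts, journal-country affinity, negative-binomial citation totals, and
# a domestic-citation preference parameter (theta_self) that the
# self-citation index must recover.

default_country_weights <- c(
  USA = 0.45, UK = 0.16, Japan = 0.07, Canada = 0.06, France = 0.05,
  Germany = 0.05, China = 0.05, Netherlands = 0.04, Australia = 0.04,
  Denmark = 0.03)

default_journals <- tibble::tibble(
  journal = c("NEJM", "Lancet", "JAMA", "BMJ", "NatMed"),
  home_country = c("USA", "UK", "USA", "UK", "UK"),
  weight = c(0.281, 0.233, 0.174, 0.163, 0.149))

#' Configuration of the synthetic publication-and-citation generator
#'
#' The defaults emulate the structure of a decade of original articles in a
#' handful of leading general-medical journals: a heavily skewed country
#' distribution (the two largest contributors holding roughly half and a
#' sixth of articles), five journals with US/UK home countries and
#' realistic size shares, heavy-tailed per-article citation totals
#' (negative binomial), and a moderate domestic-citation preference.
#'
#' @param n_articles Number of articles to generate.
#' @param years Inclusive vector of publication years.
#' @param countries Named non-negative weights (sampling probabilities after
#'   normalization).
#' @param cities_per_country How many gazetteer cities (by population) each
#'   country uses.
#' @param journals Tibble with `journal`, `home_country`, `weight`.
#' @param journal_affinity Multiplier (>= 1) applied to a journal's weight
#'   when the article's country is the journal's home country.
#' @param citation_mean,citation_dispersion Negative-binomial mean and size
#'   of per-article citation totals.
#' @param theta_self Probability in \[0, 1\] that a citing event is assigned
#'   to the cited article's own country rather than drawn from the global
#'   allocation.
#' @param p_extra_address Probability a record carries a second
#'   corresponding address (drawn from the global allocation).
#' @param trend_slopes Optional named vector of articles-per-year drifts per
#'   country.
#' @param seed RNG seed; fixing it makes all generator output reproducible.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_articles = 2000, years = 2010:2019,
                             countries = default_country_weights,
                             cities_per_country = 3,
                             journals = default_journals,
                             journal_affinity = 1,
                             citation_mean = 25, citation_dispersion = 1,
                             theta_self = 0.4, p_extra_address = 0.2,
                             trend_slopes = NULL, seed = NULL) {
  if (length(countries) == 0) abort("empty country list")
  if (any(countries < 0) || sum(countries) <= 0) {
    abort("country weights must be non-negative with positive sum")
  }
  if (theta_self < 0 || theta_self > 1) abort("theta_self must be in [0, 1]")
  if (citation_mean <= 0) abort("citation_mean must be positive")
  if (journal_affinity < 1) abort("journal_affinity must be >= 1")
  structure(
    list(n_articles = n_articles, years = years,
         countries = countries / sum(countries),
         cities_per_country = cities_per_country, journals = journals,
         journal_affinity = journal_affinity, citation_mean = citation_mean,
         citation_dispersion = citation_dispersion, theta_self = theta_self,
         p_extra_address = p_extra_address, trend_slopes = trend_slopes,
         seed = seed),
    class = "synthetic_config")
}

#' Generate synthetic publication records
#'
#' Draws (country, year) cells from the configured weights, modulated by
#' any per-country temporal drift; assigns cities within a country
#' proportional to gazetteer population, journals with the home-country
#' affinity multiplier, semicolon-delimited author strings, and address
#' strings of the form "institute, city, country" that the packaged
#' gazetteer resolves. Citation totals are zero placeholders until
#' [generate_citations()] fills them.
#'
#' @param cfg A [synthetic_config()].
#' @param gz Gazetteer used for city sampling and address synthesis.
#' @return A `wos_records` tibble with attribute `ground_truth`: the
#'   generator's own tallies (`per_country` of distinct record-country
#'   pairs, `primary_country` counts, `per_city`, `per_journal`,
#'   `per_country_year`).
#' @export
generate_publications <- function(cfg, gz = load_gazetteer()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_articles
  countries <- names(cfg$countries)
  empty <- new_wos_records(
    tibble::tibble(record_id = character(), journal = character(),
                   doc_type = character(), year = integer(),
                   authors_raw = character(), author_count = integer(),
                   addresses = list(), total_citations = integer(),
                   doi = character(), page_length = integer()),
    provenance = list(source = "synthetic", filters = character()))
  if (n == 0) return(empty)
  ny <- length(cfg$years)
  ybar <- mean(cfg$years)
  cells <- expand.grid(country = countries, year = cfg$years,
                       stringsAsFactors = FALSE)
  slope <- (cfg$trend_slopes %||% setNames(numeric(0), character(0)))
  cells$w <- pmax(0, n * cfg$countries[cells$country] / ny +
                    ifelse(cells$country %in% names(slope),
                           slope[cells$country] * (cells$year - ybar), 0))
  counts <- as.vector(rmultinom(1, n, cells$w / sum(cells$w)))
  art <- cells[rep(seq_len(nrow(cells)), counts), c("country", "year")]
  art <- art[sample.int(nrow(art)), , drop = FALSE]  # shuffle row order
  rownames(art) <- NULL

  city_pool <- gz |>
    dplyr::filter(.data$country %in% countries) |>
    dplyr::group_by(.data$country) |>
    dplyr::slice_max(.data$pop, n = cfg$cities_per_country,
                     with_ties = FALSE) |>
    dplyr::ungroup()
  missing <- setdiff(countries, unique(city_pool$country))
  if (length(missing) > 0) {
    abort(paste0("gazetteer has no cities for: ",
                 paste(missing, collapse = ", ")))
  }
  art$city <- vapply(art$country, function(cn) {
    pool <- city_pool[city_pool$country == cn, ]
    sample(pool$city, 1, prob = pool$pop)
  }, character(1))

  jw <- matrix(rep(cfg$journals$weight, each = nrow(art)),
               nrow(art), nrow(cfg$journals))
  for (j in seq_len(nrow(cfg$journals))) {
    home <- cfg$journals$home_country[j]
    jw[art$country == home, j] <- jw[art$country == home, j] *
      cfg$journal_affinity
  }
  art$journal <- cfg$journals$journal[
    vapply(seq_len(nrow(art)),
           function(i) sample.int(ncol(jw), 1, prob = jw[i, ]), integer(1))]

  n_auth <- as.integer(pmin(15, 1 + stats::rpois(nrow(art), 5)))
  authors_raw <- vapply(n_auth, function(k) {
    paste(sprintf("Author%02d A", seq_len(k)), collapse = "; ")
  }, character(1))
  addresses <- lapply(seq_len(nrow(art)), function(i) {
    sprintf("%s Univ, %s, %s", art$city[i], art$city[i], art$country[i])
  })
  extra <- stats::runif(nrow(art)) < cfg$p_extra_address
  if (any(extra)) {
    for (i in which(extra)) {
      cn <- sample(countries, 1, prob = cfg$countries)
      pool <- city_pool[city_pool$country == cn, ]
      ct <- sample(pool$city, 1, prob = pool$pop)
      addresses[[i]] <- c(addresses[[i]],
                          sprintf("%s Inst, %s, %s", ct, ct, cn))
    }
  }

  records <- new_wos_records(
    tibble::tibble(
      record_id = sprintf("rec%06d", seq_len(nrow(art))),
      journal = art$journal, doc_type = "Article", year = art$year,
      authors_raw = authors_raw, author_count = n_auth,
      addresses = addresses, total_citations = 0L,
      doi = sprintf("10.1000/synth.%06d", seq_len(nrow(art))),
      page_length = sample(4:20, nrow(art), replace = TRUE)),
    provenance = list(source = "synthetic", filters = character()))

  pair_country <- lapply(addresses, function(a) {
    unique(vapply(strsplit(a, ", "), function(tok) tok[length(tok)],
                  character(1)))
  })
  gt_country <- table(unlist(pair_country))
  attr(records, "ground_truth") <- list(
    per_country = as.integer(gt_country) |> setNames(names(gt_country)),
    primary_country = table(art$country),
    per_city = table(paste(art$city, art$country, sep = ", ")),
    per_journal = table(art$journal),
    per_country_year = table(art$country, art$year))
  records
}

#' Generate citation totals and a citing-event table
#'
#' Each article's citation total is negative binomial with the configured
#' mean and dispersion. Every citation of an article is then assigned a
#' citing country: the article's own (primary-address) country with
#' probability `theta_self`, otherwise a draw from the global allocation
#' (countries in proportion to their realized article mass). Events are
#' aggregated to country-level counts; the per-article link structure is
#' not retained.
#'
#' @param records Records from [generate_publications()].
#' @param cfg The same [synthetic_config()].
#' @return List: `records` (citation totals filled in), `events`
#'   (citing_country, cited_country, n), `matrix` (the realized tally as a
#'   `citation_matrix`), `expected_matrix` (conditional expectation given
#'   the realized citation totals, for recovery tests).
#' @export
generate_citations <- function(records, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (nrow(records) == 0) abort("no records to cite")
  primary <- vapply(records$addresses, function(a) {
    tok <- strsplit(a[1], ", ")[[1]]
    tok[length(tok)]
  }, character(1))
  cit <- rnbinom(nrow(records), mu = cfg$citation_mean,
                 size = cfg$citation_dispersion)
  records$total_citations <- as.integer(cit)

  countries <- sort(unique(primary))
  alloc <- as.vector(table(factor(primary, levels = countries))) /
    length(primary)
  C <- tapply(cit, factor(primary, levels = countries), sum)
  C[is.na(C)] <- 0
  m <- matrix(0, length(countries), length(countries),
              dimnames = list(citing = countries, cited = countries))
  for (j in seq_along(countries)) {
    if (C[j] == 0) next
    domestic <- rbinom(1, C[j], cfg$theta_self)
    external <- as.vector(rmultinom(1, C[j] - domestic, alloc))
    m[, j] <- external
    m[j, j] <- m[j, j] + domestic
  }
  expected <- outer(alloc * (1 - cfg$theta_self), as.vector(C)) +
    diag(cfg$theta_self * as.vector(C), length(countries))
  dimnames(expected) <- dimnames(m)
  events <- tibble::tibble(
    citing_country = rep(countries, times = length(countries)),
    cited_country = rep(countries, each = length(countries)),
    n = as.vector(m))
  events <- events[events$n > 0, , drop = FALSE]
  list(records = records, events = events,
       matrix = structure(m, class = c("citation_matrix", "matrix", "array")),
       expected_matrix = expected)
}

#' Analytic expectations of the synthetic citation matrix
#'
#' Under the generative model, a country's outgoing citations split between
#' a point mass on its own articles (weight `theta_self`) and the global
#' allocation. With total citation mass C and country weights w, cell
#' (i, j) has expectation `C * w_j * (theta * [i == j] + (1 - theta) *
#' w_i)`, giving closed forms `eq1 = theta + (1 - theta) * w` and
#' `eq2 = (1 - theta) * w`, hence `dsci = 1 + theta / ((1 - theta) * w)`.
#' At `theta_self = 0` the model reduces to proportional mixing and the
#' index is 1 everywhere.
#'
#' @param cfg A [synthetic_config()].
#' @return List: `matrix` (expected citation matrix), `per_country` tibble
#'   with `country`, `eq1`, `eq2`, `dsci`.
#' @export
closed_form_expectations <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  w <- cfg$countries
  theta <- cfg$theta_self
  C <- cfg$n_articles * cfg$citation_mean
  m <- C * outer((1 - theta) * w, w) + diag(theta * C * w, length(w))
  dimnames(m) <- list(citing = names(w), cited = names(w))
  eq1 <- theta + (1 - theta) * w
  eq2 <- (1 - theta) * w
  list(matrix = m,
       per_country = tibble::tibble(
         country = names(w), eq1 = unname(eq1), eq2 = unname(eq2),
         dsci = if (theta < 1) unname(eq1 / eq2) else NA_real_))
}
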