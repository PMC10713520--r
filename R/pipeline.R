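# End-to-end orchestration: configuration resolution, report emission, and
# the reproduction suite for the bundled country-metrics reference table.

#' Resolve a full pipeline configuration
#'
#' Collects input paths, filters, thresholds and every analytical
#' convention into one explicit list: nothing downstream falls back to a
#' silent default, so the emitted run metadata fully determines each
#' reported number.
#'
#' @param records Path to a tab-delimited publication export.
#' @param gazetteer,population Paths to the gazetteer and population CSVs
#'   (package defaults used when `NULL`).
#' @param citing_events Optional path to a citing-events CSV
#'   (`citing_country,cited_country,n`).
#' @param journals Journals to retain; `NULL` keeps all journals present.
#' @param years Inclusive year window, length-2 integer.
#' @param doc_types Document types to retain.
#' @param min_articles Inclusion threshold per unit.
#' @param flag_pct Excess/deficit flag threshold in percent.
#' @param reference_year Reference year for citations-per-year.
#' @param population_year Year column for wide population tables.
#' @param regression_direction Convention of [fit_loglog()].
#' @param eq2_variant Convention of [dsci()].
#' @param n_clusters Citation-fingerprint cluster count.
#' @param out Output directory for reports.
#' @param seed RNG seed recorded in the metadata.
#' @return List of class `run_config` with every field filled.
#' @export
run_config <- function(records, gazetteer = NULL, population = NULL,
                       citing_events = NULL, journals = NULL,
                       years = c(2010L, 2019L), doc_types = "Article",
                       min_articles = 10, flag_pct = 10,
                       reference_year = max(years) + 3,
                       population_year = NULL,
                       regression_direction = "articles_on_citations",
                       eq2_variant = "prose", n_clusters = 3,
                       out = tempfile("geobib_run_"), seed = 1L) {
  cfg <- list(records = records,
              gazetteer = gazetteer %||% default_gazetteer_path(),
              population = population %||% default_population_path(),
              citing_events = citing_events, journals = journals,
              years = as.integer(years), doc_types = doc_types,
              min_articles = min_articles, flag_pct = flag_pct,
              reference_year = reference_year,
              population_year = population_year,
              regression_direction = regression_direction,
              eq2_variant = eq2_variant, n_clusters = n_clusters,
              out = out, seed = seed)
  for (p in c("records", "gazetteer", "population")) {
    if (!file.exists(cfg[[p]])) {
      abort(paste0("input '", p, "' does not exist: ", cfg[[p]]))
    }
  }
  if (!is.null(cfg$citing_events) && !file.exists(cfg$citing_events)) {
    abort(paste0("input 'citing_events' does not exist: ", cfg$citing_events))
  }
  structure(cfg, class = "run_config")
}

#' Run the full disparity-analysis pipeline
#'
#' Parses the export, geolocates every corresponding-author address against
#' the offline gazetteer, aggregates by country and by city, normalizes to
#' population, fits the log-log publication-citation relation and derives
#' excess/deficit articles, fits yearly trends, tests journal-country
#' composition, and (when a citing-events table is supplied) computes the
#' self-citation index and clusters citation fingerprints. All reports are
#' written as CSV plus one JSON metadata file; on failure partial outputs
#' are removed.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with every computed table and the path of each
#'   written report.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on_fail <- function(e) {
    unlink(file.path(cfg$out, written))
    abort(paste0("pipeline failed (partial outputs removed): ",
                 conditionMessage(e)))
  }
  tryCatch({
    set.seed(cfg$seed)
    records <- parse_wos_export(cfg$records)
    journals <- cfg$journals %||% unique(records$journal)
    records <- filter_records(records, journals, cfg$years[1], cfg$years[2],
                              cfg$doc_types)
    gz <- load_gazetteer(cfg$gazetteer)
    geos <- geolocate_records(records, gz)

    country <- aggregate_by_unit(records, geos, "country",
                                 min_articles = cfg$min_articles,
                                 reference_year = cfg$reference_year)
    info <- suppressWarnings(
      join_population(country$country, cfg$population,
                      population_year = cfg$population_year))
    country <- population_normalize(country, info)
    city <- aggregate_by_unit(records, geos, "city",
                              min_articles = cfg$min_articles,
                              reference_year = cfg$reference_year)

    fit <- fit_loglog(country, direction = cfg$regression_direction)
    excess <- compute_excess(country, fit, flag_pct = cfg$flag_pct)
    city_fit <- if (nrow(city) >= 3) {
      fit_loglog(city, direction = cfg$regression_direction)
    } else NULL
    city_excess <- if (!is.null(city_fit)) {
      compute_excess(city, city_fit, flag_pct = cfg$flag_pct)
    } else NULL

    trends <- purrr::map_dfr(country$country, function(cn) {
      tr <- yearly_trend(records, geos, cn, "article_count",
                         years = seq(cfg$years[1], cfg$years[2]))
      tibble::tibble(country = cn, slope_articles_per_year = tr$slope,
                     n_years = tr$n_years)
    })
    comp <- journal_country_composition(records, geos,
                                        min_articles = cfg$min_articles)

    dsci_tbl <- NULL; clusters <- NULL
    if (!is.null(cfg$citing_events)) {
      events <- readr::read_csv(cfg$citing_events, col_types = "cci",
                                progress = FALSE)
      mat <- build_citation_matrix(events)
      dsci_tbl <- dsci(mat, eq2_variant = cfg$eq2_variant)
      clusters <- cluster_citing_profiles(mat, n_clusters = cfg$n_clusters)
      mat_df <- tibble::as_tibble(unclass(mat), rownames = "citing_country")
      readr::write_csv(mat_df, file.path(cfg$out, "citation_matrix.csv"))
      written <- c(written, "citation_matrix.csv")
    }

    emit <- function(df, name) {
      readr::write_csv(df, file.path(cfg$out, name))
      written <<- c(written, name)
    }
    emit(country, "country_metrics.csv")
    emit(city, "city_metrics.csv")
    emit(dplyr::bind_rows(excess, city_excess), "excess.csv")
    emit(trends, "trends.csv")
    emit(comp$proportions, "journal_composition.csv")
    if (!is.null(dsci_tbl)) emit(dsci_tbl, "dsci.csv")
    if (!is.null(clusters)) {
      emit(tibble::tibble(country = names(clusters$labels),
                          cluster = unname(clusters$labels)),
           "clusters.csv")
      writeLines(clusters$newick, file.path(cfg$out, "dendrogram.nwk"))
      written <- c(written, "dendrogram.nwk")
    }
    meta <- list(
      conventions = cfg[c("years", "doc_types", "min_articles", "flag_pct",
                          "reference_year", "population_year",
                          "regression_direction", "eq2_variant",
                          "n_clusters", "seed")],
      attribution = attr(country, "attribution"),
      journals = journals,
      dropped_rows = attr(records, "dropped"),
      resolution_rate = attr(geos, "resolution_rate"),
      country_coverage = attr(country, "coverage"),
      r_squared = fit$r_squared,
      package_version = as.character(utils::packageVersion("geobib")))
    jsonlite::write_json(meta, file.path(cfg$out, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, "run_metadata.json")
    summary_lines <- c(
      sprintf("%d records analyzed (%d journals, %d-%d)", nrow(records),
              length(journals), cfg$years[1], cfg$years[2]),
      sprintf("address resolution rate: %.1f%%",
              100 * attr(geos, "resolution_rate")),
      sprintf("%d countries / %d cities above the %d-article threshold",
              nrow(country), nrow(city), cfg$min_articles),
      sprintf("log-log R^2: %.3f (%s)", fit$r_squared,
              cfg$regression_direction))
    writeLines(summary_lines, file.path(cfg$out, "summary.txt"))
    written <- c(written, "summary.txt")
    invisible(list(records = records, geos = geos, country = country,
                   city = city, fit = fit, excess = excess,
                   city_excess = city_excess, trends = trends,
                   composition = comp, dsci = dsci_tbl, clusters = clusters,
                   out = cfg$out,
                   files = file.path(cfg$out, written)))
  }, error = on_fail)
}

#' Bundled country publication-metrics reference table
#'
#' The package ships a reference table of publication metrics for the 32
#' countries with at least 10 original articles in five leading
#' general-medical journals over 2010-2019: article counts, citation totals
#' (in thousands), population-normalized rates, and the published
#' excess-article columns. It is the input of [reproduce_table1()] and of
#' the package's acceptance checks.
#'
#' @return Tibble with one row per country.
#' @export
country_metrics_table <- function() {
  readr::read_csv(
    system.file("extdata", "country_metrics_2010_2019.csv",
                package = "geobib", mustWork = TRUE),
    col_types = "cidddddd", progress = FALSE)
}

#' Reproduce the headline country-level results from an aggregate table
#'
#' Fits the log-log publication-citation regression on a country metrics
#' table, and derives the quantities the analysis reports: R-squared,
#' per-country expected/excess/percent-excess articles, the count of
#' countries at or beyond the 10 percent flag, the share of the total
#' positive excess held by the two largest contributors (USA and UK), and
#' the Spearman correlation between population-normalized and absolute
#' article counts. When the table carries printed excess columns, the
#' maximum absolute deviation of the recomputed excess from them is
#' reported.
#'
#' @param table A data frame with `country`, `n_articles` and either
#'   `total_citations` or `total_citations_k` (thousands), or a path to
#'   such a CSV; defaults to the bundled reference table.
#' @param citations_in_thousands Multiply the citation column by 1000.
#'   Excess results are invariant to this scale (the intercept absorbs it);
#'   it only matters for reporting citation totals.
#' @param direction Regression convention, see [fit_loglog()].
#' @param flag_pct Flag threshold in percent.
#' @return List of class `table1_reproduction`: `fit`, `excess`,
#'   `r_squared`, `n_flagged`, `n_flagged_printed` (from the printed
#'   percent column when present), `usa_uk_positive_excess_share`,
#'   `spearman_articles_population` (list rho/p), `max_abs_dev_printed`,
#'   `article_shares` (country, share_pct).
#' @export
reproduce_table1 <- function(table = country_metrics_table(),
                             citations_in_thousands = ("total_citations_k"
                                                       %in% names(table)),
                             direction = "articles_on_citations",
                             flag_pct = 10) {
  if (is.character(table)) {
    table <- readr::read_csv(table, col_types = readr::cols(),
                             progress = FALSE)
    citations_in_thousands <- "total_citations_k" %in% names(table)
  }
  if (nrow(table) < 3) abort("need at least 3 countries")
  rows <- tibble::tibble(
    country = table$country,
    n_articles = table$n_articles,
    total_citations = if (citations_in_thousands) {
      table$total_citations_k * 1000
    } else table$total_citations)
  fit <- fit_loglog(rows, direction = direction)
  excess <- compute_excess(rows, fit, flag_pct = flag_pct)
  pos <- pmax(excess$excess_articles, 0)
  usa_uk <- sum(pos[excess$country %in% c("USA", "UK")]) / sum(pos)
  spear <- if ("articles_per_million" %in% names(table)) {
    spearman_corr(table$articles_per_million, table$n_articles)
  } else NULL
  n_flagged_printed <- if ("excess_pct" %in% names(table)) {
    sum(abs(table$excess_pct) >= flag_pct)
  } else NA_integer_
  max_dev <- if ("excess_articles" %in% names(table)) {
    max(abs(excess$excess_articles - table$excess_articles))
  } else NA_real_
  structure(
    list(fit = fit, excess = excess, r_squared = fit$r_squared,
         n_flagged = sum(excess$flag_ge10pct),
         n_flagged_printed = n_flagged_printed,
         usa_uk_positive_excess_share = usa_uk,
         spearman_articles_population = spear,
         max_abs_dev_printed = max_dev,
         article_shares = tibble::tibble(
           country = rows$country,
           share_pct = 100 * rows$n_articles / sum(rows$n_articles))),
    class = "table1_reproduction")
}

#' @export
print.table1_reproduction <- function(x, ...) {
  cat(sprintf("log-log R^2: %.4f over %d countries\n", x$r_squared,
              nrow(x$excess)))
  cat(sprintf("countries with |excess| >= 10%%: %d (printed column: %s)\n",
              x$n_flagged, x$n_flagged_printed))
  cat(sprintf("USA+UK share of positive excess: %.1f%%\n",
              100 * x$usa_uk_positive_excess_share))
  if (!is.null(x$spearman_articles_population)) {
    cat(sprintf("Spearman articles/million vs articles: %.3f (p = %.2g)\n",
                x$spearman_articles_population$rho,
                x$spearman_articles_population$p_value))
  }
  if (is.finite(x$max_abs_dev_printed)) {
    cat(sprintf("max |excess - printed excess|: %.1f articles\n",
                x$max_abs_dev_printed))
  }
  invisible(x)
}

#' Rounding envelope of the excess-article computation
#'
#' Citation totals printed in thousands carry a rounding uncertainty of
#' up to 50 citations, which for small countries is a material fraction of
#' the count and tilts the fitted log-log slope. This helper propagates
#' that uncertainty: it redraws the unrounded citation totals uniformly
#' within each printed value's rounding interval, refits, and returns the
#' per-country envelope of excess articles plus the range of the flag
#' count.
#'
#' @param table A country metrics table with `total_citations_k`.
#' @param n_draws Number of jitter draws.
#' @param flag_pct Flag threshold.
#' @param seed RNG seed.
#' @return List: `excess_range` (country, lo, hi), `flag_count_range`.
#' @export
excess_rounding_envelope <- function(table = country_metrics_table(),
                                     n_draws = 200, flag_pct = 10,
                                     seed = 1L) {
  stopifnot("total_citations_k" %in% names(table))
  set.seed(seed)
  la <- log10(table$n_articles)
  draws <- replicate(n_draws, {
    cit <- (table$total_citations_k +
              stats::runif(nrow(table), -0.05, 0.05)) * 1000
    f <- lm(la ~ log10(cit))
    ex <- table$n_articles - 10^fitted(f)
    c(ex, sum(abs(100 * ex / table$n_articles) >= flag_pct))
  })
  k <- nrow(table)
  list(excess_range = tibble::tibble(
         country = table$country,
         lo = apply(draws[seq_len(k), , drop = FALSE], 1, min),
         hi = apply(draws[seq_len(k), , drop = FALSE], 1, max)),
       flag_count_range = range(draws[k + 1, ]))
}
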