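# Country/city aggregation, the log-log publication-citation relation with
# excess/deficit articles, population normalization, temporal trends, and
# the rank-based group comparisons.

#' Aggregate publications and citations by country or city
#'
#' Each record contributes once to every distinct unit among its resolved
#' addresses: a record with two addresses in the same country counts once
#' there, while addresses in two countries add one article (and the record's
#' full citation count) to each. Units below the inclusion threshold are
#' dropped; the retained coverage fraction is recorded as an attribute.
#'
#' @param records A `wos_records` tibble.
#' @param geos Output of [geolocate_records()].
#' @param level `"country"` or `"city"` (city-level units are (city, country)
#'   pairs, so same-named cities in different countries never merge).
#' @param min_articles Inclusion threshold (default 10 articles per unit over
#'   the study window).
#' @param reference_year If given, a per-unit median of per-article
#'   [citations_per_year()] is added.
#' @param attribution Only `"once-per-unit"` is implemented; the argument
#'   records the convention in the output metadata.
#' @return Tibble with `country` (and `city` at city level), `n_articles`,
#'   `total_citations`, optionally `citations_per_year_median`; attributes
#'   `coverage` (fraction of articles retained after thresholding),
#'   `attribution`, `level`.
#' @export
aggregate_by_unit <- function(records, geos, level = c("country", "city"),
                              min_articles = 10, reference_year = NULL,
                              attribution = "once-per-unit") {
  level <- match.arg(level)
  if (!identical(attribution, "once-per-unit")) {
    abort(paste0("unknown attribution rule: ", attribution))
  }
  geo <- geos[geos$resolution != "unresolved", , drop = FALSE]
  if (level == "city") {
    geo <- geo[geo$resolution == "city", , drop = FALSE]
    keys <- c("city", "country")
  } else {
    keys <- "country"
  }
  pairs <- dplyr::distinct(geo, .data$record_id,
                           dplyr::across(dplyr::all_of(keys)))
  pairs <- dplyr::inner_join(
    pairs,
    tibble::tibble(record_id = records$record_id,
                   total_citations = records$total_citations,
                   year = records$year),
    by = "record_id")
  rows <- pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_articles = dplyr::n(),
      # per-article median must see the raw counts, so it is computed
      # before the sum shadows the column name
      citations_per_year_median = if (!is.null(reference_year)) {
        median(citations_per_year(.data$total_citations, .data$year,
                                  reference_year))
      } else NA_real_,
      total_citations = sum(.data$total_citations),
      .groups = "drop")
  rows <- rows[, c(keys, "n_articles", "total_citations",
                   "citations_per_year_median")]
  if (is.null(reference_year)) rows$citations_per_year_median <- NULL
  keep <- rows$n_articles >= min_articles
  coverage <- sum(rows$n_articles[keep]) / sum(rows$n_articles)
  out <- rows[keep, , drop = FALSE] |>
    dplyr::arrange(dplyr::desc(.data$n_articles))
  attr(out, "coverage") <- coverage
  attr(out, "attribution") <- attribution
  attr(out, "level") <- level
  out
}

#' Fit the log-log publication-citation relation
#'
#' Ordinary least squares between log10 article counts and log10 citation
#' totals across units. The default direction regresses log10(articles) on
#' log10(citations), the form whose fitted values define the expected
#' article count in [compute_excess()]. R-squared equals the squared Pearson
#' correlation of the two log columns and is therefore identical in both
#' directions.
#'
#' @param rows Aggregate table with `n_articles` and `total_citations`, all
#'   positive, at least 3 units.
#' @param direction `"articles_on_citations"` (default) or
#'   `"citations_on_articles"`.
#' @return Object of class `loglog_fit`: `slope`, `intercept`, `r_squared`,
#'   `residuals` (named by unit, response log10 units), `direction`, `units`.
#' @export
fit_loglog <- function(rows,
                       direction = c("articles_on_citations",
                                     "citations_on_articles")) {
  direction <- match.arg(direction)
  if (nrow(rows) < 3) abort("need at least 3 units to fit")
  if (any(rows$n_articles <= 0) || any(rows$total_citations <= 0)) {
    abort(paste0("zero counts cannot be log-transformed: apply an inclusion ",
                 "threshold (min_articles) before fitting"))
  }
  la <- log10(rows$n_articles)
  lc <- log10(rows$total_citations)
  if (direction == "articles_on_citations") {
    fit <- lm(la ~ lc)
  } else {
    fit <- lm(lc ~ la)
  }
  units <- unit_labels(rows)
  res <- stats::residuals(fit)
  names(res) <- units
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit))$r.squared,
         residuals = res,
         direction = direction, units = units),
    class = "loglog_fit")
}

unit_labels <- function(rows) {
  if ("city" %in% names(rows)) paste(rows$city, rows$country, sep = ", ")
  else rows$country
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat("log-log fit (", x$direction, ")\n", sep = "")
  cat(sprintf("  slope %.4f  intercept %.4f  R^2 %.4f  (%d units)\n",
              x$slope, x$intercept, x$r_squared, length(x$units)))
  invisible(x)
}

#' Excess and deficit articles relative to accumulated citations
#'
#' The expected article count of a unit is the fitted value of the log-log
#' relation at the unit's citation total, back-transformed to the count
#' scale; the excess is observed minus expected, also expressed as a
#' percentage of the observed count. Units publishing at least `flag_pct`
#' percent more (excess) or fewer (deficit) articles than expected are
#' flagged.
#'
#' @param rows The aggregate table the fit was produced from.
#' @param fit A [fit_loglog()] object on the same units.
#' @param flag_pct Flag threshold in percent (default 10).
#' @return Tibble: unit columns, `n_articles`, `total_citations`,
#'   `expected_articles`, `excess_articles`, `excess_pct`, `flag_ge10pct`.
#' @export
compute_excess <- function(rows, fit, flag_pct = 10) {
  units <- unit_labels(rows)
  if (!all(units %in% fit$units)) {
    abort("aggregate table contains units absent from the fit")
  }
  lc <- log10(rows$total_citations)
  la <- log10(rows$n_articles)
  expected <- if (fit$direction == "articles_on_citations") {
    10^(fit$intercept + fit$slope * lc)
  } else {
    10^((lc - fit$intercept) / fit$slope)
  }
  out <- rows
  out$expected_articles <- expected
  out$excess_articles <- rows$n_articles - expected
  out$excess_pct <- 100 * out$excess_articles / rows$n_articles
  out$flag_ge10pct <- abs(out$excess_pct) >= flag_pct
  out
}

#' Literal publication-to-citation log ratio
#'
#' The ratio log10(articles) / log10(citations) for a unit, the direct
#' per-unit form of the international research-impact measure; values above
#' the cross-unit trend indicate publication excess. Counts of 1 or less are
#' rejected because a log10 of 0 (or negative) makes the ratio meaningless.
#'
#' @param n_articles,total_citations Counts, both greater than 1.
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' iri_literal(100, 1000)  # 2/3
iri_literal <- function(n_articles, total_citations) {
  if (any(n_articles <= 1) || any(total_citations <= 1)) {
    abort("iri_literal requires counts > 1 (log10 must be positive)")
  }
  log10(n_articles) / log10(total_citations)
}

#' Population-normalized publication metrics
#'
#' Adds `articles_per_million` (articles per million inhabitants) and, when
#' a per-unit median yearly citation rate is present,
#' `citations_per_article_per_population_per_year` (that median divided by
#' the population in millions). Units with missing population keep `NA` and
#' are flagged.
#'
#' @param rows Country-level aggregate table.
#' @param info [join_population()] output covering the table's countries.
#' @return `rows` with the normalized columns and `population_missing`.
#' @export
population_normalize <- function(rows, info) {
  pop <- info$population[match(rows$country, info$country)]
  out <- rows
  out$population <- pop
  out$articles_per_million <- rows$n_articles / (pop / 1e6)
  if ("citations_per_year_median" %in% names(rows)) {
    out$citations_per_article_per_population_per_year <-
      rows$citations_per_year_median / (pop / 1e6)
  }
  out$population_missing <- is.na(pop)
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks), with the usual t-approximation p-value.
#'
#' @param x,y Numeric vectors of equal length, at least 3, non-constant.
#' @return List: `rho`, `p_value`, `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("constant input: Spearman correlation undefined")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Yearly publication or citation-rate trend for one unit
#'
#' Builds the unit's yearly series and fits an OLS line against calendar
#' year. For `article_count`, years inside the window with no articles
#' contribute zero; for `citations_per_article` such years are omitted (the
#' rate is undefined there).
#'
#' @param records A `wos_records` tibble.
#' @param geos [geolocate_records()] output.
#' @param unit Country name.
#' @param value `"article_count"` or `"citations_per_article"`.
#' @param years Window of years to cover; defaults to the record range.
#' @return List of class `trend_fit`: `unit`, `value`, `slope`, `n_years`,
#'   `data` (year, value tibble).
#' @export
yearly_trend <- function(records, geos,
                         unit, value = c("article_count",
                                         "citations_per_article"),
                         years = NULL) {
  value <- match.arg(value)
  geo <- dplyr::distinct(geos[geos$resolution != "unresolved", ],
                         .data$record_id, .data$country)
  ids <- geo$record_id[geo$country == unit]
  sub <- records[records$record_id %in% ids, , drop = FALSE]
  if (is.null(years)) years <- seq(min(records$year), max(records$year))
  counts <- table(factor(sub$year, levels = years))
  if (value == "article_count") {
    dat <- tibble::tibble(year = years, value = as.numeric(counts))
  } else {
    cites <- tapply(sub$total_citations, factor(sub$year, levels = years), sum)
    dat <- tibble::tibble(year = years,
                          value = as.numeric(cites) / as.numeric(counts))
    dat <- dat[is.finite(dat$value), , drop = FALSE]
  }
  if (length(unique(dat$year[!is.na(dat$value)])) < 2) {
    abort(paste0("need >= 2 distinct years with data for unit ", unit))
  }
  fit <- lm(value ~ year, data = dat)
  structure(list(unit = unit, value = value,
                 slope = unname(coef(fit)[2]), n_years = nrow(dat),
                 data = dat),
            class = "trend_fit")
}

#' Compare two regression slopes via the interaction term
#'
#' Pools both series into one regression with a group indicator and a
#' group-by-predictor interaction; the two-sided t-test on the interaction
#' coefficient tests equality of the slopes.
#'
#' @param a,b Data frames whose first two columns are the predictor (e.g.
#'   year) and the response; each needs at least 3 rows.
#' @return List: `estimate` (slope difference b minus a), `statistic`
#'   (t value), `p_value`, `df`.
#' @export
compare_slopes <- function(a, b) {
  if (nrow(a) < 3 || nrow(b) < 3) abort("each series needs >= 3 points")
  dat <- rbind(
    data.frame(x = a[[1]], y = a[[2]], g = 0),
    data.frame(x = b[[1]], y = b[[2]], g = 1))
  fit <- lm(y ~ x * g, data = dat)
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  if (!"x:g" %in% rownames(sm) || anyNA(sm["x:g", ]) ||
      !is.finite(sm["x:g", "t value"]) ||
      sfit$sigma^2 < 1e-16 * mean(dat$y^2)) {
    abort("degenerate series: interaction slope has no residual variance")
  }
  list(estimate = unname(sm["x:g", "Estimate"]),
       statistic = unname(sm["x:g", "t value"]),
       p_value = unname(sm["x:g", "Pr(>|t|)"]),
       df = fit$df.residual)
}

#' Rank-based group comparisons with multiplicity adjustment
#'
#' Two-group comparisons use the Wilcoxon rank-sum test (unpaired,
#' two-tailed; all pairwise comparisons when more than two groups are
#' supplied); `"kruskal_wallis"` runs one omnibus test across all groups.
#' P-values are Benjamini-Hochberg adjusted within the returned family when
#' `adjust = "BH"`.
#'
#' @param values_by_group Named list of numeric vectors, each non-empty.
#' @param test `"wilcoxon"` or `"kruskal_wallis"`.
#' @param adjust `"BH"` or `"none"`.
#' @return Tibble: `comparison`, `statistic`, `p_value`, `p_adj`.
#' @export
group_compare <- function(values_by_group,
                          test = c("wilcoxon", "kruskal_wallis"),
                          adjust = c("BH", "none")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (length(values_by_group) < 2) abort("need at least 2 groups")
  if (any(lengths(values_by_group) == 0)) abort("empty group supplied")
  if (is.null(names(values_by_group))) {
    names(values_by_group) <- paste0("g", seq_along(values_by_group))
  }
  if (test == "kruskal_wallis") {
    kt <- kruskal.test(values_by_group)
    out <- tibble::tibble(comparison = paste(names(values_by_group),
                                             collapse = " vs "),
                          statistic = unname(kt$statistic),
                          p_value = kt$p.value)
  } else {
    idx <- utils::combn(names(values_by_group), 2, simplify = FALSE)
    out <- purrr::map_dfr(idx, function(pair) {
      wt <- suppressWarnings(
        wilcox.test(values_by_group[[pair[1]]], values_by_group[[pair[2]]],
                    alternative = "two.sided"))
      tibble::tibble(comparison = paste(pair, collapse = " vs "),
                     statistic = unname(wt$statistic), p_value = wt$p.value)
    })
  }
  out$p_adj <- if (adjust == "BH") p.adjust(out$p_value, method = "BH")
               else out$p_value
  out
}

#' Journal-by-country composition of publications
#'
#' Computes each journal's share of articles by country and tests, for each
#' country with enough articles, whether its per-year share differs across
#' journals (Kruskal-Wallis on the per-(journal, year) shares,
#' Benjamini-Hochberg adjusted across countries). Flagged countries are
#' those whose distribution across journals departs from the pooled
#' proportions at the adjusted 5 percent level.
#'
#' @param records A `wos_records` tibble spanning at least 2 journals.
#' @param geos [geolocate_records()] output.
#' @param min_articles Minimum articles for a country to be tested.
#' @param alpha Adjusted significance level for flagging.
#' @return List of class `journal_composition`: `proportions` (journal,
#'   country, n, share), `tests` (country, statistic, p_value, p_adj,
#'   flagged).
#' @export
journal_country_composition <- function(records, geos, min_articles = 10,
                                        alpha = 0.05) {
  if (length(unique(records$journal)) < 2) {
    abort("need at least 2 journals to compare composition")
  }
  geo <- dplyr::distinct(geos[geos$resolution != "unresolved", ],
                         .data$record_id, .data$country)
  dat <- dplyr::inner_join(
    tibble::tibble(record_id = records$record_id,
                   journal = records$journal, year = records$year),
    geo, by = "record_id")
  totals <- dat |> dplyr::count(.data$country, name = "n_total")
  tested <- totals$country[totals$n_total >= min_articles]
  if (length(tested) < 2) abort("fewer than 2 countries pass the threshold")
  props <- dat |>
    dplyr::count(.data$journal, .data$country) |>
    dplyr::group_by(.data$journal) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  # per-(journal, year) share of each tested country; zero share when absent
  jy_totals <- dat |> dplyr::count(.data$journal, .data$year, name = "jy_n")
  tests <- purrr::map_dfr(tested, function(cn) {
    shares <- dat |>
      dplyr::filter(.data$country == cn) |>
      dplyr::count(.data$journal, .data$year) |>
      dplyr::right_join(jy_totals, by = c("journal", "year")) |>
      dplyr::mutate(share = dplyr::coalesce(.data$n, 0L) / .data$jy_n)
    if (stats::sd(shares$share) == 0) {
      # identical shares everywhere: no journal effect by construction
      return(tibble::tibble(country = cn, statistic = 0, p_value = 1))
    }
    kt <- kruskal.test(shares$share, factor(shares$journal))
    tibble::tibble(country = cn, statistic = unname(kt$statistic),
                   p_value = kt$p.value)
  })
  tests$p_adj <- p.adjust(tests$p_value, method = "BH")
  tests$flagged <- tests$p_adj < alpha
  structure(list(proportions = props, tests = tests),
            class = "journal_composition")
}
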