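test_that("a record counts once per distinct country among its addresses", {
  recs <- tibble::tibble(
    record_id = c("r1", "r2"),
    total_citations = c(40L, 6L), year = c(2014L, 2016L))
  geos <- tibble::tibble(
    record_id = c("r1", "r1", "r1", "r2"),
    country = c("USA", "USA", "UK", "USA"),
    resolution = "country")
  agg <- aggregate_by_unit(recs, geos, "country", min_articles = 1)
  usa <- agg[agg$country == "USA", ]
  uk <- agg[agg$country == "UK", ]
  # two USA addresses on r1 collapse to one contribution; the UK address
  # adds the full record (and its citations) there too
  expect_equal(usa$n_articles, 2)
  expect_equal(usa$total_citations, 46)
  expect_equal(uk$n_articles, 1)
  expect_equal(uk$total_citations, 40)
})

test_that("aggregation matches the generator's own tallies and threshold bookkeeping", {
  cfg <- synthetic_config(n_articles = 500, seed = 13)
  recs <- generate_publications(cfg)
  gt <- attr(recs, "ground_truth")
  geos <- fast_geos(recs)
  agg <- aggregate_by_unit(recs, geos, "country", min_articles = 1)
  expect_equal(setNames(agg$n_articles, agg$country)[names(gt$per_country)],
               gt$per_country)
  agg10 <- aggregate_by_unit(recs, geos, "country", min_articles = 10)
  expect_setequal(agg10$country,
                  names(gt$per_country)[gt$per_country >= 10])
})

test_that("log-log fit reproduces closed-form OLS and perfect collinearity", {
  # collinear in log space
  rows <- tibble::tibble(country = c("A", "B", "C"),
                         n_articles = c(10, 100, 1000),
                         total_citations = c(100, 1000, 10000))
  expect_equal(fit_loglog(rows)$r_squared, 1)
  # closed-form OLS oracle on three points
  rows2 <- tibble::tibble(country = c("A", "B", "C"),
                          n_articles = c(10, 100, 1000),
                          total_citations = c(100, 1000, 5000))
  x <- log10(rows2$total_citations); y <- log10(rows2$n_articles)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  r2 <- (sum((x - mean(x)) * (y - mean(y))) /
           sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  fit <- fit_loglog(rows2)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  # R^2 is direction-independent
  expect_equal(fit_loglog(rows2, "citations_on_articles")$r_squared, r2,
               tolerance = 1e-12)
  expect_error(fit_loglog(rows2[1:2, ]), "at least 3")
  rows2$total_citations[1] <- 0
  expect_error(fit_loglog(rows2), "threshold")
})

test_that("excess is zero on the line, residual-balanced, and scale invariant", {
  rows <- tibble::tibble(country = letters[1:5],
                         n_articles = c(20, 50, 120, 400, 1000),
                         total_citations = c(300, 900, 2500, 9000, 30000))
  fit <- fit_loglog(rows)
  ex <- compute_excess(rows, fit)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
  expect_equal(ex$excess_pct, 100 * ex$excess_articles / ex$n_articles)
  expect_equal(ex$flag_ge10pct, abs(ex$excess_pct) >= 10)
  # a unit exactly on the fitted line has zero excess
  on_line <- rows
  on_line$n_articles <- 10^(fit$intercept +
                              fit$slope * log10(rows$total_citations))
  ex0 <- compute_excess(on_line, fit_loglog(on_line))
  expect_equal(ex0$excess_articles, rep(0, 5), tolerance = 1e-9)
  # multiplying all citations by k shifts the intercept, not the excess
  scaled <- rows
  scaled$total_citations <- rows$total_citations * 1000
  ex_scaled <- compute_excess(scaled, fit_loglog(scaled))
  expect_equal(ex_scaled$excess_articles, ex$excess_articles,
               tolerance = 1e-9)
  # reordering rows reorders, never changes, the per-unit excess
  perm <- c(3, 1, 5, 2, 4)
  ex_perm <- compute_excess(rows[perm, ], fit_loglog(rows[perm, ]))
  expect_equal(ex_perm$excess_articles, ex$excess_articles[perm],
               tolerance = 1e-9)
  expect_error(compute_excess(dplyr::mutate(rows, country = LETTERS[1:5]),
                              fit),
               "absent")
})

test_that("the literal log-ratio impact index evaluates exactly", {
  expect_equal(iri_literal(100, 1000), 2 / 3)
  expect_equal(iri_literal(1000, 1000), 1)
  expect_equal(iri_literal(50, 2000), log10(50) / log10(2000))
  expect_error(iri_literal(1, 100), "> 1")
  expect_error(iri_literal(100, 1), "> 1")
})

test_that("population normalization yields articles per million and flags gaps", {
  rows <- tibble::tibble(country = c("Denmark", "Atlantis"),
                         n_articles = c(182, 5),
                         total_citations = c(6600, 50))
  info <- suppressWarnings(
    join_population(rows$country,
                    data.frame(country = "Denmark", population = 5.85e6)))
  out <- population_normalize(rows, info)
  expect_equal(out$articles_per_million[1], 31.1, tolerance = 0.01)
  expect_true(out$population_missing[2])
  expect_true(is.na(out$articles_per_million[2]))
})

test_that("spearman matches an explicit rank-then-Pearson oracle to 1e-12", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(1:10, -(1:10))$rho, -1)
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(30)
    y <- x + rnorm(30)
    y[sample(30, 5)] <- y[1]  # induce ties
    oracle <- cor(rank(x), rank(y))
    expect_equal(spearman_corr(x, y)$rho, oracle, tolerance = 1e-12)
  }
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("yearly trends recover exact, null and injected slopes", {
  years <- 2010:2019
  recs <- make_records_tbl(
    journal = "J", year = rep(years, times = seq(20, 2, by = -2)),
    total_citations = 0L)
  geos <- make_geos_tbl(recs$record_id, "USA")
  tr <- yearly_trend(recs, geos, "USA", "article_count", years = years)
  expect_equal(tr$slope, -2, tolerance = 1e-10)
  # constant series
  recs2 <- make_records_tbl("J", rep(years, each = 5), 0L)
  geos2 <- make_geos_tbl(recs2$record_id, "USA")
  expect_equal(yearly_trend(recs2, geos2, "USA", years = years)$slope, 0,
               tolerance = 1e-10)
  # the rate series drops empty years, so one populated year cannot be fit
  expect_error(yearly_trend(recs2[recs2$year == 2010, ], geos2, "USA",
                            "citations_per_article", years = years),
               "2 distinct years")
  # simulation recovery of an injected drift
  slopes <- vapply(1:120, function(s) {
    cfg <- synthetic_config(n_articles = 1000, seed = 100 + s,
                            trend_slopes = c(USA = -3))
    rs <- generate_publications(cfg)
    yearly_trend(rs, fast_geos(rs), "USA", "article_count",
                 years = 2010:2019)$slope
  }, numeric(1))
  ci <- mean(slopes) + c(-1, 1) *
    stats::qt(0.995, length(slopes) - 1) * sd(slopes) / sqrt(length(slopes))
  expect_gt(-3, ci[1])
  expect_lt(-3, ci[2])
})

test_that("slope comparison is exact under shifts and calibrated under the null", {
  a <- data.frame(x = 1:8, y = 2 * (1:8) + c(0.3, -0.2, 0.1, 0, -0.1, 0.2, -0.3, 0))
  shifted <- a; shifted$y <- a$y + 5
  out <- compare_slopes(a, shifted)
  expect_equal(out$estimate, 0, tolerance = 1e-12)
  # opposite slopes with low noise are detected decisively
  set.seed(8)
  up <- data.frame(x = 1:10, y = 2 * (1:10) + rnorm(10, sd = 0.1))
  down <- data.frame(x = 1:10, y = -2 * (1:10) + rnorm(10, sd = 0.1))
  expect_lt(compare_slopes(up, down)$p_value, 1e-3)
  # null calibration: ~5% rejections at the 5% level
  set.seed(123)
  rejections <- mean(replicate(300, {
    g1 <- data.frame(x = 1:10, y = 1:10 + rnorm(10))
    g2 <- data.frame(x = 1:10, y = 1:10 + rnorm(10))
    compare_slopes(g1, g2)$p_value < 0.05
  }))
  expect_gt(rejections, 0.01)
  expect_lt(rejections, 0.10)
  exact <- data.frame(x = 1:5, y = 2 * (1:5))
  expect_error(compare_slopes(exact, exact), "degenerate")
})

test_that("rank tests behave on degenerate input and BH matches the hand step-up", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  kw <- group_compare(same, test = "kruskal_wallis")
  expect_equal(kw$statistic, 0, tolerance = 1e-12)
  expect_error(group_compare(list(a = 1:3)), "2 groups")
  expect_error(group_compare(list(a = 1:3, b = numeric())), "empty group")
  # hand step-up: p_(i) * n / i with running minima from the largest p
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(7)
  p <- runif(20)
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  oracle <- pmin(1, cummin(p[o] * n / (n:1)))[order(o)]
  expect_equal(p.adjust(p, method = "BH"), oracle, tolerance = 1e-12)
})

test_that("no-effect group comparisons reject at the nominal rate", {
  set.seed(31)
  rejections <- mean(replicate(200, {
    capital <- rnbinom(25, mu = 25, size = 1) / sample(3:12, 25, TRUE)
    other <- rnbinom(25, mu = 25, size = 1) / sample(3:12, 25, TRUE)
    group_compare(list(capital = capital, other = other),
                  test = "wilcoxon")$p_value < 0.05
  }))
  expect_lt(rejections, 0.12)
})

test_that("journal-country composition flags injected affinity, not the null", {
  build <- function(affinity, n = 600, seed) {
    set.seed(seed)
    journals <- c("NEJM", "Lancet", "JAMA", "BMJ", "NatMed")
    countries <- c("USA", "UK", "Canada", "Germany", "France", "Japan")
    cw <- c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1)
    country <- sample(countries, n, TRUE, prob = cw)
    jw <- matrix(rep(c(0.28, 0.23, 0.17, 0.16, 0.15), each = n), n, 5)
    jw[country == "UK", 4] <- jw[country == "UK", 4] * affinity
    journal <- journals[vapply(seq_len(n), function(i)
      sample.int(5, 1, prob = jw[i, ]), integer(1))]
    recs <- make_records_tbl(journal, sample(2010:2019, n, TRUE), 0L)
    list(recs = recs, geos = make_geos_tbl(recs$record_id, country))
  }
  # strong domestic affinity for UK in BMJ is flagged
  d <- build(affinity = 5, seed = 100)
  comp <- journal_country_composition(d$recs, d$geos)
  expect_true(comp$tests$flagged[comp$tests$country == "UK"])
  # under uniform affinity, flags are at most occasional across replicates
  any_flag <- vapply(1:15, function(s) {
    d0 <- build(affinity = 1, n = 400, seed = 200 + s)
    any(journal_country_composition(d0$recs, d0$geos)$tests$flagged)
  }, logical(1))
  expect_lte(mean(any_flag), 0.3)
  # identical composition by construction: H exactly 0, no flags
  recs <- make_records_tbl(rep(c("A", "B"), each = 20),
                           rep(rep(2010:2014, each = 4), 2), 0L)
  geos <- make_geos_tbl(recs$record_id,
                        rep(rep(c("USA", "UK"), each = 2), 10))
  comp0 <- journal_country_composition(recs, geos)
  expect_equal(comp0$tests$statistic, c(0, 0), tolerance = 1e-12)
  expect_false(any(comp0$tests$flagged))
  expect_error(journal_country_composition(
    make_records_tbl("A", 2010:2019, 0L),
    make_geos_tbl(sprintf("r%04d", 1:10), "USA")), "2 journals")
})
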