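test_that("citation matrices densify events over the country union", {
  ev <- data.frame(citing_country = c("A", "A", "B"),
                   cited_country = c("A", "B", "A"),
                   n = c(5L, 2L, 3L))
  m <- build_citation_matrix(ev)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["A", "A"], 5)
  expect_equal(m["B", "B"], 0)
  # duplicate events sum
  m2 <- build_citation_matrix(rbind(ev, ev))
  expect_equal(unclass(m2), unclass(m) * 2, ignore_attr = TRUE)
  expect_error(build_citation_matrix(
    data.frame(citing_country = "A", cited_country = "B", n = -1)),
    "negative")
})

test_that("the generator's event table re-aggregates to its internal tally", {
  cfg <- synthetic_config(n_articles = 300, seed = 21)
  gen <- generate_citations(generate_publications(cfg), cfg)
  m <- build_citation_matrix(gen$events)
  expect_equal(unclass(m), unclass(gen$matrix)[rownames(m), colnames(m)],
               ignore_attr = TRUE)
})

test_that("the self-citation index matches hand evaluation on a 3x3 matrix", {
  m <- build_citation_matrix(expand.grid(
    citing_country = c("A", "B", "C"), cited_country = c("A", "B", "C"),
    stringsAsFactors = FALSE) |>
      dplyr::mutate(n = ifelse(citing_country == cited_country, 8L, 1L)))
  res <- dsci(m, "A")
  expect_equal(res$eq1, 0.8)         # 8 of 10 outgoing are domestic
  expect_equal(res$eq2, 0.1)         # 2 external received / 20 emitted by B,C
  expect_equal(res$dsci, 8)
  # literal variant: external received / citations from A to others = 2/2
  lit <- dsci(m, "A", eq2_variant = "literal")
  expect_equal(lit$eq2, 1)
  expect_equal(lit$dsci, 0.8)
})

test_that("proportional mixing gives an index of exactly 1 for every country", {
  alloc <- c(0.5, 0.3, 0.2)
  totals <- c(1000, 300, 60)
  m <- build_citation_matrix(tidyr::crossing(
    citing_country = c("A", "B", "C"), cited_country = c("A", "B", "C")) |>
      dplyr::mutate(n = totals[match(citing_country, c("A", "B", "C"))] *
                      alloc[match(cited_country, c("A", "B", "C"))]))
  res <- dsci(m)
  expect_equal(res$dsci, rep(1, 3), tolerance = 1e-12)
})

test_that("undefined and degenerate index cases are flagged, not fabricated", {
  # a country receiving no external citations has an undefined index
  m <- build_citation_matrix(data.frame(
    citing_country = c("A", "B", "B"), cited_country = c("A", "A", "B"),
    n = c(4L, 1L, 5L)))
  res <- dsci(m)
  expect_false(res$defined[res$country == "B"])
  expect_true(is.na(res$dsci[res$country == "B"]))
  # zero outgoing citations is an error, not a silent zero
  m2 <- m; m2["B", ] <- 0
  expect_error(dsci(m2, "B"), "outgoing")
})

test_that("the index is scale invariant and monotone in the diagonal", {
  set.seed(5)
  base <- matrix(rpois(25, 20) + 1, 5, 5,
                 dimnames = list(citing = LETTERS[1:5],
                                 cited = LETTERS[1:5]))
  m <- structure(base, class = c("citation_matrix", "matrix", "array"))
  r1 <- dsci(m)
  r2 <- dsci(structure(base * 7, class = class(m)))
  expect_equal(r1$dsci, r2$dsci, tolerance = 1e-12)
  # increasing a country's self-citations strictly increases its index
  grown <- base; grown["C", "C"] <- grown["C", "C"] + 50
  expect_gt(dsci(structure(grown, class = class(m)), "C")$dsci,
            dsci(m, "C")$dsci)
  # eq1 invariant under scaling one row
  row_scaled <- base; row_scaled["D", ] <- base["D", ] * 11
  expect_equal(dsci(structure(row_scaled, class = class(m)), "D")$eq1,
               dsci(m, "D")$eq1, tolerance = 1e-12)
})

test_that("self-citation summaries cover diagonal-dominant and zero-diagonal cases", {
  d <- structure(diag(c(5, 3, 2)) + 0,
                 dimnames = list(citing = c("A", "B", "C"),
                                 cited = c("A", "B", "C")),
                 class = c("citation_matrix", "matrix", "array"))
  expect_equal(self_citation_summary(d)$domestic_share, 1)
  off <- structure(matrix(c(0, 2, 3, 0), 2, 2,
                          dimnames = list(citing = c("A", "B"),
                                          cited = c("A", "B"))),
                   class = c("citation_matrix", "matrix", "array"))
  s <- self_citation_summary(off)
  expect_equal(s$domestic_share, 0)
  expect_equal(s$top_citing$top_citing, c("B", "A"))
})

test_that("fingerprint clustering recovers structure and respects permutations", {
  tmpl <- rbind(c(10, 1, 1, 1), c(1, 10, 1, 1), c(1, 1, 10, 1))
  rows <- tmpl[rep(1:3, each = 3), ]
  rownames(rows) <- paste0("c", 1:9)
  colnames(rows) <- paste0("t", 1:4)
  m <- structure(rows, class = c("citation_matrix", "matrix", "array"))
  cl <- cluster_citing_profiles(m, 3)
  expect_equal(adjusted_rand(cl$labels, rep(1:3, each = 3)), 1)
  expect_match(cl$newick, "^\\(")
  # permuting input rows permutes labels identically
  perm <- c(4, 1, 7, 2, 9, 3, 5, 8, 6)
  clp <- cluster_citing_profiles(
    structure(rows[perm, ], class = class(m)), 3)
  expect_equal(adjusted_rand(clp$labels, cl$labels[perm]), 1)
  # identical rows: degenerate but deterministic
  same <- structure(rows[c(1, 1, 1, 1), ], class = class(m))
  rownames(same) <- paste0("s", 1:4)
  l1 <- cluster_citing_profiles(same, 2)$labels
  l2 <- cluster_citing_profiles(same, 2)$labels
  expect_identical(l1, l2)
  expect_error(cluster_citing_profiles(m, 99), "exceeds")
})

test_that("noisy draws from separated templates cluster back to their template", {
  set.seed(17)
  tmpl <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1),
                c(0.1, 0.1, 0.7, 0.1))
  ari <- replicate(20, {
    truth <- rep(1:3, each = 4)
    rows <- t(vapply(truth, function(g)
      as.vector(rmultinom(1, 400, tmpl[g, ])), numeric(4)))
    dimnames(rows) <- list(paste0("c", 1:12), paste0("t", 1:4))
    cl <- cluster_citing_profiles(
      structure(rows, class = c("citation_matrix", "matrix", "array")), 3)
    adjusted_rand(cl$labels, truth)
  })
  expect_gt(mean(ari), 0.9)
})

test_that("index correlations respond to matched metrics and reject degeneracy", {
  set.seed(9)
  cfg <- synthetic_config(n_articles = 2000, seed = 9, theta_self = 0.4)
  gen <- generate_citations(generate_publications(cfg), cfg)
  d <- dsci(gen$matrix)
  rows <- tibble::tibble(
    country = names(attr(generate_publications(cfg), "ground_truth")$primary_country),
    n_articles = as.integer(attr(generate_publications(cfg), "ground_truth")$primary_country),
    total_citations = colSums(gen$matrix))
  out <- dsci_correlations(d, rows)
  expect_setequal(out$metric, c("total_citations", "n_articles"))
  # under the shared-theta model, the index falls with country size
  expect_lt(out$rho[out$metric == "n_articles"], 0)
  # permuted country labels leave the correlations unchanged
  perm <- sample(nrow(rows))
  out_perm <- dsci_correlations(d[perm, ], rows)
  expect_equal(out_perm$rho, out$rho, tolerance = 1e-12)
  # constant index: flagged NA
  d0 <- d; d0$dsci <- 1
  warns <- testthat::capture_warnings(outc <- dsci_correlations(d0, rows))
  expect_match(warns, "undefined", all = TRUE)
  expect_true(all(is.na(outc$rho)))
  expect_error(dsci_correlations(d[1:2, ], rows[1:2, ]), "3 matched")
})
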