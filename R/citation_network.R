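# Citing-country by cited-country matrix, the Domestic Self-Citation Index,
# and clustering of national citation fingerprints.

#' Build a citing-country by cited-country matrix
#'
#' Aggregates citing events into a dense square matrix over the union of
#' citing and cited countries; duplicate (citing, cited) events sum, unseen
#' pairs are zero. Rows are citing countries, columns cited countries, in
#' one shared alphabetical order.
#'
#' @param events Data frame with columns `citing_country`, `cited_country`,
#'   `n` (non-negative counts).
#' @return Square matrix of class `citation_matrix`.
#' @export
build_citation_matrix <- function(events) {
  stopifnot(all(c("citing_country", "cited_country", "n") %in% names(events)))
  if (any(events$n < 0)) abort("negative citing-event count")
  countries <- sort(unique(c(events$citing_country, events$cited_country)))
  m <- matrix(0, length(countries), length(countries),
              dimnames = list(citing = countries, cited = countries))
  for (k in seq_len(nrow(events))) {
    m[events$citing_country[k], events$cited_country[k]] <-
      m[events$citing_country[k], events$cited_country[k]] + events$n[k]
  }
  structure(m, class = c("citation_matrix", "matrix", "array"))
}

#' Domestic Self-Citation Index
#'
#' For a country a, part one is the share of the country's outgoing
#' citations that it directs at itself: `m[a, a] / sum(m[a, ])`. Part two
#' normalizes this by how much the rest of the world cites the country: the
#' external citations a receives divided by the total citations emitted by
#' all other countries, `sum(m[-a, a]) / sum(m[-a, ])`. The index is the
#' ratio of the two parts and equals 1 exactly under proportional mixing
#' (every citing country allocating its citations in the same proportions).
#'
#' The typeset form of part two's denominator in the source literature is
#' ambiguous; `eq2_variant = "literal"` uses the alternative reading
#' (citations from a to all countries except a) for sensitivity analysis,
#' and `include_diagonal = FALSE` drops other countries' self-citations from
#' the default denominator.
#'
#' @param m A [build_citation_matrix()] matrix.
#' @param countries Countries to evaluate; default all with outgoing
#'   citations.
#' @param eq2_variant `"prose"` (default) or `"literal"`.
#' @param include_diagonal Keep other countries' diagonal in the prose
#'   denominator.
#' @return Tibble: `country`, `eq1`, `eq2`, `dsci`, `defined` (`FALSE` when
#'   the country receives no external citations, leaving the index
#'   undefined).
#' @export
#' @examples
#' m <- build_citation_matrix(data.frame(
#'   citing_country = c("A", "A", "B", "B"),
#'   cited_country = c("A", "B", "A", "B"),
#'   n = c(8, 2, 2, 8)))
#' dsci(m)
dsci <- function(m, countries = NULL, eq2_variant = c("prose", "literal"),
                 include_diagonal = TRUE) {
  eq2_variant <- match.arg(eq2_variant)
  if (sum(m) <= 0) abort("empty citation matrix")
  if (is.null(countries)) countries <- rownames(m)
  if (!all(countries %in% rownames(m))) {
    abort(paste0("country not in matrix: ",
                 paste(setdiff(countries, rownames(m)), collapse = ", ")))
  }
  purrr::map_dfr(countries, function(a) {
    i <- match(a, rownames(m))
    out_total <- sum(m[i, ])
    if (out_total <= 0) abort(paste0(a, " has zero outgoing citations"))
    eq1 <- m[i, i] / out_total
    ext_received <- sum(m[-i, i])
    if (eq2_variant == "prose") {
      denom <- if (include_diagonal) sum(m[-i, ]) else
        sum(m[-i, ]) - sum(diag(m)[-i])
      eq2 <- ext_received / denom
    } else {
      eq2 <- ext_received / sum(m[i, -i])
    }
    defined <- is.finite(eq2) && eq2 > 0
    tibble::tibble(country = a, eq1 = eq1,
                   eq2 = if (is.finite(eq2)) eq2 else NA_real_,
                   dsci = if (defined) eq1 / eq2 else NA_real_,
                   defined = defined)
  })
}

#' Summary of domestic self-citation
#'
#' @param m A citation matrix with positive total.
#' @return List: `domestic_share` (fraction of all citations on the
#'   diagonal), `per_country` (country, eq1 = domestic share of outgoing
#'   citations), `top_citing` (per cited country, the citing country
#'   contributing most of its received citations).
#' @export
self_citation_summary <- function(m) {
  if (sum(m) <= 0) abort("empty citation matrix")
  out_totals <- rowSums(m)
  per_country <- tibble::tibble(
    country = rownames(m),
    eq1 = ifelse(out_totals > 0, diag(m) / out_totals, NA_real_))
  top <- tibble::tibble(
    cited = colnames(m),
    top_citing = rownames(m)[apply(m, 2, which.max)],
    share_of_received = apply(m, 2, function(col) {
      if (sum(col) > 0) max(col) / sum(col) else NA_real_
    }))
  list(domestic_share = sum(diag(m)) / sum(m),
       per_country = per_country, top_citing = top)
}

#' Cluster national citation fingerprints
#'
#' Each citing country's row (its allocation of citations across cited
#' countries) is converted to proportions (optional) and clustered by
#' agglomerative hierarchical clustering with Euclidean distances and the
#' Ward.D2 criterion, cut at `n_clusters` groups. Deterministic: exact
#' distance ties are broken by the merge order of [stats::hclust()], which
#' depends only on row order.
#'
#' @param m A citation matrix.
#' @param n_clusters Number of groups to cut (default 3).
#' @param normalize Convert rows to proportions before clustering.
#' @return List of class `citation_clusters`: `labels` (named integer
#'   vector), `hclust`, `newick` (dendrogram as a Newick string).
#' @export
cluster_citing_profiles <- function(m, n_clusters = 3, normalize = TRUE) {
  if (n_clusters > nrow(m)) {
    abort("n_clusters exceeds the number of citing countries")
  }
  x <- unclass(m)
  if (normalize) {
    rs <- rowSums(x)
    if (any(rs <= 0)) abort("citing country with zero outgoing citations")
    x <- x / rs
  }
  hc <- hclust(dist(x, method = "euclidean"), method = "ward.D2")
  labels <- cutree(hc, k = n_clusters)
  structure(list(labels = labels, hclust = hc,
                 newick = ape::write.tree(ape::as.phylo(hc))),
            class = "citation_clusters")
}

#' Correlate the self-citation index with publication metrics
#'
#' Spearman correlations of the per-country DSCI against total citations,
#' article counts, and (when supplied) absolute and percentage publication
#' excess, over the countries common to all inputs.
#'
#' @param dsci_tbl [dsci()] output.
#' @param rows Country aggregate table (`country`, `n_articles`,
#'   `total_citations`).
#' @param excess Optional [compute_excess()] output.
#' @return Tibble: `metric`, `rho`, `p_value`, `n`; correlations against a
#'   constant index are flagged `NA` with a warning.
#' @export
dsci_correlations <- function(dsci_tbl, rows, excess = NULL) {
  d <- dsci_tbl[dsci_tbl$defined, c("country", "dsci")]
  merged <- dplyr::inner_join(d, rows, by = "country")
  if (!is.null(excess)) {
    merged <- dplyr::inner_join(
      merged,
      excess[, c("country", "excess_articles", "excess_pct")], by = "country")
  }
  if (nrow(merged) < 3) abort("fewer than 3 matched countries")
  metrics <- intersect(
    c("total_citations", "n_articles", "excess_articles", "excess_pct"),
    names(merged))
  purrr::map_dfr(metrics, function(mcol) {
    if (stats::sd(merged$dsci) == 0 || stats::sd(merged[[mcol]]) == 0) {
      warn(paste0("constant input for ", mcol, ": correlation undefined"))
      return(tibble::tibble(metric = mcol, rho = NA_real_,
                            p_value = NA_real_, n = nrow(merged)))
    }
    sc <- spearman_corr(merged$dsci, merged[[mcol]])
    tibble::tibble(metric = mcol, rho = sc$rho, p_value = sc$p_value,
                   n = sc$n)
  })
}
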