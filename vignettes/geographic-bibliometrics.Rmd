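---
title: "Auditing geographic disparity in medical publishing with geobib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing geographic disparity in medical publishing with geobib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geobib)
```

## The problem

Who gets to publish in the most visible medical journals, and whose work
gets cited? geobib turns a tab-delimited publication-metadata export (one
row per article: authors, journal, year, corresponding-author addresses,
accumulated citations) into country- and city-level audit tables that answer
those questions with two simple instruments:

* a **log-log publication-citation regression** whose residuals quantify how
  many more (or fewer) articles a country publishes than its accumulated
  citations predict — its *publication excess* or *deficit*; and
* the **Domestic Self-Citation Index (DSCI)**, which measures how strongly a
  country's researchers cite their own country once the world's general
  interest in that country's work is accounted for.

The package is built around an offline, fully deterministic pipeline: no
geocoding service, no database queries, and a synthetic-data generator that
reproduces the statistical structure of the real data closely enough that
every stage — parsing, geolocation, aggregation, regression, citation-matrix
analysis, clustering — is testable end to end.

## From records to aggregates

Records enter through `parse_wos_export()`, which reads the common
field-tag dialect (AU authors, SO journal, PY year, C1 addresses, TC total
citations). Author counts are text-mined from the semicolon-delimited author
string; the robust default counts non-empty tokens, while `literal = TRUE`
applies the naive "delimiter count plus one" rule, which differs only on
dirty exports with trailing delimiters.

Addresses are resolved by `geolocate_address()` against a packaged gazetteer
(a curated table of roughly 200 cities with approximate coordinates,
populations and capital flags). Matching is country-first: the rightmost
token that canonicalizes to a known country wins, then the longest city
token belonging to that country. This is deliberately precision-oriented —
there is no fuzzy matching by default — and it guarantees that same-named
cities in different countries (London, UK vs London, Canada) never merge,
because city-level units are always (city, country) pairs.

Aggregation follows a *once-per-unit* attribution rule: an article counts
once toward every distinct country (or city) among its corresponding
addresses, and its full citation count is attributed to each such unit. This
is why country totals can exceed the article total; the convention is
recorded in the run metadata of every pipeline run. Units need at least 10
articles over the study window to enter any regression (configurable via
`min_articles`); below that, log-scale counts are dominated by noise and a
single highly cited article can swing the unit across the flag threshold.

### Citations per year

Article impact is compared through citations per year,
`total_citations / max(1, reference_year - publication_year)`. The field
has no standard convention for the denominator; this package counts whole
years from publication to the retrieval year and floors the denominator at
one so articles published in the retrieval year keep their raw count. The
reference year is an explicit argument everywhere it matters and defaults,
in the pipeline, to three years after the window's end (mirroring a
retrieval lag typical of citation snapshots).

## The excess/deficit regression

Across units, log10 citations are very nearly linear in log10 articles.
geobib fits

$$\log_{10}(\text{articles}) = a + b \,\log_{10}(\text{citations})$$

by ordinary least squares and defines, for each unit,

$$\text{excess} = \text{observed} - 10^{\,a + b \log_{10}(\text{citations})},
\qquad \text{excess\%} = 100\cdot\frac{\text{excess}}{\text{observed}}.$$

Units with $|\text{excess\%}| \ge 10$ are flagged. Two conventions were
possible — regress articles on citations, or invert the citations-on-articles
fit — and the package fixes the default by calibration: only the
articles-on-citations form reproduces the excess-article column of the
bundled 32-country reference table (`country_metrics_table()`); the inverse
convention remains available through `direction =` for sensitivity analysis.
$R^2$ is the squared Pearson correlation of the two log columns and is
therefore identical under either direction.

Two numerical properties are worth knowing. First, excess articles are
invariant to any uniform rescaling of citations (the intercept absorbs the
scale), so it does not matter whether citation totals are supplied raw or in
thousands. Second, when citation totals are *rounded* to thousands, the
rounding is material for small units (a printed 0.2 thousand may be anything
from 150 to 249) and tilts the fitted slope enough to move the largest
unit's excess by a few hundred articles.
`excess_rounding_envelope()` propagates exactly this uncertainty by
refitting under uniform redraws inside each rounding interval, and the
package's acceptance checks compare reproduced excess values against that
envelope rather than pretending the rounded table determines them exactly.

The literal per-unit ratio $\log_{10}(\text{articles}) /
\log_{10}(\text{citations})$ is also provided (`iri_literal()`) as a
reporting column; the regression form drives all excess computations because
it is the form that an observed-versus-expected decomposition needs.

## The Domestic Self-Citation Index

From a citing-country × cited-country matrix $m$ (entry $m_{ij}$ = citations
from country $i$ to articles from country $j$), for a country $\alpha$:

$$\text{eq}_1(\alpha) = \frac{m_{\alpha\alpha}}{\sum_j m_{\alpha j}},\qquad
\text{eq}_2(\alpha) = \frac{\sum_{i\neq\alpha} m_{i\alpha}}
{\sum_{i\neq\alpha}\sum_j m_{ij}},\qquad
\text{DSCI}(\alpha) = \frac{\text{eq}_1(\alpha)}{\text{eq}_2(\alpha)}.$$

$\text{eq}_1$ is the share of a country's outgoing citations directed at
itself; $\text{eq}_2$ is the share of the rest of the world's outgoing
citations that the country receives. Their ratio equals 1 exactly under
proportional mixing — when every citing country allocates its citations in
identical proportions — which is the property that makes the ratio the only
natural combination of the two parts: values above 1 measure domestic
preference beyond the world's revealed interest in the country's work.

The normalizing denominator admits a second, literal reading (citations from
$\alpha$ to all countries except $\alpha$); it is implemented behind
`eq2_variant = "literal"` for robustness comparisons, and a flag excludes
other countries' own diagonals from the default denominator. The default is
the proportional reading above, because it is the one under which the
mixing null holds exactly.

The index is undefined for a country that receives no external citations
(eq2 = 0); such countries are flagged rather than assigned a value.
DSCI is invariant to a global rescaling of the matrix, strictly increasing
in the country's own diagonal entry, and — under the generative model below —
has closed form $1 + \theta / ((1-\theta)\,w_\alpha)$, so small countries
show larger indices at equal domestic preference $\theta$.

Citation *fingerprints* (the rows of $m$, as proportions) are clustered with
Ward.D2 agglomeration on Euclidean distances, cut at three groups by
default. Rows are normalized to proportions first, so the clustering groups
citing *patterns* rather than citing *volumes*; absolute-count clustering is
available by flag. Exact-tie merges follow `stats::hclust()`'s deterministic
order, so results are reproducible for a fixed row order.

## The synthetic generator

`synthetic_config()` defines the study conditions the package's tests run
under, chosen to emulate a decade of original articles in five leading
general-medical journals:

* **countries** — ten countries with weights 0.45 (USA), 0.16 (UK), 0.07,
  0.06, 0.05, 0.05, 0.05, 0.04, 0.04, 0.03: the two-country dominance and
  long tail seen in such journals;
* **journals** — five, with US/UK home countries and size shares between
  0.15 and 0.28; `journal_affinity` multiplies a journal's selection weight
  for articles from its home country;
* **citations** — negative binomial (mean 25, dispersion 1): citation counts
  are heavy-tailed, and a Poisson model would badly understate the spread of
  unit totals;
* **theta_self** — the domestic-preference probability: each citation of an
  article is attributed to the article's own country with probability
  $\theta$ and otherwise drawn from the global allocation (countries in
  proportion to article mass). $\theta = 0$ is exact mixing (DSCI = 1);
  $\theta = 1$ leaves every country without external citations (DSCI
  undefined everywhere);
* **trend_slopes** — optional per-country articles-per-year drifts,
  implemented by tilting the (country, year) cell weights of one multinomial
  draw, so injected drifts are recoverable by the trend module without bias;
* about 20% of records carry a second corresponding address drawn from the
  global allocation, exercising the multi-address attribution rule.

`closed_form_expectations()` gives the analytic citation-matrix expectations
under this model and is the oracle for the recovery tests: empirical cells
sit within binomial sampling error of it, and the pipeline recovers country
shares, injected affinity and injected drifts at the tolerances the test
suite states.

What the generator does *not* emulate: article-level citation graphs (only
country-level totals), collaboration networks, journal prestige dynamics,
address-string noise (its addresses always resolve), and any correlation
between citation rate and country beyond what the shared negative binomial
induces. Tests passing on synthetic data therefore validate the machinery
and the statistical behaviour of the estimators, not claims about any
particular real corpus.

## Conventions and numerical choices

* Population normalization uses a packaged World-Bank-style table of 2019
  national populations; back-checking the bundled reference table's
  articles-per-million column against its article counts shows it was
  produced with populations close to the window's final year, so the
  package defaults to the most recent year in the table rather than the
  window midpoint (`population_year` overrides this).
* Records missing year or journal are dropped at parse time and counted;
  unresolvable addresses yield `resolution = "unresolved"` and are reported
  through the pipeline's resolution rate rather than silently discarded.
* Wilcoxon / Kruskal-Wallis comparisons adjust p-values with
  Benjamini-Hochberg within each family (for journal-country composition:
  across countries); a composition test whose per-year shares show no
  variation at all is reported as statistic 0, p 1 rather than NaN.
* Zero counts are rejected by the log-log fit with a pointer to the
  inclusion threshold; counts of 1 are rejected by `iri_literal()` because
  a log10 of 0 cannot be used in a ratio.
* The test suite runs its simulations at deliberately moderate sizes
  (500-10,000 articles, 15-120 replicates per property), sized so each
  property check is stable under its stated tolerance.

## Limitations

City-level conclusions depend on the gazetteer's coverage; the packaged
table covers the countries most active in medical publishing and is meant
to be replaced (`load_gazetteer()`) for other corpora. The excess/deficit
measure inherits the usual caveats of citation analysis — field mix,
article age and document type all move citation rates — and the DSCI is a
country-level summary that cannot distinguish self-citation by authors from
genuine domestic research focus. Neither measure is causal; both are audit
instruments that make geographic asymmetries visible and comparable.
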