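# Reading and preprocessing tab-delimited publication-metadata exports
# (Web of Science field-tag dialect by default).

#' Describe an export dialect
#'
#' Maps the package's record fields onto the column names of a tab-delimited
#' publication-metadata export. The default follows the Web of Science
#' field-tag convention (AU authors, SO journal, DT document type, PY year,
#' C1 addresses, TC total citations, DI DOI, PG page count).
#'
#' @param authors,journal,doc_type,year,address,citations Column names of the
#'   mandatory fields.
#' @param doi,pages Column names of the optional fields.
#' @param address_sep Separator between multiple addresses inside the address
#'   field.
#' @return A named list of class `wos_dialect`.
#' @export
#' @examples
#' wos_dialect()
wos_dialect <- function(authors = "AU", journal = "SO", doc_type = "DT",
                        year = "PY", address = "C1", citations = "TC",
                        doi = "DI", pages = "PG", address_sep = ";") {
  structure(
    list(authors = authors, journal = journal, doc_type = doc_type,
         year = year, address = address, citations = citations,
         doi = doi, pages = pages, address_sep = address_sep),
    class = "wos_dialect"
  )
}

mandatory_fields <- c("authors", "journal", "year", "address", "citations")

#' Parse a publication-metadata export
#'
#' Reads a tab-delimited export (UTF-8, header row) into a normalized record
#' table: one row per article with journal, document type, publication year,
#' raw author string, derived author count, corresponding-author address
#' list, total citations, DOI and page count. Rows missing the year or the
#' journal are dropped; the number of dropped rows is recorded in the
#' `dropped` attribute and reported as a message.
#'
#' @param path Path to the export file.
#' @param dialect A [wos_dialect()] mapping fields to column names.
#' @return A tibble of class `wos_records` with columns `record_id`,
#'   `journal`, `doc_type`, `year`, `authors_raw`, `author_count`,
#'   `addresses` (list column), `total_citations`, `doi`, `page_length`, and
#'   attributes `dropped` (count of rows dropped for missing year/journal)
#'   and `provenance`.
#' @export
parse_wos_export <- function(path, dialect = wos_dialect()) {
  if (!file.exists(path)) {
    abort(paste0("cannot read export file: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = c("", "NA"))
  missing <- mandatory_fields[!unlist(dialect[mandatory_fields]) %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("export header is missing mandatory field(s): ",
                 paste0(missing, " (column '", unlist(dialect[missing]), "')",
                        collapse = ", ")))
  }
  get_col <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  year <- suppressWarnings(as.integer(get_col("year")))
  journal <- get_col("journal")
  keep <- !is.na(year) & !is.na(journal) & nzchar(journal)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " row(s) dropped for missing year or journal")
  }
  addresses <- strsplit(get_col("address")[keep], dialect$address_sep, fixed = TRUE)
  addresses <- lapply(addresses, function(a) {
    a <- trimws(a)
    a[nzchar(a)]
  })
  authors_raw <- get_col("authors")[keep]
  out <- tibble::tibble(
    record_id = sprintf("rec%06d", seq_len(sum(keep))),
    journal = journal[keep],
    doc_type = get_col("doc_type")[keep],
    year = year[keep],
    authors_raw = authors_raw,
    author_count = ifelse(is.na(authors_raw) | !nzchar(authors_raw),
                          NA_integer_, count_authors(authors_raw)),
    addresses = addresses,
    total_citations = suppressWarnings(as.integer(get_col("citations")[keep])),
    doi = get_col("doi")[keep],
    page_length = suppressWarnings(as.integer(get_col("pages")[keep]))
  )
  if (anyNA(out$total_citations)) {
    abort("citation counts must be non-negative integers for every retained row")
  }
  if (any(out$total_citations < 0)) {
    abort("negative citation count in export")
  }
  new_wos_records(out, dropped = dropped,
                  provenance = list(source = path, filters = character()))
}

new_wos_records <- function(x, dropped = 0L, provenance = list()) {
  stopifnot(!anyDuplicated(x$record_id))
  structure(x, dropped = dropped, provenance = provenance,
            class = c("wos_records", class(tibble::tibble())))
}

#' Write records back to the export dialect
#'
#' Inverse of [parse_wos_export()]: serializes a record table to the
#' tab-delimited dialect so that parsing the file again yields
#' field-identical records.
#'
#' @param records A `wos_records` tibble.
#' @param path Output file path.
#' @param dialect A [wos_dialect()].
#' @return `path`, invisibly.
#' @export
write_wos_export <- function(records, path, dialect = wos_dialect()) {
  out <- tibble::tibble(
    !!dialect$authors := records$authors_raw,
    !!dialect$journal := records$journal,
    !!dialect$doc_type := records$doc_type,
    !!dialect$year := as.character(records$year),
    !!dialect$address := vapply(records$addresses, paste,
                                collapse = paste0(dialect$address_sep, " "),
                                FUN.VALUE = character(1)),
    !!dialect$citations := as.character(records$total_citations),
    !!dialect$doi := records$doi,
    !!dialect$pages := as.character(records$page_length)
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Count authors in a delimiter-separated author string
#'
#' Author lists in the export separate names with semicolons. The default
#' counts non-empty tokens after splitting on `;`, which is robust to
#' trailing delimiters in dirty exports. `literal = TRUE` applies the naive
#' rule instead: number of `;` occurrences plus one.
#'
#' @param authors_raw Character vector of author strings.
#' @param literal Use the delimiter-count-plus-one rule verbatim.
#' @return Integer vector of author counts.
#' @export
#' @examples
#' count_authors("Smith J; Doe A")  # 2
count_authors <- function(authors_raw, literal = FALSE) {
  if (any(is.na(authors_raw)) || any(!nzchar(authors_raw))) {
    abort("author field is empty: cannot count authors")
  }
  if (literal) {
    return(vapply(gregexpr(";", authors_raw, fixed = TRUE), function(m) {
      if (m[1] == -1L) 1L else length(m) + 1L
    }, integer(1)))
  }
  vapply(strsplit(authors_raw, ";", fixed = TRUE), function(tok) {
    sum(nzchar(trimws(tok)))
  }, integer(1))
}

#' Filter records by journal, year window and document type
#'
#' @param records A `wos_records` tibble.
#' @param journals Character vector of journal names to retain (mandatory:
#'   an empty set is an error, not "keep everything").
#' @param year_min,year_max Inclusive publication-year window.
#' @param doc_types Document types to retain; `NULL` retains all.
#' @return The filtered `wos_records`, original order preserved; the applied
#'   filter is appended to the `provenance` attribute.
#' @export
filter_records <- function(records, journals, year_min, year_max,
                           doc_types = "Article") {
  if (length(journals) == 0) {
    abort("empty journal set: supply at least one journal name")
  }
  if (year_min > year_max) abort("year_min must be <= year_max")
  keep <- records$journal %in% journals &
    records$year >= year_min & records$year <= year_max
  if (!is.null(doc_types)) keep <- keep & records$doc_type %in% doc_types
  prov <- attr(records, "provenance")
  prov$filters <- c(prov$filters,
                    sprintf("journals=%s; years=%d-%d; doc_types=%s",
                            paste(journals, collapse = ","), year_min, year_max,
                            paste(doc_types %||% "any", collapse = ",")))
  new_wos_records(records[keep, , drop = FALSE],
                  dropped = attr(records, "dropped") %||% 0L,
                  provenance = prov)
}

#' Average citations per year since publication
#'
#' Divides the total citation count by the number of years elapsed between
#' publication and a reference year (typically the data-retrieval year). The
#' denominator is floored at one year so that articles published in the
#' reference year itself get their raw count.
#'
#' @param total_citations Non-negative citation counts.
#' @param year Publication years.
#' @param reference_year Reference (retrieval) year; must not precede any
#'   publication year.
#' @return Numeric vector of citations per year.
#' @export
#' @examples
#' citations_per_year(70, 2015, 2022)  # 10
citations_per_year <- function(total_citations, year, reference_year) {
  if (any(reference_year < year)) {
    abort("reference_year precedes a publication year")
  }
  total_citations / pmax(1, reference_year - year)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
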