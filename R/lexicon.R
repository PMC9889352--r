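# Categorization dictionaries: loading, validation, and priority ordering.
#
# A lexicon is a prioritized phrase -> category dictionary.  Priority (rank)
# implements the categorical hierarchy that disambiguates substring-related
# terms: "non-small cell carcinoma" must be tried before its embedded
# sub-phrase "small cell carcinoma", so longer phrases rank earlier by
# default.

#' Load a categorization lexicon
#'
#' Reads a tab-separated dictionary (`phrase<TAB>category_id[<TAB>rank]`) and
#' its category table (YAML).  Phrases are normalized with [normalize_text()]
#' (lower case, collapsed whitespace, punctuation stripped except intra-word
#' hyphens).  When no explicit rank is given, entries are ranked by descending
#' phrase length with lexicographic tie-break, so that any phrase containing
#' another phrase is matched first — the hierarchy that lets
#' "non-small cell carcinoma" and the sub-string "small cell carcinoma" be
#' separated.
#'
#' For `kind = "diagnosis"` the category table must provide `category_id`,
#' `display_name`, `exclusive_group` (one of benign / suspicious / malignant /
#' insufficient / none) and `group_rank`.  For `kind = "site"` it provides
#' `category_id` and `station_label` (an IASLC/AJCC nodal station such as
#' `"7"`, `"4R"`, `"11L"`).
#'
#' @param path Path to the TSV dictionary.
#' @param kind `"diagnosis"` or `"site"`.
#' @param categories Path to the YAML category table (or a data frame with the
#'   same columns).
#' @return An object of class `mlnqa_lexicon`: a list with `kind`, `entries`
#'   (tibble `phrase`, `category_id`, `rank`, sorted by rank) and `categories`.
#' @examples
#' lex <- default_lexicon("diagnosis")
#' head(lex$entries)
#' @export
load_lexicon <- function(path, kind = c("diagnosis", "site"), categories) {
  kind <- match.arg(kind)
  .assert(file.exists(path), "lexicon file not found: %s", path)
  raw <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                           colClasses = "character", fileEncoding = "UTF-8")
  .assert(all(c("phrase", "category_id") %in% names(raw)),
          "lexicon TSV must have columns 'phrase' and 'category_id'")

  if (is.character(categories)) {
    .assert(file.exists(categories), "category table not found: %s", categories)
    cat_list <- yaml::read_yaml(categories)
    categories <- dplyr::bind_rows(lapply(cat_list, tibble::as_tibble))
  }
  categories <- tibble::as_tibble(categories)
  if (kind == "diagnosis") {
    .assert(all(c("category_id", "display_name", "exclusive_group",
                  "group_rank") %in% names(categories)),
            "diagnosis category table lacks required columns")
    bad <- setdiff(unique(categories$exclusive_group),
                   c(names(.severity), "none"))
    .assert(length(bad) == 0L, "unknown exclusive_group(s): %s",
            paste(bad, collapse = ", "))
  } else {
    .assert(all(c("category_id", "station_label") %in% names(categories)),
            "site category table lacks required columns")
  }
  dup_cat <- categories$category_id[duplicated(categories$category_id)]
  .assert(length(dup_cat) == 0L, "duplicate category_id(s): %s",
          paste(dup_cat, collapse = ", "))

  phrase <- normalize_text(raw$phrase)
  empty <- which(!nzchar(phrase))
  .assert(length(empty) == 0L,
          "lexicon row %d: phrase is empty after normalization", empty[1])
  dup <- unique(phrase[duplicated(phrase)])
  .assert(length(dup) == 0L,
          "duplicate phrase(s) after normalization: %s",
          paste(utils::head(dup, 10), collapse = "; "))
  unknown <- setdiff(unique(raw$category_id), categories$category_id)
  .assert(length(unknown) == 0L,
          "lexicon references unknown category_id(s): %s",
          paste(unknown, collapse = ", "))

  entries <- tibble::tibble(phrase = phrase, category_id = raw$category_id)
  if ("rank" %in% names(raw) && any(nzchar(raw$rank))) {
    entries$rank <- as.integer(raw$rank)
    .assert(!anyNA(entries$rank), "non-integer rank in lexicon")
    entries <- entries[order(entries$rank, -nchar(entries$phrase),
                             entries$phrase), ]
  } else {
    entries <- entries[order(-nchar(entries$phrase), entries$phrase), ]
  }
  entries$rank <- seq_len(nrow(entries))

  lex <- structure(list(kind = kind, entries = entries,
                        categories = categories),
                   class = "mlnqa_lexicon")
  conf <- validate_conflicts(lex)
  unresolved <- conf[!conf$resolved, , drop = FALSE]
  if (nrow(unresolved) > 0) {
    warning(sprintf(
      "%d substring conflict(s) not resolved by rank (contained phrase ranked before containing phrase), e.g. '%s' / '%s'",
      nrow(unresolved), unresolved$phrase_a[1], unresolved$phrase_b[1]),
      call. = FALSE)
  }
  lex
}

#' Packaged default lexicons
#'
#' Returns the dictionary shipped with the package.  These are representative
#' stand-ins built for the synthetic corpus generator and the worked examples
#' — they cover the diagnostic categories and the 24 IASLC/AJCC nodal
#' stations, but are not an institutional dictionary; a site-specific TSV/YAML
#' pair can be dropped in via [load_lexicon()].
#'
#' @param kind `"diagnosis"` or `"site"`.
#' @return An `mlnqa_lexicon` object.
#' @export
default_lexicon <- function(kind = c("diagnosis", "site")) {
  kind <- match.arg(kind)
  tsv <- system.file("extdata", paste0(kind, "_lexicon.tsv"),
                     package = "mlnqa", mustWork = TRUE)
  yml <- system.file("extdata", paste0(kind, "_categories.yaml"),
                     package = "mlnqa", mustWork = TRUE)
  load_lexicon(tsv, kind = kind, categories = yml)
}

#' List substring conflicts between lexicon phrases
#'
#' Returns every ordered pair where one phrase is a proper substring of
#' another and the two map to different categories.  Such pairs are exactly
#' the places where greedy matching could be ambiguous; the pair is `resolved`
#' when the containing (longer) phrase has strictly lower rank, so the greedy
#' matcher tries it first and consumes the span.
#'
#' @param lex An `mlnqa_lexicon`.
#' @return A tibble with columns `phrase_a` (containing), `phrase_b`
#'   (contained), `category_a`, `category_b`, `rank_a`, `rank_b`, `resolved`.
#' @export
validate_conflicts <- function(lex) {
  .assert(inherits(lex, "mlnqa_lexicon"), "not an mlnqa_lexicon")
  e <- lex$entries
  out <- list()
  for (i in seq_len(nrow(e))) {
    shorter <- which(nchar(e$phrase) < nchar(e$phrase[i]))
    if (length(shorter) == 0L) next
    hit <- shorter[vapply(e$phrase[shorter], grepl, logical(1),
                          x = e$phrase[i], fixed = TRUE)]
    hit <- hit[e$category_id[hit] != e$category_id[i]]
    if (length(hit) > 0L) {
      out[[length(out) + 1L]] <- tibble::tibble(
        phrase_a = e$phrase[i], phrase_b = e$phrase[hit],
        category_a = e$category_id[i], category_b = e$category_id[hit],
        rank_a = e$rank[i], rank_b = e$rank[hit],
        resolved = e$rank[i] < e$rank[hit])
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(phrase_a = character(0), phrase_b = character(0),
                          category_a = character(0), category_b = character(0),
                          rank_a = integer(0), rank_b = integer(0),
                          resolved = logical(0)))
  }
  dplyr::bind_rows(out)
}

#' @export
print.mlnqa_lexicon <- function(x, ...) {
  cat(sprintf("<mlnqa_lexicon: %s>  %d phrases -> %d categories\n",
              x$kind, nrow(x$entries), nrow(x$categories)))
  invisible(x)
}

# category_id -> exclusive_group lookup (diagnosis lexicons only)
.group_map <- function(lex) {
  .assert(lex$kind == "diagnosis", "group mapping needs a diagnosis lexicon")
  setNames(lex$categories$exclusive_group, lex$categories$category_id)
}

# category_id -> station_label lookup (site lexicons only)
.station_map <- function(lex) {
  .assert(lex$kind == "site", "station mapping needs a site lexicon")
  setNames(lex$categories$station_label, lex$categories$category_id)
}
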