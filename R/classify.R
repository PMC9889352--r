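# Hierarchical free-text string matching: normalize -> greedy rank-ordered
# phrase matching with span consumption -> per-section category -> severity
# resolution across the mutually exclusive groups.

#' Normalize free text for dictionary matching
#'
#' Lower-cases, replaces punctuation with spaces (keeping hyphens between
#' word characters, so "non-small" survives), collapses whitespace runs and
#' trims.  Idempotent: `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param x Character vector.
#' @return Normalized character vector of the same length.
#' @examples
#' normalize_text("Non-Small  Cell CARCINOMA.")
#' @export
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x[is.na(x)] <- ""
  # protect intra-word hyphens, strip the rest of the punctuation
  x <- gsub("(?<=[[:alnum:]])-(?=[[:alnum:]])", "\x01", x, perl = TRUE)
  x <- gsub("[^[:alnum:]\x01 ]", " ", x)
  x <- gsub("\x01", "-", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Vectorized matcher: for each text, locate occurrences of every lexicon
# phrase, then resolve overlaps greedily in rank order (then left to right):
# a span consumed by an earlier-ranked match blocks any overlapping
# later-ranked match.  Returns a list (one element per text) of data frames
# with columns entry (row index into lex$entries), start, end (0-based,
# half-open, on the normalized text).
.match_many <- function(texts, lex) {
  texts <- normalize_text(texts)
  e <- lex$entries
  n_text <- length(texts)
  hits <- vector("list", nrow(e))
  for (k in seq_len(nrow(e))) {
    g <- gregexpr(e$phrase[k], texts, fixed = TRUE)
    starts <- lapply(g, function(m) if (m[1] == -1L) integer(0)
                     else as.integer(m))
    nh <- lengths(starts)
    idx <- which(nh > 0L)
    if (length(idx) == 0L) next
    hits[[k]] <- data.frame(text = rep.int(idx, nh[idx]),
                            entry = k,
                            start = unlist(starts[idx], use.names = FALSE) - 1L)
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  out <- rep(list(data.frame(entry = integer(0), start = integer(0),
                             end = integer(0))), n_text)
  if (length(hits) == 0L) return(out)
  all <- do.call(rbind, hits)
  all$end <- all$start + nchar(e$phrase[all$entry])
  all <- all[order(all$text, all$entry, all$start), ]
  split_idx <- split(seq_len(nrow(all)), all$text)
  for (tx in names(split_idx)) {
    rows <- split_idx[[tx]]
    s <- all$start[rows]; en <- all$end[rows]
    keep <- logical(length(rows))
    ks <- integer(0); ke <- integer(0)
    for (j in seq_along(rows)) {
      if (!any(s[j] < ke & en[j] > ks)) {
        keep[j] <- TRUE
        ks <- c(ks, s[j]); ke <- c(ke, en[j])
      }
    }
    kept <- rows[keep]
    out[[as.integer(tx)]] <- data.frame(entry = all$entry[kept],
                                        start = all$start[kept],
                                        end = all$end[kept])
  }
  out
}

#' Match lexicon phrases in a text
#'
#' Greedy hierarchical matching: dictionary entries are tried in rank order
#' (by default longest phrase first); each occurrence claims its span of the
#' normalized text, and lower-priority phrases cannot re-match an overlapping
#' span.  This is how "non-small cell carcinoma" wins over its embedded
#' sub-string "small cell carcinoma".
#'
#' @param text A single character string (normalized internally).
#' @param lex An `mlnqa_lexicon`.
#' @return A tibble of match spans: `phrase`, `category_id`, `rank`, `start`,
#'   `end` (0-based, half-open offsets into the normalized text), ordered by
#'   `start`.
#' @export
match_phrases <- function(text, lex) {
  .assert(inherits(lex, "mlnqa_lexicon"), "not an mlnqa_lexicon")
  .assert(length(text) == 1L, "match_phrases() takes a single text")
  m <- .match_many(text, lex)[[1]]
  e <- lex$entries
  res <- tibble::tibble(phrase = e$phrase[m$entry],
                        category_id = e$category_id[m$entry],
                        rank = e$rank[m$entry],
                        start = m$start, end = m$end)
  res[order(res$start), ]
}

#' Resolve the mutually exclusive group for a set of categories
#'
#' The four groups are ordered by severity: malignant > suspicious >
#' insufficient > benign.  A report matching categories in several groups is
#' assigned the highest-severity group present; an empty set is
#' `"unclassified"`.
#'
#' @param category_ids Character vector of diagnosis category ids (may be
#'   empty).
#' @param lex The diagnosis `mlnqa_lexicon` providing the category -> group
#'   mapping.
#' @return One of `"malignant"`, `"suspicious"`, `"insufficient"`,
#'   `"benign"`, `"unclassified"`.
#' @export
resolve_group <- function(category_ids, lex) {
  gm <- .group_map(lex)
  category_ids <- category_ids[!is.na(category_ids)]
  if (length(category_ids) == 0L) return("unclassified")
  unknown <- setdiff(category_ids, names(gm))
  .assert(length(unknown) == 0L, "unknown category id(s): %s",
          paste(unknown, collapse = ", "))
  groups <- gm[category_ids]
  groups <- groups[groups %in% names(.severity)]
  if (length(groups) == 0L) return("unclassified")
  names(.severity)[min(.severity[groups])]
}

# Given span data frames for a set of section texts, pick the section-level
# category: highest-severity group first, earliest offset within that group
# as tie-break.  Returns NA_character_ when nothing matched.
.section_category <- function(spans, lex) {
  if (nrow(spans) == 0L) return(NA_character_)
  e <- lex$entries
  gm <- .group_map(lex)
  cats <- e$category_id[spans$entry]
  sev <- .group_rank(unname(gm[cats]))
  pick <- order(sev, spans$start)[1]
  cats[pick]
}

#' Classify the diagnosis of a single report
#'
#' Sections are matched in chronological order: diagnosis, consultation, then
#' each addendum.  Within a section, if phrases from several categories
#' match, the category whose exclusive group is highest in the severity
#' hierarchy wins, with ties broken by earliest offset.  Across sections the
#' latest classifiable section overrides earlier ones — an addendum refining
#' "non-small cell carcinoma" to "adenocarcinoma" changes the final category
#' and sets `changed_by_addendum`.  A report with no match in any section is
#' `UNCLASSIFIED`.
#'
#' @param record A one-row report corpus tibble (or a list with the same
#'   fields).
#' @param lex The diagnosis `mlnqa_lexicon`.
#' @return A list with `category` (category id or `"UNCLASSIFIED"`),
#'   `exclusive_group`, `changed_by_addendum`, and `matches` (a tibble of all
#'   match spans labelled by `section`).
#' @export
classify_diagnosis <- function(record, lex) {
  record <- as_report_corpus(tibble::as_tibble(record))
  .assert(nrow(record) == 1L, "classify_diagnosis() takes a single record")
  sections <- c(diagnosis = record$diagnosis_text[[1]],
                consult = record$consult_text[[1]])
  add <- record$addenda[[1]]
  if (length(add) > 0) names(add) <- paste0("addendum_", seq_along(add))
  sections <- c(sections, add)
  nonempty <- nzchar(trimws(sections))
  spans <- rep(list(data.frame(entry = integer(0), start = integer(0),
                               end = integer(0))), length(sections))
  if (any(nonempty)) spans[nonempty] <- .match_many(sections[nonempty], lex)

  section_cats <- vapply(spans, .section_category, character(1), lex = lex)
  dx_cat <- section_cats[1]
  classifiable <- which(!is.na(section_cats))
  final <- if (length(classifiable) == 0L) .UNCLASSIFIED
           else section_cats[max(classifiable)]
  changed <- length(classifiable) > 0L && max(classifiable) > 1L &&
    !identical(section_cats[max(classifiable)], dx_cat)

  e <- lex$entries
  match_tbl <- dplyr::bind_rows(lapply(seq_along(spans), function(i) {
    m <- spans[[i]]
    tibble::tibble(section = rep(names(sections)[i], nrow(m)),
                   phrase = e$phrase[m$entry],
                   category_id = e$category_id[m$entry],
                   rank = e$rank[m$entry], start = m$start, end = m$end)
  }))
  group <- if (identical(final, .UNCLASSIFIED)) "unclassified"
           else resolve_group(final, lex)
  list(category = final, exclusive_group = group,
       changed_by_addendum = changed, matches = match_tbl)
}

#' Classify the nodal station of a report
#'
#' Station matching runs on the "source of specimen" section only.  The
#' highest-rank (then earliest) station phrase wins; a report with no station
#' phrase is `UNKNOWN`.
#'
#' @param record A one-row report corpus tibble.
#' @param site_lex The site `mlnqa_lexicon` (phrases and synonyms mapping to
#'   IASLC/AJCC station labels).
#' @return A station label such as `"7"`, `"4R"`, or `"UNKNOWN"`.
#' @export
classify_site <- function(record, site_lex) {
  record <- as_report_corpus(tibble::as_tibble(record))
  .assert(nrow(record) == 1L, "classify_site() takes a single record")
  m <- .match_many(record$source_text[[1]], site_lex)[[1]]
  if (nrow(m) == 0L) return(.UNKNOWN_STATION)
  sm <- .station_map(site_lex)
  pick <- order(m$entry, m$start)[1]
  unname(sm[site_lex$entries$category_id[m$entry[pick]]])
}

#' Classify a whole corpus
#'
#' Applies diagnosis classification ([classify_diagnosis()]), severity-group
#' resolution and station assignment ([classify_site()]) to every record.
#' Deterministic: the same corpus and lexicons always give the same result.
#'
#' @param records A report corpus tibble.
#' @param dx_lex Diagnosis lexicon.
#' @param site_lex Site lexicon.
#' @param keep_matches If `TRUE`, a `matches` list-column with the full match
#'   provenance (phrase, section, offsets) is retained for audit; off by
#'   default to keep large corpora light.
#' @return The input tibble plus columns `diagnosis_category`,
#'   `exclusive_group`, `station`, `changed_by_addendum` (and optionally
#'   `matches`).
#' @export
classify_corpus <- function(records, dx_lex = default_lexicon("diagnosis"),
                            site_lex = default_lexicon("site"),
                            keep_matches = FALSE) {
  records <- as_report_corpus(records)
  n <- nrow(records)
  if (n == 0L) {
    records$diagnosis_category <- character(0)
    records$exclusive_group <- character(0)
    records$station <- character(0)
    records$changed_by_addendum <- logical(0)
    return(records)
  }

  # assemble all diagnosis-bearing section texts into one vector
  sec_record <- seq_len(n)
  sec_order <- rep(1L, n)
  sec_text <- records$diagnosis_text
  has_consult <- nzchar(trimws(records$consult_text))
  sec_record <- c(sec_record, which(has_consult))
  sec_order <- c(sec_order, rep(2L, sum(has_consult)))
  sec_text <- c(sec_text, records$consult_text[has_consult])
  n_add <- lengths(records$addenda)
  if (any(n_add > 0)) {
    add_rec <- rep.int(seq_len(n), n_add)
    add_ord <- 2L + unlist(lapply(n_add[n_add > 0], seq_len), use.names = FALSE)
    sec_record <- c(sec_record, add_rec)
    sec_order <- c(sec_order, add_ord)
    sec_text <- c(sec_text, unlist(records$addenda, use.names = FALSE))
  }

  spans <- .match_many(sec_text, dx_lex)
  sec_cat <- vapply(spans, .section_category, character(1), lex = dx_lex)

  # per record: diagnosis-section category and the latest classifiable one
  dx_cat <- rep(NA_character_, n)
  dx_cat[sec_record[sec_order == 1L]] <- sec_cat[sec_order == 1L]
  hit <- which(!is.na(sec_cat))
  final <- rep(NA_character_, n)
  changed <- rep(FALSE, n)
  if (length(hit) > 0L) {
    o <- hit[order(sec_record[hit], sec_order[hit])]
    last <- o[!duplicated(sec_record[o], fromLast = TRUE)]
    final[sec_record[last]] <- sec_cat[last]
    changed[sec_record[last]] <- sec_order[last] > 1L &
      !mapply(identical, sec_cat[last], dx_cat[sec_record[last]])
  }
  gm <- .group_map(dx_lex)
  group <- unname(gm[final])
  group[is.na(final)] <- "unclassified"
  group[!is.na(group) & group == "none"] <- "unclassified"
  final[is.na(final)] <- .UNCLASSIFIED

  # stations from source_text
  site_spans <- .match_many(records$source_text, site_lex)
  sm <- .station_map(site_lex)
  station <- vapply(site_spans, function(m) {
    if (nrow(m) == 0L) return(.UNKNOWN_STATION)
    pick <- order(m$entry, m$start)[1]
    unname(sm[site_lex$entries$category_id[m$entry[pick]]])
  }, character(1))

  records$diagnosis_category <- final
  records$exclusive_group <- group
  records$station <- station
  records$changed_by_addendum <- changed
  if (keep_matches) {
    e <- dx_lex$entries
    lab <- c("diagnosis", "consult", paste0("addendum_", seq_len(max(c(n_add, 1)))))
    by_rec <- split(seq_along(spans), sec_record)
    records$matches <- lapply(seq_len(n), function(i) {
      ids <- by_rec[[as.character(i)]]
      if (is.null(ids)) ids <- integer(0)
      dplyr::bind_rows(lapply(ids, function(j) {
        m <- spans[[j]]
        tibble::tibble(section = rep(lab[sec_order[j]], nrow(m)),
                       phrase = e$phrase[m$entry],
                       category_id = e$category_id[m$entry],
                       start = m$start, end = m$end)
      }))
    })
  }
  records
}

#' Draw an audit worksheet
#'
#' Seeded uniform sample of classified records, without replacement, with
#' blank human-verdict columns — the manual review step used to estimate how
#' often the string matcher categorizes reports and how often it is right.
#'
#' @param classified A classified corpus ([classify_corpus()]).
#' @param n Sample size (must not exceed the corpus size).
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @return A worksheet tibble with report text, assigned category / station,
#'   and empty `verdict_category` / `verdict_station` columns to be filled
#'   with `"correct"` / `"incorrect"`.
#' @export
audit_sample <- function(classified, n = 500L, seed = 1L) {
  .assert(n <= nrow(classified), "audit sample (%d) exceeds corpus size (%d)",
          n, nrow(classified))
  idx <- withr_seed_sample(nrow(classified), n, seed)
  sampled <- classified[idx, ]
  tibble::tibble(
    specimen_id = sampled$specimen_id,
    source_text = sampled$source_text,
    diagnosis_text = sampled$diagnosis_text,
    diagnosis_category = sampled$diagnosis_category,
    exclusive_group = sampled$exclusive_group,
    station = sampled$station,
    verdict_category = NA_character_,
    verdict_station = NA_character_,
    notes = NA_character_
  )
}

# seeded sampling that does not disturb the caller's RNG stream
withr_seed_sample <- function(pool, n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(pool, n)
}

#' Summarize a filled audit worksheet
#'
#' @param worksheet An [audit_sample()] worksheet with `verdict_category`
#'   filled in (`"correct"` / `"incorrect"`; `NA` rows are ignored for the
#'   accuracy estimate).
#' @return A list with `n`, `pct_categorized` (share of sampled reports the
#'   matcher placed in a category) and `pct_correct` (share of categorized,
#'   reviewed reports judged correct).
#' @export
audit_summary <- function(worksheet) {
  categorized <- worksheet$diagnosis_category != .UNCLASSIFIED
  reviewed <- categorized & !is.na(worksheet$verdict_category)
  list(
    n = nrow(worksheet),
    pct_categorized = mean(categorized),
    pct_correct = if (any(reviewed))
      mean(worksheet$verdict_category[reviewed] == "correct") else NA_real_
  )
}
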