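# Reading, validating and writing pseudonymized report corpora.

.required_fields <- c("specimen_id", "patient_pseudo_id", "sps_id",
                      "pathologist_id", "received_date", "source_text",
                      "diagnosis_text")
.optional_fields <- c("consult_text", "addenda")

#' Validate a report corpus
#'
#' Checks that a tibble of report records carries the required fields
#' (`specimen_id`, `patient_pseudo_id`, `sps_id`, `pathologist_id`,
#' `received_date`, `source_text`, `diagnosis_text`), that identifiers are
#' non-empty opaque tokens, that `specimen_id` is unique, and that dates are
#' ISO-8601.  Missing optional sections (`consult_text`, `addenda`) are filled
#' with empty text / empty lists.  Pseudonymization is assumed done upstream.
#'
#' @param records A data frame of report records; `addenda` may be a
#'   list-column of character vectors (order is preserved).
#' @return A validated tibble with all columns present, addenda as a
#'   list-column.
#' @export
as_report_corpus <- function(records) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(.required_fields, names(records))
  .assert(length(missing_cols) == 0L,
          "corpus is missing required field(s): %s",
          paste(missing_cols, collapse = ", "))
  if (!"consult_text" %in% names(records)) records$consult_text <- ""
  if (!"addenda" %in% names(records)) {
    records$addenda <- replicate(nrow(records), character(0), simplify = FALSE)
  }
  if (!is.list(records$addenda)) {
    records$addenda <- lapply(records$addenda, function(a) {
      if (is.na(a) || !nzchar(a)) character(0) else a
    })
  }
  records$addenda <- lapply(records$addenda, function(a) {
    a <- as.character(a)
    a[!is.na(a) & nzchar(a)]
  })
  records$consult_text[is.na(records$consult_text)] <- ""

  for (f in .required_fields) {
    bad <- which(is.na(records[[f]]))
    .assert(length(bad) == 0L,
            "record %d: required field '%s' is missing", bad[1], f)
  }
  for (f in c("specimen_id", "sps_id", "pathologist_id", "patient_pseudo_id")) {
    bad <- which(!nzchar(trimws(records[[f]])))
    .assert(length(bad) == 0L,
            "record %d: identifier '%s' is empty", bad[1], f)
  }
  dup <- unique(records$specimen_id[duplicated(records$specimen_id)])
  .assert(length(dup) == 0L, "duplicate specimen_id(s): %s",
          paste(utils::head(dup, 10), collapse = ", "))
  bad_date <- which(is.na(suppressWarnings(
    as.Date(records$received_date, format = "%Y-%m-%d"))))
  .assert(length(bad_date) == 0L,
          "record %d: received_date '%s' is not an ISO-8601 date",
          bad_date[1], records$received_date[bad_date[1]])
  records
}

#' Read a report corpus from disk
#'
#' Corpora are stored either as JSON-lines (one record object per line,
#' addenda as a JSON array; the primary format) or CSV (RFC 4180, with the
#' multi-valued addenda joined by the `"|||"` delimiter).
#'
#' @param path Path to an existing `.jsonl` or `.csv` file.
#' @param format `"jsonl"` or `"csv"`; inferred from the file extension when
#'   omitted.
#' @return A tibble of report records (see [as_report_corpus()]).
#' @seealso [write_corpus()] for the inverse operation.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  .assert(file.exists(path), "corpus file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                      error = function(e)
                        .stop("record %d: malformed JSON (%s)", i,
                              conditionMessage(e)))
      rec
    })
    addenda <- lapply(recs, function(r) as.character(r$addenda %||% character(0)))
    scalar <- function(field, default = NA_character_) {
      vapply(recs, function(r) {
        v <- r[[field]]
        if (is.null(v)) default else as.character(v)
      }, character(1))
    }
    records <- tibble::tibble(
      specimen_id = scalar("specimen_id"),
      patient_pseudo_id = scalar("patient_pseudo_id"),
      sps_id = scalar("sps_id"),
      pathologist_id = scalar("pathologist_id"),
      received_date = scalar("received_date"),
      source_text = scalar("source_text"),
      diagnosis_text = scalar("diagnosis_text"),
      consult_text = scalar("consult_text", ""),
      addenda = addenda
    )
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          fileEncoding = "UTF-8")
    if ("addenda" %in% names(df)) {
      df$addenda <- lapply(df$addenda, function(a) {
        if (is.na(a) || !nzchar(a)) character(0)
        else strsplit(a, "|||", fixed = TRUE)[[1]]
      })
    }
    records <- tibble::as_tibble(df)
  }
  as_report_corpus(records)
}

#' Write a report corpus to disk
#'
#' Lossless serialization: `read_corpus()` applied to the written file
#' reproduces the input field-for-field.
#'
#' @param records A report corpus tibble.
#' @param path Output path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @export
write_corpus <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  records <- as_report_corpus(records)
  dir <- dirname(path)
  .assert(dir.exists(dir), "output directory does not exist: %s", dir)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      rec <- list(
        specimen_id = records$specimen_id[i],
        patient_pseudo_id = records$patient_pseudo_id[i],
        sps_id = records$sps_id[i],
        pathologist_id = records$pathologist_id[i],
        received_date = records$received_date[i],
        source_text = records$source_text[i],
        diagnosis_text = records$diagnosis_text[i],
        consult_text = records$consult_text[i],
        addenda = I(records$addenda[[i]])
      )
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    flat <- records
    flat$addenda <- vapply(records$addenda, paste, character(1),
                           collapse = "|||")
    utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Apply the study inclusion criteria
#'
#' A specimen enters the analysis when its "source of specimen" section
#' contains (case-insensitively) the substring `"lymph node"` and at least one
#' of `"EBUS"` or `"EUS"`.  Matching is on the raw text, as substrings, so
#' hyphenated forms such as "EBUS-TBNA" qualify.  The operation is idempotent
#' and preserves record order.
#'
#' @param records A report corpus tibble.
#' @return The subset of `records` meeting the criteria (possibly empty).
#' @export
filter_inclusion <- function(records) {
  records <- as_report_corpus(records)
  src <- tolower(records$source_text)
  keep <- grepl("lymph node", src, fixed = TRUE) &
    (grepl("ebus", src, fixed = TRUE) | grepl("eus", src, fixed = TRUE))
  records[keep, , drop = FALSE]
}
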