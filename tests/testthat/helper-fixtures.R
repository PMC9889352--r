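# In-code fixtures: tiny corpora and a miniature diagnosis lexicon used by
# the unit tests (the packaged dictionaries are exercised separately).

make_record <- function(specimen_id = "S1",
                        source_text = "EBUS FNA, lymph node, station 7.",
                        diagnosis_text = "benign lymphocytes.",
                        consult_text = "",
                        addenda = character(0),
                        sps_id = "SPS1", pathologist_id = "PATH1",
                        received_date = "2015-06-01") {
  tibble::tibble(specimen_id = specimen_id, patient_pseudo_id = "PT1",
                 sps_id = sps_id, pathologist_id = pathologist_id,
                 received_date = received_date, source_text = source_text,
                 diagnosis_text = diagnosis_text, consult_text = consult_text,
                 addenda = list(addenda))
}

make_corpus <- function(...) dplyr::bind_rows(...)

# a small diagnosis lexicon with the substring-conflict structure of the
# full dictionary
mini_dx_lexicon <- function() {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "phrase\tcategory_id",
    "non-small cell carcinoma\tNSCC",
    "small cell carcinoma\tSCLC",
    "adenocarcinoma\tADC",
    "malignant cells\tMAL",
    "negative for malignant cells\tNEG",
    "suspicious for malignancy\tSUSP",
    "insufficient for diagnosis\tINSUF",
    "benign lymphocytes\tBEN"), tsv)
  cats <- tibble::tibble(
    category_id = c("NSCC", "SCLC", "ADC", "MAL", "NEG", "SUSP", "INSUF",
                    "BEN"),
    display_name = category_id,
    exclusive_group = c("malignant", "malignant", "malignant", "malignant",
                        "benign", "suspicious", "insufficient", "benign"),
    group_rank = c(1L, 1L, 1L, 1L, 4L, 2L, 3L, 4L))
  load_lexicon(tsv, kind = "diagnosis", categories = cats)
}

mini_site_lexicon <- function() {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("phrase\tcategory_id",
               "station 7\tst_7", "subcarinal\tst_7",
               "station 4r\tst_4R", "right lower paratracheal\tst_4R",
               "station 11r\tst_11R"), tsv)
  cats <- tibble::tibble(category_id = c("st_7", "st_4R", "st_11R"),
                         station_label = c("7", "4R", "11R"))
  load_lexicon(tsv, kind = "site", categories = cats)
}

# random corpus for round-trip properties
random_corpus <- function(n, seed = 1) {
  withr::with_seed(seed, {
    rand_text <- function(k) {
      vapply(seq_len(k), function(i)
        paste(sample(c(letters, LETTERS, ",", ".", "-", " "), sample(5:40, 1),
                     replace = TRUE), collapse = ""), character(1))
    }
    tibble::tibble(
      specimen_id = sprintf("S%04d", seq_len(n)),
      patient_pseudo_id = sprintf("PT%04d", sample.int(n * 2, n)),
      sps_id = sample(paste0("SPS", 1:3), n, replace = TRUE),
      pathologist_id = sample(paste0("PATH", 1:3), n, replace = TRUE),
      received_date = format(as.Date("2014-01-01") + sample.int(1000, n),
                             "%Y-%m-%d"),
      source_text = rand_text(n),
      diagnosis_text = rand_text(n),
      consult_text = ifelse(runif(n) < 0.5, "", rand_text(n)),
      addenda = lapply(seq_len(n), function(i)
        if (runif(1) < 0.6) character(0) else rand_text(sample(1:3, 1)))
    )
  })
}

# classified-corpus builder with exact group counts (for table arithmetic)
classified_stub <- function(group_counts, station = "7",
                            sps = "SPS1", path = "PATH1") {
  groups <- rep(names(group_counts), unname(group_counts))
  n <- length(groups)
  tibble::tibble(
    specimen_id = sprintf("%s-%s-%05d", station, sps, seq_len(n)),
    sps_id = sps, pathologist_id = path, station = station,
    diagnosis_category = ifelse(groups == "unclassified", "UNCLASSIFIED",
                                groups),
    exclusive_group = groups,
    changed_by_addendum = FALSE)
}
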