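test_that("normalize_text lowercases, strips punctuation, keeps intra-word hyphens, is idempotent", {
  expect_equal(normalize_text("Non-Small  Cell CARCINOMA."),
               "non-small cell carcinoma")
  expect_equal(normalize_text(""), "")
  expect_equal(normalize_text("a - b"), "a b")   # free-standing hyphen drops
  expect_equal(normalize_text("see comment;\n\tstation 4R (left)"),
               "see comment station 4r left")
  withr::with_seed(9, {
    x <- vapply(1:50, function(i)
      paste(sample(c(letters, LETTERS, 0:9, ".", ",", "-", ";", " ", "("),
                   30, replace = TRUE), collapse = ""), character(1))
  })
  expect_equal(normalize_text(normalize_text(x)), normalize_text(x))
})

test_that("greedy matching separates a phrase from its embedded sub-phrase", {
  lex <- mini_dx_lexicon()
  m <- match_phrases("non-small cell carcinoma", lex)
  expect_equal(nrow(m), 1L)
  expect_equal(m$category_id, "NSCC")
  m2 <- match_phrases("small cell carcinoma", lex)
  expect_equal(m2$category_id, "SCLC")
  # negation consumes the embedded malignant phrase
  m3 <- match_phrases("negative for malignant cells", lex)
  expect_equal(m3$category_id, "NEG")
})

test_that("match_phrases equals the brute-force overlap-resolution oracle on random inputs", {
  lex <- mini_dx_lexicon()
  e <- lex$entries
  oracle <- function(text) {
    text <- normalize_text(text)
    consumed <- rep(FALSE, nchar(text))
    kept <- list()
    for (k in seq_len(nrow(e))) {          # rank order
      ph <- e$phrase[k]; ln <- nchar(ph)
      if (ln > nchar(text)) next
      for (o in 0:(nchar(text) - ln)) {    # left to right
        if (substr(text, o + 1, o + ln) == ph &&
            !any(consumed[(o + 1):(o + ln)])) {
          consumed[(o + 1):(o + ln)] <- TRUE
          kept[[length(kept) + 1]] <- c(k, o, o + ln)
        }
      }
    }
    if (length(kept) == 0) {
      return(data.frame(rank = integer(0), start = integer(0),
                        end = integer(0)))
    }
    df <- as.data.frame(do.call(rbind, kept))
    names(df) <- c("rank", "start", "end")
    df[order(df$start), ]
  }
  withr::with_seed(31, {
    filler <- c("the", "specimen", "shows", "and", "with", "cells", "of")
    texts <- vapply(1:60, function(i) {
      bits <- c(sample(e$phrase, sample(0:3, 1), replace = TRUE),
                sample(filler, sample(1:4, 1), replace = TRUE))
      paste(sample(bits), collapse = " ")
    }, character(1))
  })
  for (tx in texts) {
    got <- match_phrases(tx, lex)
    exp <- oracle(tx)
    expect_equal(got$rank, exp$rank, info = tx)
    expect_equal(got$start, exp$start, info = tx)
    expect_equal(got$end, exp$end, info = tx)
  }
})

test_that("diagnosis classification follows section order, severity, and addendum override", {
  lex <- mini_dx_lexicon()
  # latest addendum refines the diagnosis
  r <- make_record(diagnosis_text = "non-small cell carcinoma.",
                   addenda = "immunostains support adenocarcinoma.")
  out <- classify_diagnosis(r, lex)
  expect_equal(out$category, "ADC")
  expect_true(out$changed_by_addendum)
  expect_equal(out$exclusive_group, "malignant")

  # same-category consult is not a change
  r2 <- make_record(diagnosis_text = "benign lymphocytes.",
                    consult_text = "concur: benign lymphocytes.")
  out2 <- classify_diagnosis(r2, lex)
  expect_equal(out2$category, "BEN")
  expect_false(out2$changed_by_addendum)

  # within-section severity: malignant beats benign regardless of order
  r3 <- make_record(diagnosis_text = "benign lymphocytes. adenocarcinoma.")
  expect_equal(classify_diagnosis(r3, lex)$category, "ADC")

  # no match anywhere
  r4 <- make_record(diagnosis_text = "descriptive findings only.")
  out4 <- classify_diagnosis(r4, lex)
  expect_equal(out4$category, "UNCLASSIFIED")
  expect_equal(out4$exclusive_group, "unclassified")
})

test_that("the combined favor-adenocarcinoma wording maps to adenocarcinoma", {
  dx <- default_lexicon("diagnosis")
  r <- make_record(diagnosis_text = "Non-small cell carcinoma, favor adenocarcinoma.")
  expect_equal(classify_diagnosis(r, dx)$category, "adenocarcinoma")
})

test_that("resolve_group applies the severity hierarchy", {
  lex <- mini_dx_lexicon()
  expect_equal(resolve_group(c("BEN", "ADC"), lex), "malignant")
  expect_equal(resolve_group(c("INSUF", "BEN"), lex), "insufficient")
  expect_equal(resolve_group(c("SUSP", "INSUF"), lex), "suspicious")
  expect_equal(resolve_group(character(0), lex), "unclassified")
  expect_error(resolve_group("NOPE", lex), "unknown category")
})

test_that("site classification uses source text, synonyms, and UNKNOWN fallback", {
  site <- mini_site_lexicon()
  expect_equal(classify_site(
    make_record(source_text = "EBUS FNA lymph node, station 4R"), site), "4R")
  expect_equal(classify_site(
    make_record(source_text = "EUS lymph node subcarinal (station 7)"), site), "7")
  expect_equal(classify_site(
    make_record(source_text = "EBUS lymph node, site not specified"), site),
    "UNKNOWN")
})

test_that("classified corpora partition into the five groups and classification is deterministic", {
  cfg <- synthetic_config(n_records = 400, seed = 77, distractor_level = "mild")
  gen <- generate_corpus(cfg)
  cls1 <- classify_corpus(gen$corpus)
  cls2 <- classify_corpus(gen$corpus)
  expect_identical(cls1, cls2)
  tab <- table(factor(cls1$exclusive_group,
                      levels = c("benign", "suspicious", "malignant",
                                 "insufficient", "unclassified")))
  expect_equal(sum(tab), nrow(cls1))
  expect_true(all(cls1$exclusive_group %in% names(tab)))
})

test_that("adding a malignant phrase never lowers the exclusive group", {
  lex <- mini_dx_lexicon()
  sev <- c(malignant = 1, suspicious = 2, insufficient = 3, benign = 4,
           unclassified = 5)
  base_texts <- c("benign lymphocytes.", "suspicious for malignancy.",
                  "insufficient for diagnosis.", "descriptive only.",
                  "small cell carcinoma.")
  for (tx in base_texts) {
    before <- classify_diagnosis(make_record(diagnosis_text = tx), lex)
    after <- classify_diagnosis(
      make_record(diagnosis_text = paste(tx, "malignant cells.")), lex)
    expect_lte(sev[after$exclusive_group], sev[before$exclusive_group])
  }
})

test_that("audit sampling is seeded, and accuracy equals agreement with truth", {
  cfg <- synthetic_config(n_records = 300, seed = 5, distractor_level = "none")
  gen <- generate_corpus(cfg)
  cls <- classify_corpus(gen$corpus)
  w1 <- audit_sample(cls, n = 100, seed = 123)
  w2 <- audit_sample(cls, n = 100, seed = 123)
  expect_identical(w1$specimen_id, w2$specimen_id)
  expect_error(audit_sample(cls, n = 1000, seed = 1), "exceeds")

  truth <- truth_as_classified(gen$truth)
  key <- setNames(truth$diagnosis_category, truth$specimen_id)
  w1$verdict_category <- ifelse(
    w1$diagnosis_category == key[w1$specimen_id], "correct", "incorrect")
  s <- audit_summary(w1)
  expect_equal(s$n, 100)
  expect_equal(s$pct_correct,
               mean((w1$diagnosis_category == key[w1$specimen_id])[
                 w1$diagnosis_category != "UNCLASSIFIED"]))

  all_correct <- w1
  all_correct$verdict_category <- "correct"
  expect_equal(audit_summary(all_correct)$pct_correct, 1.0)
})
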