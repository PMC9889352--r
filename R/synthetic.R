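# Ground-truth synthetic report corpora.
#
# The generator emulates the statistical structure the analysis assumes:
# a station mix, per-station category distributions over the mutually
# exclusive groups, and additive provider effects on the group log-odds,
# rendered to free text through a versioned template bank.  Default
# parameters are chosen so a full-size run resembles a large referral-centre
# MLN-FNA cohort (clearly an emulation, not data).

.default_station_mix <- function() {
  tibble::tibble(
    station = c("7", "4R", "4L", "2R", "10R", "11R", "11L",
                "2L", "5", "8", "9", "10L", "12R"),
    prob = c(0.351, 0.277, 0.146, 0.049, 0.056, 0.040, 0.026,
             0.012, 0.010, 0.009, 0.008, 0.009, 0.007))
}

.default_group_probs <- function(stations) {
  # per-station probability vectors over the five outcome tiers
  named <- list(
    "7"   = c(0.527, 0.037, 0.208, 0.222, 0.006),
    "4R"  = c(0.493, 0.039, 0.268, 0.190, 0.010),
    "4L"  = c(0.419, 0.043, 0.187, 0.346, 0.005),
    "2R"  = c(0.300, 0.053, 0.413, 0.231, 0.003),
    "10R" = c(0.374, 0.050, 0.274, 0.296, 0.006),
    "11R" = c(0.345, 0.048, 0.238, 0.356, 0.013),
    "11L" = c(0.362, 0.070, 0.262, 0.297, 0.009))
  fallback <- c(0.459, 0.042, 0.248, 0.243, 0.008)
  m <- t(vapply(stations, function(s) {
    p <- named[[s]] %||% fallback
    p / sum(p)
  }, numeric(5)))
  colnames(m) <- c("benign", "suspicious", "malignant", "insufficient",
                   "unclassified")
  rownames(m) <- stations
  m
}

.default_category_probs <- function() {
  list(
    benign = c(benign_lymphocytes = 0.46, reactive_lymphoid_hyperplasia = 0.20,
               granulomatous_inflammation = 0.17, negative_for_malignancy = 0.12,
               normal_lymph_node = 0.03, anthracotic_pigment = 0.02),
    suspicious = c(suspicious_malignancy = 0.75, atypical_cells = 0.25),
    malignant = c(adenocarcinoma = 0.27, non_small_cell_carcinoma = 0.25,
                  squamous_cell_carcinoma = 0.10, small_cell_carcinoma = 0.15,
                  carcinoma_nos = 0.09, metastasis = 0.12, lymphoma = 0.01,
                  malignant_nos = 0.005,
                  large_cell_neuroendocrine_carcinoma = 0.003,
                  melanoma = 0.002),
    insufficient = c(insufficient = 0.70, nondiagnostic = 0.30))
}

#' Configure the synthetic corpus generator
#'
#' The defaults emulate a 7.5-year referral-centre cohort: 8,846 specimens,
#' 7 submitting physicians/surgeons and 11 pathologists (each therefore well
#' above the 250-specimen inclusion threshold), 13 nodal stations dominated
#' by stations 7, 4R and 4L, per-station mixes over the four exclusive groups
#' (plus a sub-1% unclassifiable tier), and an addendum process that refines
#' about one in six non-small cell carcinoma reports to a specific subtype
#' (mostly adenocarcinoma).  Patients are assigned to providers uniformly at
#' random, and records are i.i.d.
#'
#' Provider effects act additively on the per-group log-odds before the
#' group is drawn: `sps_effects = list(SPS3 = c(insufficient = log(2.5)))`
#' gives provider SPS3 2.5-fold odds of an insufficient specimen, all else
#' equal.  Because the offset enters one group's log-odds only, the binary
#' group-vs-rest logistic model is correctly specified with exactly that
#' log-odds shift, which is what the regression module estimates.
#'
#' @param n_records Corpus size.
#' @param seed Integer seed; corpora are bit-for-bit reproducible.
#' @param sps_ids,pathologist_ids Provider identifier vectors.
#' @param stations Tibble with `station`, `prob` (must sum to 1).
#' @param base_group_probs Matrix station x group probabilities (rows sum
#'   to 1); defaults derived from the station mix.
#' @param category_probs Named list: per-group category distributions.
#' @param sps_effects,pathologist_effects Named list of named numeric
#'   vectors: per-provider log-odds offsets per group (default none).
#' @param addendum_prob Probability an initially non-small-cell-carcinoma
#'   report gains a refining addendum.
#' @param consult_prob Probability a (non-addendum) report carries a
#'   concurring consultation section.
#' @param distractor_level `"none"`, `"mild"` or `"heavy"` rendering noise.
#' @return An object of class `mlnqa_syn_config`.
#' @export
synthetic_config <- function(n_records = 8846L, seed = 20120701L,
                             sps_ids = paste0("SPS", 1:7),
                             pathologist_ids = sprintf("PATH%02d", 1:11),
                             stations = .default_station_mix(),
                             base_group_probs = NULL,
                             category_probs = .default_category_probs(),
                             sps_effects = NULL,
                             pathologist_effects = NULL,
                             addendum_prob = 0.17,
                             consult_prob = 0.03,
                             distractor_level = c("mild", "none", "heavy")) {
  distractor_level <- match.arg(distractor_level)
  stations <- tibble::as_tibble(stations)
  .assert(abs(sum(stations$prob) - 1) < 1e-8, "station probabilities must sum to 1")
  if (is.null(base_group_probs)) {
    base_group_probs <- .default_group_probs(stations$station)
  }
  .assert(all(rownames(base_group_probs) == stations$station),
          "base_group_probs rows must match stations")
  .assert(all(abs(rowSums(base_group_probs) - 1) < 1e-8),
          "base_group_probs rows must sum to 1")
  for (g in names(category_probs)) {
    .assert(abs(sum(category_probs[[g]]) - 1) < 1e-6,
            "category probabilities for group '%s' must sum to 1", g)
  }
  expand_effects <- function(eff, ids) {
    m <- matrix(0, nrow = length(ids), ncol = 5,
                dimnames = list(ids, colnames(base_group_probs)))
    for (id in names(eff)) {
      .assert(id %in% ids, "effect for unknown provider '%s'", id)
      v <- eff[[id]]
      .assert(all(names(v) %in% colnames(m)),
              "effect for '%s' names unknown group(s)", id)
      m[id, names(v)] <- v
    }
    m
  }
  structure(list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    sps_ids = sps_ids, pathologist_ids = pathologist_ids,
    stations = stations, base_group_probs = base_group_probs,
    category_probs = category_probs,
    sps_effects = expand_effects(sps_effects, sps_ids),
    pathologist_effects = expand_effects(pathologist_effects, pathologist_ids),
    addendum_prob = addendum_prob, consult_prob = consult_prob,
    distractor_level = distractor_level), class = "mlnqa_syn_config")
}

#' @export
print.mlnqa_syn_config <- function(x, ...) {
  cat(sprintf("<mlnqa_syn_config> n = %d, seed = %d, %d SPS, %d pathologists, %d stations, distractors = %s\n",
              x$n_records, x$seed, length(x$sps_ids),
              length(x$pathologist_ids), nrow(x$stations),
              x$distractor_level))
  invisible(x)
}

#' Draw ground-truth records (no text rendering)
#'
#' Samples `n` latent records from the configured model using the current
#' RNG state: station from the configured multinomial, providers uniformly,
#' the exclusive group from the softmax of the station's base log-odds plus
#' the providers' offsets, and the diagnostic category from the within-group
#' distribution.  An initially non-small-cell-carcinoma record is refined by
#' a later addendum with probability `addendum_prob`, in which case
#' `true_category` is the refined category and `original_category` the
#' pre-addendum one.
#'
#' @param config An [synthetic_config()].
#' @param n Number of records (defaults to `config$n_records`).
#' @return A truth tibble: identifiers, `station`, `true_group`,
#'   `true_category` (`NA` for the unclassifiable tier), `original_category`,
#'   `has_addendum`.
#' @seealso [truth_as_classified()] to use the truth labels directly as a
#'   classified corpus; [render_report_text()] to realize the free text.
#' @export
generate_truth <- function(config, n = config$n_records) {
  .assert(inherits(config, "mlnqa_syn_config"), "not an mlnqa_syn_config")
  st_idx <- sample.int(nrow(config$stations), n, replace = TRUE,
                       prob = config$stations$prob)
  sps_idx <- sample.int(length(config$sps_ids), n, replace = TRUE)
  path_idx <- sample.int(length(config$pathologist_ids), n, replace = TRUE)

  logit <- log(pmax(config$base_group_probs[st_idx, , drop = FALSE], 1e-12)) +
    config$sps_effects[sps_idx, , drop = FALSE] +
    config$pathologist_effects[path_idx, , drop = FALSE]
  p <- exp(logit - apply(logit, 1, max))
  p <- p / rowSums(p)
  cum <- p
  for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1]
  u <- stats::runif(n)
  grp_idx <- rowSums(u > cum) + 1L
  grp_idx[grp_idx > ncol(p)] <- ncol(p)
  group <- colnames(p)[grp_idx]

  category <- rep(NA_character_, n)
  for (g in names(config$category_probs)) {
    idx <- which(group == g)
    if (length(idx) == 0) next
    probs <- config$category_probs[[g]]
    category[idx] <- sample(names(probs), length(idx), replace = TRUE,
                            prob = probs)
  }
  original <- category
  is_nscc <- !is.na(category) & category == "non_small_cell_carcinoma"
  refine <- is_nscc & stats::runif(n) < config$addendum_prob
  if (any(refine)) {
    category[refine] <- sample(c("adenocarcinoma", "squamous_cell_carcinoma"),
                               sum(refine), replace = TRUE,
                               prob = c(77, 21) / 98)
  }
  dates <- as.Date("2012-07-01") +
    sample.int(as.integer(as.Date("2019-12-31") - as.Date("2012-07-01")) + 1L,
               n, replace = TRUE) - 1L
  tibble::tibble(
    specimen_id = sprintf("S%07d", seq_len(n)),
    patient_pseudo_id = sprintf("PT%07d", sample.int(n * 5L, n)),
    sps_id = config$sps_ids[sps_idx],
    pathologist_id = config$pathologist_ids[path_idx],
    received_date = format(dates, "%Y-%m-%d"),
    station = config$stations$station[st_idx],
    true_group = group,
    true_category = category,
    original_category = original,
    has_addendum = refine)
}

#' Draw a single ground-truth record
#'
#' @param config An [synthetic_config()].
#' @return A one-row truth tibble (see [generate_truth()]).
#' @export
sample_truth <- function(config) generate_truth(config, n = 1L)

#' Treat truth labels as a classified corpus
#'
#' Re-labels the columns of a truth tibble so it can be fed directly into the
#' tabulation, chart and regression machinery — the oracle classification,
#' bypassing text rendering and the string matcher.
#'
#' @param truth A [generate_truth()] tibble.
#' @return A tibble with `diagnosis_category`, `exclusive_group`, `station`
#'   and provider columns as produced by [classify_corpus()].
#' @export
truth_as_classified <- function(truth) {
  out <- truth
  out$diagnosis_category <- ifelse(is.na(truth$true_category), .UNCLASSIFIED,
                                   truth$true_category)
  out$exclusive_group <- truth$true_group
  out$changed_by_addendum <- truth$has_addendum
  out
}

#' Packaged report template bank
#'
#' @return The template list shipped under `inst/extdata/report_templates.yaml`.
#' @export
default_templates <- function() {
  yaml::read_yaml(system.file("extdata", "report_templates.yaml",
                              package = "mlnqa", mustWork = TRUE))
}

.fill <- function(template, ...) {
  vals <- list(...)
  for (k in names(vals)) {
    template <- sub(paste0("{", k, "}"), vals[[k]], template, fixed = TRUE)
  }
  template
}

#' Render ground-truth records to free-text reports
#'
#' Builds the "source of specimen" section from a modality token (EBUS/EUS),
#' the words "lymph node" and a station synonym drawn from the site lexicon,
#' and the diagnosis section from a template embedding a lexicon phrase of
#' the true category.  Depending on `distractor_level`, neutral prose
#' (`"mild"`) and group-safe lexicon distractors such as negations
#' (`"heavy"`) are appended after the diagnosis phrase.  Records flagged
#' `has_addendum` are rendered with the original (pre-refinement) category in
#' the diagnosis section and the refined category in an addendum, emulating
#' how pathology amendments supersede the original wording.  Unclassifiable
#' records get descriptive prose containing no lexicon phrase.
#'
#' @param truth A [generate_truth()] tibble (any number of rows).
#' @param dx_lex,site_lex Lexicons used for phrase banks (defaults: packaged).
#' @param templates Template bank (default: [default_templates()]).
#' @param distractor_level `"none"`, `"mild"` or `"heavy"`.
#' @param consult_prob Probability of a concurring consultation section.
#' @return A report corpus tibble ([as_report_corpus()]).
#' @export
render_report_text <- function(truth, dx_lex = default_lexicon("diagnosis"),
                               site_lex = default_lexicon("site"),
                               templates = default_templates(),
                               distractor_level = "mild",
                               consult_prob = 0.03) {
  n <- nrow(truth)
  phrase_bank <- split(dx_lex$entries$phrase, dx_lex$entries$category_id)
  sm <- .station_map(site_lex)
  site_bank <- split(site_lex$entries$phrase,
                     sm[site_lex$entries$category_id])

  missing_station <- setdiff(unique(truth$station), names(site_bank))
  .assert(length(missing_station) == 0,
          "no site synonyms for station(s): %s",
          paste(missing_station, collapse = ", "))

  modality <- sample(c("EBUS", "EUS"), n, replace = TRUE, prob = c(0.8, 0.2))
  src_tmpl <- sample(templates$source_templates, n, replace = TRUE)
  site_syn <- vapply(truth$station, function(s) {
    b <- site_bank[[s]]
    b[sample.int(length(b), 1L)]
  }, character(1))
  source_text <- vapply(seq_len(n), function(i)
    .fill(src_tmpl[i], modality = modality[i], site = site_syn[i]),
    character(1))

  pick_phrase <- function(cat) {
    b <- phrase_bank[[cat]]
    b[sample.int(length(b), 1L)]
  }
  dx_tmpl <- sample(templates$diagnosis_templates, n, replace = TRUE)
  diagnosis_text <- character(n)
  for (i in seq_len(n)) {
    if (is.na(truth$original_category[i])) {
      diagnosis_text[i] <- sample(templates$unclassified_texts, 1L)
    } else {
      diagnosis_text[i] <- .fill(dx_tmpl[i],
                                 phrase = pick_phrase(truth$original_category[i]))
    }
  }
  if (distractor_level %in% c("mild", "heavy")) {
    add_mild <- stats::runif(n) < 0.5
    extra <- sample(templates$mild_distractors, n, replace = TRUE)
    diagnosis_text[add_mild] <- paste(diagnosis_text[add_mild],
                                      extra[add_mild])
  }
  if (distractor_level == "heavy") {
    for (i in seq_len(n)) {
      bank <- templates$heavy_distractors[[truth$true_group[i]]]
      if (length(bank) > 0 && stats::runif(1) < 0.8) {
        diagnosis_text[i] <- paste(diagnosis_text[i], sample(bank, 1L))
      }
    }
  }

  consult_text <- rep("", n)
  can_consult <- !truth$has_addendum & !is.na(truth$original_category)
  gets_consult <- can_consult & stats::runif(n) < consult_prob
  for (i in which(gets_consult)) {
    consult_text[i] <- .fill(sample(templates$consult_templates, 1L),
                             phrase = pick_phrase(truth$original_category[i]))
  }

  addenda <- replicate(n, character(0), simplify = FALSE)
  for (i in which(truth$has_addendum)) {
    addenda[[i]] <- .fill(sample(templates$addendum_templates, 1L),
                          phrase = pick_phrase(truth$true_category[i]))
  }

  as_report_corpus(tibble::tibble(
    specimen_id = truth$specimen_id,
    patient_pseudo_id = truth$patient_pseudo_id,
    sps_id = truth$sps_id,
    pathologist_id = truth$pathologist_id,
    received_date = truth$received_date,
    source_text = source_text,
    diagnosis_text = diagnosis_text,
    consult_text = consult_text,
    addenda = addenda))
}

#' Generate a synthetic corpus with ground truth
#'
#' Seeds the RNG from the config, draws the latent truth, renders the free
#' text, and optionally writes both files (corpus as JSONL/CSV, truth as
#' JSONL keyed by `specimen_id`) together with a small metadata sidecar
#' recording the seed and a config hash.
#'
#' @param config An [synthetic_config()].
#' @param corpus_path,truth_path Optional output paths.
#' @param format Corpus file format, `"jsonl"` or `"csv"`.
#' @return Invisibly, a list with `corpus` and `truth` tibbles.
#' @export
generate_corpus <- function(config, corpus_path = NULL, truth_path = NULL,
                            format = c("jsonl", "csv")) {
  format <- match.arg(format)
  set.seed(config$seed)
  truth <- generate_truth(config)
  corpus <- render_report_text(truth,
                               distractor_level = config$distractor_level,
                               consult_prob = config$consult_prob)
  if (!is.null(corpus_path)) {
    write_corpus(corpus, corpus_path, format = format)
    meta <- list(seed = config$seed, n_records = config$n_records,
                 distractor_level = config$distractor_level,
                 config_hash = rlang::hash(config))
    jsonlite::write_json(meta, paste0(corpus_path, ".meta.json"),
                         auto_unbox = TRUE)
  }
  if (!is.null(truth_path)) {
    lines <- vapply(seq_len(nrow(truth)), function(i)
      as.character(jsonlite::toJSON(as.list(truth[i, ]), auto_unbox = TRUE,
                                    na = "null")),
      character(1))
    writeLines(lines, truth_path, useBytes = TRUE)
  }
  invisible(list(corpus = corpus, truth = truth))
}
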