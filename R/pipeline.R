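# Orchestration: simulate (or read) -> classify -> tabulate -> charts ->
# regression, with a reproducible manifest.

#' Assemble a pipeline run configuration
#'
#' @param synthetic An [synthetic_config()] to simulate a corpus, or `NULL`
#'   to read `corpus_path`.
#' @param corpus_path Path to an existing corpus (ignored when `synthetic`
#'   is given).
#' @param dx_lexicon,site_lexicon TSV paths or `mlnqa_lexicon` objects
#'   (defaults: packaged dictionaries).
#' @param dx_categories,site_categories Category table paths (used when the
#'   lexicons are given as TSV paths).
#' @param min_n Provider inclusion threshold (default 250).
#' @param min_station Station inclusion threshold (default 20).
#' @param alphas Chart significance levels, descending.
#' @param normalization `"indirect"` (station case-mix standardized) or
#'   `"raw"`.
#' @param regression_outcomes Outcomes to model; defaults to the four
#'   exclusive groups plus the main cancer subtypes.
#' @param render_images Also write PNG charts (chart JSON is always written).
#' @return A named list (class `mlnqa_run_config`).
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            corpus_path = NULL,
                            dx_lexicon = NULL, site_lexicon = NULL,
                            dx_categories = NULL, site_categories = NULL,
                            min_n = 250L, min_station = 20L,
                            alphas = c(0.05, 1e-3, 1e-6, 1e-12),
                            normalization = c("indirect", "raw"),
                            regression_outcomes = c(
                              "benign", "suspicious", "malignant",
                              "insufficient", "adenocarcinoma",
                              "squamous_cell_carcinoma",
                              "non_small_cell_carcinoma",
                              "small_cell_carcinoma"),
                            render_images = FALSE) {
  normalization <- match.arg(normalization)
  .assert(all(diff(alphas) < 0), "alphas must be sorted descending")
  structure(list(synthetic = synthetic, corpus_path = corpus_path,
                 dx_lexicon = dx_lexicon, site_lexicon = site_lexicon,
                 dx_categories = dx_categories,
                 site_categories = site_categories,
                 min_n = as.integer(min_n),
                 min_station = as.integer(min_station),
                 alphas = alphas, normalization = normalization,
                 regression_outcomes = regression_outcomes,
                 render_images = render_images),
            class = "mlnqa_run_config")
}

.resolve_lexicon <- function(spec, kind, categories) {
  if (is.null(spec)) return(default_lexicon(kind))
  if (inherits(spec, "mlnqa_lexicon")) return(spec)
  load_lexicon(spec, kind = kind,
               categories = categories %||%
                 system.file("extdata", paste0(kind, "_categories.yaml"),
                             package = "mlnqa", mustWork = TRUE))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, na = "null",
                       pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (or load) the corpus, apply the
#' inclusion filter, classify, tabulate the cohort and per-provider rates,
#' build provider charts for both roles and all four exclusive groups, fit
#' the per-category regressions with ROC curves — and writes every artifact
#' plus a run manifest into `out_dir`.  Re-running with the same config and
#' seed reproduces all non-image outputs byte-identically.  On a stage
#' failure the manifest (recording the failed stage and the error) is still
#' written, and the error is re-signalled.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the synthetic config's seed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  .assert(inherits(config, "mlnqa_run_config"), "not an mlnqa_run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "charts"), showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("mlnqa")),
                   config_hash = rlang::hash(config),
                   seed = seed %||% (if (!is.null(config$synthetic))
                     config$synthetic$seed else NA),
                   stages = list(), status = "ok")
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "error",
                                      error = conditionMessage(err))
    manifest$status <<- "error"
    .write_json(manifest, file.path(out_dir, "manifest.json"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(err)), call. = FALSE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) fail(name, e))
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  lex <- stage("lexicons", {
    list(dx = .resolve_lexicon(config$dx_lexicon, "diagnosis",
                               config$dx_categories),
         site = .resolve_lexicon(config$site_lexicon, "site",
                                 config$site_categories))
  })

  corpus <- stage("corpus", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      if (!is.null(seed)) syn$seed <- as.integer(seed)
      gen <- generate_corpus(syn,
                             corpus_path = file.path(out_dir, "corpus.jsonl"),
                             truth_path = file.path(out_dir, "truth.jsonl"))
      gen$corpus
    } else {
      read_corpus(config$corpus_path)
    }
  })

  classified <- stage("classify", {
    cls <- classify_corpus(filter_inclusion(corpus), lex$dx, lex$site)
    flat <- cls[, c("specimen_id", "sps_id", "pathologist_id", "station",
                    "diagnosis_category", "exclusive_group",
                    "changed_by_addendum")]
    utils::write.csv(flat, file.path(out_dir, "classified.csv"),
                     row.names = FALSE)
    cls
  })

  stage("tables", {
    t1 <- tabulate_groups(classified)
    .write_json(list(total = attr(t1, "total"),
                     groups = as.data.frame(t1)),
                file.path(out_dir, "group_table.json"))
    utils::write.csv(as.data.frame(t1), file.path(out_dir, "group_table.csv"),
                     row.names = FALSE)
    t2 <- tabulate_by_station(classified)
    .write_json(as.data.frame(t2), file.path(out_dir, "station_table.json"))
    utils::write.csv(as.data.frame(t2),
                     file.path(out_dir, "station_table.csv"),
                     row.names = FALSE)
    NULL
  })

  charts <- stage("charts", {
    out <- list()
    for (role in c("pathologist", "sps")) {
      rates <- provider_rates(classified, role = role, min_n = config$min_n)
      .write_json(list(role = role, gmr = as.list(rates$gmr),
                       table = rates$table),
                  file.path(out_dir, sprintf("provider_rates_%s.json", role)))
      for (grp in c("benign", "suspicious", "malignant", "insufficient")) {
        ch <- build_chart(rates, grp, alphas = config$alphas,
                          mode = config$normalization,
                          classified = classified)
        base <- file.path(out_dir, "charts", sprintf("%s_%s", role, grp))
        .write_json(chart_data(ch), paste0(base, ".json"))
        if (isTRUE(config$render_images)) {
          render_chart(ch, "control_chart", paste0(base, "_control.png"))
          render_chart(ch, "funnel", paste0(base, "_funnel.png"))
        }
        out[[sprintf("%s_%s", role, grp)]] <- ch
      }
    }
    out
  })

  stage("regression", {
    design <- trim_design(classified, min_n = config$min_n,
                          min_station = config$min_station)
    results <- list(trimmed_n = design$n,
                    levels = lapply(design$levels, length),
                    test_type = "likelihood_ratio",
                    models = list())
    for (oc in config$regression_outcomes) {
      m <- tryCatch(fit_category_model(design, oc), error = function(e) NULL)
      if (is.null(m)) {
        results$models[[oc]] <- list(status = "skipped")
        next
      }
      roc <- roc_from_model(m)
      results$models[[oc]] <- list(
        status = "ok", n = m$n, converged = m$converged,
        separation = m$separation,
        factor_tests = m$factor_tests,
        coefficients = m$coefficients, auc = roc$auc)
      utils::write.table(roc$points,
                         file.path(out_dir, sprintf("roc_%s.tsv", oc)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    .write_json(results, file.path(out_dir, "regression.json"))
    NULL
  })

  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
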