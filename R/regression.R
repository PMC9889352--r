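# Multivariable categorical logistic regression: submitting physician,
# pathologist and nodal station as additive factors, with per-factor
# likelihood-ratio tests and in-sample ROC curves.

#' Trim a classified corpus for regression
#'
#' Over-fitting protection: drops records whose submitting physician/surgeon
#' or pathologist has fewer than `min_n` specimens in the corpus, whose
#' station has fewer than `min_station` records, or whose station is
#' `UNKNOWN`.  The remaining factors are releveled with the highest-volume
#' level as reference (for coefficient stability).
#'
#' @param classified A classified corpus.
#' @param min_n Provider volume threshold (default 250).
#' @param min_station Station record threshold (default 20).
#' @return An object of class `mlnqa_design`: list with `data` (tibble with
#'   factor columns `sps`, `pathologist`, `station` plus the classification
#'   columns), `n`, per-factor level counts, and the thresholds used.
#' @export
trim_design <- function(classified, min_n = 250L, min_station = 20L) {
  .assert(nrow(classified) > 0, "empty corpus")
  sps_n <- table(classified$sps_id)
  path_n <- table(classified$pathologist_id)
  stn_n <- table(classified$station)
  keep_sps <- names(sps_n)[sps_n >= min_n]
  keep_path <- names(path_n)[path_n >= min_n]
  keep_stn <- setdiff(names(stn_n)[stn_n >= min_station], .UNKNOWN_STATION)
  .assert(length(keep_sps) >= 2, "fewer than 2 SPS with n >= %d", min_n)
  .assert(length(keep_path) >= 2, "fewer than 2 pathologists with n >= %d",
          min_n)
  .assert(length(keep_stn) >= 2, "fewer than 2 stations with n >= %d",
          min_station)
  keep <- classified$sps_id %in% keep_sps &
    classified$pathologist_id %in% keep_path &
    classified$station %in% keep_stn
  data <- classified[keep, , drop = FALSE]
  by_volume <- function(x) names(sort(table(x), decreasing = TRUE))
  data$sps <- factor(data$sps_id, levels = by_volume(data$sps_id))
  data$pathologist <- factor(data$pathologist_id,
                             levels = by_volume(data$pathologist_id))
  data$station <- factor(data$station, levels = by_volume(data$station))
  structure(list(data = data, n = nrow(data),
                 levels = list(sps = levels(data$sps),
                               pathologist = levels(data$pathologist),
                               station = levels(data$station)),
                 min_n = min_n, min_station = min_station,
                 n_dropped = sum(!keep)),
            class = "mlnqa_design")
}

#' @export
print.mlnqa_design <- function(x, ...) {
  cat(sprintf("<mlnqa_design> %d specimens (%d dropped); %d SPS, %d pathologists, %d stations\n",
              x$n, x$n_dropped, length(x$levels$sps),
              length(x$levels$pathologist), length(x$levels$station)))
  invisible(x)
}

#' Fit a per-category logistic model
#'
#' Maximum-likelihood logistic regression of a binary outcome (membership in
#' an exclusive group, or in a specific diagnostic category) on the additive
#' categorical factors SPS + pathologist + station.  Each factor's overall
#' significance is a likelihood-ratio test of the full model against the
#' model without that factor, on `levels - 1` degrees of freedom (a Type-3
#' style test; preferred over Wald for small cells).  Wald odds ratios and
#' 95% CIs are reported per non-reference level.
#'
#' @param design An [trim_design()] result.
#' @param outcome An exclusive group (`"benign"`, `"suspicious"`,
#'   `"malignant"`, `"insufficient"`) or a diagnosis category id present in
#'   the design.
#' @return An object of class `mlnqa_model`: list with `outcome`, `n`,
#'   `coefficients` (tibble of log-odds, odds ratios, Wald CIs),
#'   `factor_tests` (tibble `factor`, `df`, `statistic`, `p_value`),
#'   `converged`, `separation`, and the underlying `glm` fit.
#' @export
fit_category_model <- function(design, outcome) {
  .assert(inherits(design, "mlnqa_design"), "not an mlnqa_design")
  data <- design$data
  y <- if (outcome %in% .group_levels) {
    data$exclusive_group == outcome
  } else if (outcome %in% data$diagnosis_category) {
    data$diagnosis_category == outcome
  } else {
    .stop("outcome '%s' is neither an exclusive group nor a category present in the design",
          outcome)
  }
  .assert(length(unique(y)) == 2,
          "outcome '%s' is constant in the trimmed design", outcome)
  data$.y <- as.integer(y)

  full <- suppressWarnings(
    stats::glm(.y ~ sps + pathologist + station, family = stats::binomial(),
               data = data))
  separation <- any(fitted(full) < 1e-8 | fitted(full) > 1 - 1e-8)
  factors <- c("sps", "pathologist", "station")
  tests <- lapply(factors, function(f) {
    reduced_form <- stats::as.formula(
      paste(".y ~", paste(setdiff(factors, f), collapse = " + ")))
    reduced <- suppressWarnings(
      stats::glm(reduced_form, family = stats::binomial(), data = data))
    lr <- as.numeric(2 * (stats::logLik(full) - stats::logLik(reduced)))
    df <- reduced$df.residual - full$df.residual
    tibble::tibble(factor = f, df = df, statistic = lr,
                   p_value = stats::pchisq(lr, df, lower.tail = FALSE))
  })
  est <- summary(full)$coefficients
  coefs <- tibble::tibble(
    term = rownames(est),
    estimate = est[, "Estimate"],
    std_error = est[, "Std. Error"],
    odds_ratio = exp(est[, "Estimate"]),
    or_low = exp(est[, "Estimate"] - 1.96 * est[, "Std. Error"]),
    or_high = exp(est[, "Estimate"] + 1.96 * est[, "Std. Error"]),
    p_value = est[, "Pr(>|z|)"])
  structure(list(outcome = outcome, n = nrow(data),
                 coefficients = coefs,
                 factor_tests = dplyr::bind_rows(tests),
                 converged = full$converged, separation = separation,
                 fit = full),
            class = "mlnqa_model")
}

#' @export
print.mlnqa_model <- function(x, ...) {
  cat(sprintf("<mlnqa_model: %s>  n = %d, converged = %s%s\n", x$outcome, x$n,
              x$converged, if (x$separation) " (separation suspected)" else ""))
  df <- as.data.frame(x$factor_tests)
  df$p_value <- format.pval(df$p_value, digits = 3, eps = 1e-4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' In-sample ROC curve from a fitted model
#'
#' Thresholds the in-sample predicted probabilities at every unique value and
#' computes the ROC curve; the area is by the trapezoid rule (equivalently
#' the rank statistic).
#'
#' @param model An `mlnqa_model`.
#' @return A list: `points` (tibble `fpr`, `tpr`, ascending) and `auc`.
#' @export
roc_from_model <- function(model) {
  .assert(inherits(model, "mlnqa_model"), "not an mlnqa_model")
  scores <- as.numeric(fitted(model$fit))
  y <- as.numeric(model$fit$y)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  .assert(n_pos > 0 && n_neg > 0, "ROC needs both classes")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  # collapse ties: keep the last index of each run of equal scores
  last <- c(ss[-1] != ss[-length(ss)], TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = tibble::tibble(fpr = fpr, tpr = tpr), auc = auc)
}
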