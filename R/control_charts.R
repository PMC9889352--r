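# Funnel plots / control charts centred on the group median rate, with
# exact binomial control limits and per-alpha outlier flags.
#
# Limits are obtained by exact CDF inversion rather than a normal
# approximation: the outer bands sit at alpha = 1e-6 and 1e-12, far in the
# tails where the Gaussian approximation to the binomial is unusable.

#' Exact binomial control limits
#'
#' For a provider with volume `n` and a centre rate `p0` (the group median
#' rate), the lower control limit is the largest count `k` with
#' `P(X <= k - 1) <= alpha/2` and the upper limit the smallest `k` with
#' `P(X >= k + 1) <= alpha/2` under `X ~ Binomial(n, p0)`; both are returned
#' as rates.  Because the binomial is discrete the achieved coverage is at
#' least `1 - alpha` (conservative).  Limits nest across alpha (smaller alpha,
#' wider band) and narrow weakly as `n` grows.
#'
#' @param n Provider volume (>= 1).
#' @param p0 Centre rate in `[0, 1]`.
#' @param alpha Two-sided significance level in `(0, 1)`; the chart bands use
#'   0.05, 1e-3, 1e-6 and 1e-12.
#' @return A list: `alpha`, `n`, `p0`, `k_lower`, `k_upper` (limit counts),
#'   `lower`, `upper` (limit rates).  A count strictly below `k_lower` or
#'   strictly above `k_upper` is out of control; ties with the limit count are
#'   in control.
#' @export
binomial_limits <- function(n, p0, alpha) {
  .assert(length(n) == 1 && n >= 1 && n == as.integer(n),
          "n must be a single positive integer")
  .assert(length(p0) == 1 && p0 >= 0 && p0 <= 1, "p0 must be in [0, 1]")
  .assert(length(alpha) == 1 && alpha > 0 && alpha < 1,
          "alpha must be in (0, 1)")
  half <- alpha / 2
  if (p0 == 0) {
    k_lo <- 0L; k_up <- 0L
  } else if (p0 == 1) {
    k_lo <- as.integer(n); k_up <- as.integer(n)
  } else {
    # largest k with P(X <= k-1) <= half; seed with qbinom then adjust
    k_lo <- stats::qbinom(half, n, p0)
    while (k_lo < n && stats::pbinom(k_lo, n, p0) <= half) k_lo <- k_lo + 1L
    while (k_lo > 0 && stats::pbinom(k_lo - 1L, n, p0) > half) k_lo <- k_lo - 1L
    # smallest k with P(X >= k+1) <= half, i.e. P(X <= k) >= 1 - half
    k_up <- stats::qbinom(1 - half, n, p0)
    while (k_up > 0 &&
           stats::pbinom(k_up - 1L, n, p0, lower.tail = FALSE) <= half)
      k_up <- k_up - 1L
    while (k_up < n &&
           stats::pbinom(k_up, n, p0, lower.tail = FALSE) > half)
      k_up <- k_up + 1L
  }
  list(alpha = alpha, n = as.integer(n), p0 = p0,
       k_lower = as.integer(k_lo), k_upper = as.integer(k_up),
       lower = k_lo / n, upper = k_up / n)
}

#' Two-sided exact binomial tail probability
#'
#' `2 * min(P(X <= k), P(X >= k))` capped at 1, for `X ~ Binomial(n, p0)` —
#' the outlier P value attached to each provider point on a chart.
#'
#' @param k Observed count(s).
#' @param n Volume(s).
#' @param p0 Centre rate.
#' @return Probabilities in `[0, 1]`, vectorized over `k`/`n`.
#' @export
two_sided_binomial_p <- function(k, n, p0) {
  .assert(all(p0 >= 0 & p0 <= 1), "p0 must be in [0, 1]")
  .assert(all(k >= 0 & k <= n), "k must lie in [0, n]")
  lo <- stats::pbinom(k, n, p0)
  hi <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

#' Case-mix normalization of a provider rate
#'
#' Indirect standardization by nodal station: the provider's expected count
#' is the sum over stations of their volume at that station times the pooled
#' station-specific rate, and the normalized rate is
#' `observed / expected * p0` — the provider's standardized ratio re-centred
#' at the group median rate.  `mode = "raw"` returns the crude rate.
#' Stations absent from `stratum_rates` (no pooled data) are dropped from the
#' expectation with a warning.
#'
#' @param observed_count Provider's event count for the group.
#' @param n Provider's total volume (used for the raw rate).
#' @param station_counts Named vector: provider volume per station
#'   (required for `mode = "indirect"`).
#' @param stratum_rates Named vector: pooled group rate per station.
#' @param p0 Centre rate the normalized rate is re-centred at.
#' @param mode `"indirect"` or `"raw"`.
#' @return A single normalized rate.
#' @export
normalize_rate <- function(observed_count, n, station_counts = NULL,
                           stratum_rates = NULL, p0 = NULL,
                           mode = c("indirect", "raw")) {
  mode <- match.arg(mode)
  if (mode == "raw") return(observed_count / n)
  .assert(!is.null(station_counts) && !is.null(stratum_rates) && !is.null(p0),
          "indirect normalization needs station_counts, stratum_rates and p0")
  known <- names(station_counts)[names(station_counts) %in%
                                   names(stratum_rates)]
  dropped <- setdiff(names(station_counts), known)
  dropped <- dropped[station_counts[dropped] > 0]
  if (length(dropped) > 0) {
    warning(sprintf("station(s) without pooled rate excluded from expectation: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  expected <- sum(station_counts[known] * stratum_rates[known])
  .assert(expected > 0, "expected count is zero; cannot normalize")
  observed_count / expected * p0
}

#' Build a provider control chart / funnel plot
#'
#' Centres the chart on the group median rate (GMR) of `rate_table`, computes
#' exact binomial limits at each significance level for every provider's
#' volume, flags providers whose observed count falls strictly outside the
#' limit counts, and orders points by the (optionally case-mix normalized)
#' rate.  The GMR is treated as a fixed plug-in centre; no uncertainty is
#' propagated from its estimation, matching standard funnel-plot practice.
#'
#' @param rate_table An [provider_rates()] result.
#' @param group One of the exclusive groups, e.g. `"insufficient"`.
#' @param alphas Significance levels for the bands, widest first.
#' @param mode `"raw"` or `"indirect"` (station case-mix normalization;
#'   requires `classified`).
#' @param classified The classified corpus, needed for `mode = "indirect"`
#'   (pooled station rates and provider station mixes).
#' @return An object of class `mlnqa_chart`: list with `role`, `group`, `p0`,
#'   `mode`, `alphas`, `points` (per-provider tibble with rates, two-sided P
#'   and one `flag_<alpha>` column per level, ordered by normalized rate),
#'   `limits` (long tibble provider x alpha) and `outlier_counts`.
#' @export
build_chart <- function(rate_table, group,
                        alphas = c(0.05, 1e-3, 1e-6, 1e-12),
                        mode = c("raw", "indirect"), classified = NULL) {
  mode <- match.arg(mode)
  .assert(inherits(rate_table, "mlnqa_rate_table"), "not an mlnqa_rate_table")
  .assert(group %in% .group_levels, "unknown group '%s'", group)
  .assert(all(diff(alphas) < 0), "alphas must be sorted descending")
  p0 <- unname(rate_table$gmr[group])
  tab <- rate_table$table

  observed <- tab[[paste0("n_", group)]]
  raw_rate <- observed / tab$n
  if (mode == "indirect") {
    .assert(!is.null(classified),
            "indirect normalization needs the classified corpus")
    id_col <- if (rate_table$role == "pathologist") "pathologist_id" else "sps_id"
    known <- classified[classified$station != .UNKNOWN_STATION, , drop = FALSE]
    pooled <- tapply(known$exclusive_group == group, known$station, mean)
    stratum_rates <- setNames(as.numeric(pooled), names(pooled))
    normalized <- vapply(seq_len(nrow(tab)), function(i) {
      mine <- classified[classified[[id_col]] == tab$provider_id[i], ,
                         drop = FALSE]
      mix <- table(mine$station[mine$station != .UNKNOWN_STATION])
      normalize_rate(observed[i], tab$n[i],
                     station_counts = setNames(as.numeric(mix), names(mix)),
                     stratum_rates = stratum_rates, p0 = p0,
                     mode = "indirect")
    }, numeric(1))
  } else {
    normalized <- raw_rate
  }

  points <- tibble::tibble(provider_id = tab$provider_id, n = tab$n,
                           observed_count = observed, raw_rate = raw_rate,
                           normalized_rate = normalized,
                           two_sided_p = two_sided_binomial_p(observed, tab$n, p0))
  limits <- list()
  for (a in alphas) {
    flag <- character(nrow(points))
    for (i in seq_len(nrow(points))) {
      lim <- binomial_limits(points$n[i], p0, a)
      flag[i] <- if (points$observed_count[i] > lim$k_upper) "high"
                 else if (points$observed_count[i] < lim$k_lower) "low"
                 else "in_control"
      limits[[length(limits) + 1L]] <- tibble::tibble(
        provider_id = points$provider_id[i], alpha = a, n = lim$n,
        k_lower = lim$k_lower, k_upper = lim$k_upper,
        lower = lim$lower, upper = lim$upper)
    }
    points[[paste0("flag_", format(a, scientific = FALSE))]] <- flag
  }
  ord <- order(points$normalized_rate, points$provider_id)
  points <- points[ord, ]
  limits <- dplyr::bind_rows(limits)
  flag_cols <- grep("^flag_", names(points), value = TRUE)
  outlier_counts <- setNames(
    vapply(flag_cols, function(cn) sum(points[[cn]] != "in_control"),
           integer(1)),
    vapply(alphas, format, character(1), scientific = FALSE))
  structure(list(role = rate_table$role, group = group, p0 = p0, mode = mode,
                 alphas = alphas, points = points, limits = limits,
                 outlier_counts = outlier_counts),
            class = "mlnqa_chart")
}

#' @export
print.mlnqa_chart <- function(x, ...) {
  cat(sprintf("<mlnqa_chart: %s / %s>  p0 (GMR) = %.4f, %d providers, mode = %s\n",
              x$role, x$group, x$p0, nrow(x$points), x$mode))
  cat("outliers:", paste(sprintf("alpha=%s: %d", names(x$outlier_counts),
                                 x$outlier_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Chart data as plain lists (for JSON export)
#'
#' @param chart An `mlnqa_chart`.
#' @return A list serializable with `jsonlite::write_json()`.
#' @export
chart_data <- function(chart) {
  list(role = chart$role, group = chart$group, p0 = chart$p0,
       mode = chart$mode, alphas = chart$alphas,
       points = chart$points, limits = chart$limits,
       outlier_counts = as.list(chart$outlier_counts))
}

#' Render a control chart or funnel plot
#'
#' Control chart: providers on the x axis ordered by normalized rate, centre
#' line at the GMR, dashed 95% band, solid 99.9% band, dashed outer 1e-6 and
#' 1e-12 bands (limits vary per provider with volume).  Funnel plot: rate
#' against volume with continuous limit curves.
#'
#' @param chart An `mlnqa_chart`.
#' @param kind `"control_chart"` or `"funnel"`.
#' @param path Optional output file (`.png` or `.svg`); when `NULL` the
#'   ggplot object is returned without writing.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly when written to `path`.
#' @export
render_chart <- function(chart, kind = c("control_chart", "funnel"),
                         path = NULL, width = 7, height = 5) {
  kind <- match.arg(kind)
  pts <- chart$points
  pts$order <- seq_len(nrow(pts))
  band_style <- function(a) {
    if (a == 1e-3) "solid" else "dashed"
  }
  if (kind == "control_chart") {
    lim <- dplyr::left_join(chart$limits,
                            pts[, c("provider_id", "order")],
                            by = "provider_id")
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$order)) +
      ggplot2::geom_hline(yintercept = chart$p0, linewidth = 0.8) +
      ggplot2::geom_point(ggplot2::aes(y = .data$normalized_rate),
                          colour = "red", size = 2.5, shape = 1, stroke = 1.1)
    for (a in chart$alphas) {
      la <- lim[lim$alpha == a, ]
      la <- la[order(la$order), ]
      p <- p +
        ggplot2::geom_step(data = la,
                           ggplot2::aes(y = .data$lower), colour = "blue",
                           linetype = band_style(a), linewidth = 0.4) +
        ggplot2::geom_step(data = la,
                           ggplot2::aes(y = .data$upper), colour = "blue",
                           linetype = band_style(a), linewidth = 0.4)
    }
    p <- p +
      ggplot2::scale_x_continuous(breaks = pts$order) +
      ggplot2::labs(x = sprintf("%s (ordered by normalized rate)", chart$role),
                    y = sprintf("%s rate", chart$group),
                    title = sprintf("%s control chart: %s (GMR %.3f)",
                                    chart$role, chart$group, chart$p0)) +
      ggplot2::theme_minimal()
  } else {
    n_grid <- unique(round(exp(seq(log(max(1, min(pts$n) * 0.7)),
                                   log(max(pts$n) * 1.15), length.out = 120))))
    curves <- dplyr::bind_rows(lapply(chart$alphas, function(a) {
      dplyr::bind_rows(lapply(n_grid, function(nn) {
        l <- binomial_limits(nn, chart$p0, a)
        tibble::tibble(n = nn, alpha = a, lower = l$lower, upper = l$upper)
      }))
    }))
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$n)) +
      ggplot2::geom_hline(yintercept = chart$p0, linewidth = 0.8)
    for (a in chart$alphas) {
      ca <- curves[curves$alpha == a, ]
      p <- p +
        ggplot2::geom_line(data = ca, ggplot2::aes(y = .data$lower),
                           colour = "blue", linetype = band_style(a),
                           linewidth = 0.4) +
        ggplot2::geom_line(data = ca, ggplot2::aes(y = .data$upper),
                           colour = "blue", linetype = band_style(a),
                           linewidth = 0.4)
    }
    p <- p +
      ggplot2::geom_point(ggplot2::aes(y = .data$raw_rate), colour = "red",
                          size = 2.5, shape = 1, stroke = 1.1) +
      ggplot2::labs(x = "specimens (n)", y = sprintf("%s rate", chart$group),
                    title = sprintf("%s funnel plot: %s (GMR %.3f)",
                                    chart$role, chart$group, chart$p0)) +
      ggplot2::theme_minimal()
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}
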