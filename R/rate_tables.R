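# Cohort crosstabs and per-provider rate tables with group median rates.

#' Tabulate the mutually exclusive groups
#'
#' Counts and fractions of the corpus in each exclusive group (benign,
#' suspicious, malignant, insufficient, unclassified).  Fractions are kept at
#' full precision; rounding to the conventional 3 decimals happens only at
#' print time.
#'
#' @param classified A classified corpus ([classify_corpus()]), or any tibble
#'   with an `exclusive_group` column.
#' @return A tibble `exclusive_group`, `n`, `fraction` (class
#'   `mlnqa_group_table`, with the corpus total as attribute `total`).
#' @export
tabulate_groups <- function(classified) {
  .assert(nrow(classified) > 0, "cannot tabulate an empty corpus")
  g <- factor(classified$exclusive_group, levels = .group_levels)
  .assert(!anyNA(g), "unknown exclusive_group value(s) in corpus")
  counts <- as.integer(table(g))
  out <- tibble::tibble(exclusive_group = .group_levels,
                        n = counts,
                        fraction = counts / nrow(classified))
  structure(out, total = nrow(classified),
            class = c("mlnqa_group_table", class(out)))
}

#' @export
print.mlnqa_group_table <- function(x, ...) {
  cat(sprintf("Mutually exclusive groupings (n = %d)\n", attr(x, "total")))
  df <- as.data.frame(x)
  df$fraction <- sprintf("%.3f", df$fraction)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Crosstab of exclusive groups by nodal station
#'
#' Per-station group fractions plus the derived insufficient + suspicious
#' row (the share of specimens that fail to yield a definite diagnosis).
#' Records with `UNKNOWN` station are excluded from the crosstab rows but
#' remain in the denominator of `fraction_of_corpus`, so the station shares
#' match a whole-cohort table.
#'
#' @param classified A classified corpus.
#' @return A tibble, one row per station (ordered by volume): `station`, `n`,
#'   `fraction_of_corpus`, one fraction column per group, and
#'   `insufficient_plus_suspicious`.
#' @export
tabulate_by_station <- function(classified) {
  .assert(nrow(classified) > 0, "cannot tabulate an empty corpus")
  total <- nrow(classified)
  known <- classified[classified$station != .UNKNOWN_STATION, , drop = FALSE]
  .assert(nrow(known) > 0, "no records with a known station")
  out <- known |>
    dplyr::count(.data$station, .data$exclusive_group) |>
    tidyr::pivot_wider(names_from = "exclusive_group", values_from = "n",
                       values_fill = 0L)
  for (g in .group_levels) if (!g %in% names(out)) out[[g]] <- 0L
  out$n <- rowSums(out[, .group_levels])
  for (g in .group_levels) out[[g]] <- out[[g]] / out$n
  out$insufficient_plus_suspicious <- out$insufficient + out$suspicious
  out$fraction_of_corpus <- out$n / total
  out <- out[order(-out$n, out$station),
             c("station", "n", "fraction_of_corpus", .group_levels,
               "insufficient_plus_suspicious")]
  structure(out, total = total,
            class = c("mlnqa_station_table", class(out)))
}

#' Per-provider rates and the group median rate
#'
#' Tabulates, for each provider in a role (interpreting pathologist or
#' submitting physician/surgeon), the number of specimens and the per-group
#' counts and rates.  Low-volume providers (fewer than `min_n` specimens) are
#' excluded, and the group median rate (GMR) — the centre line of the funnel
#' plots and control charts — is the median of the per-provider rates among
#' included providers (mean of the middle two for an even count), not the
#' pooled rate.
#'
#' @param classified A classified corpus.
#' @param role `"pathologist"` or `"sps"` (submitting physician/surgeon).
#' @param min_n Minimum specimen volume for inclusion (default 250).
#' @return An object of class `mlnqa_rate_table`: list with `role`, `table`
#'   (tibble of per-provider `n`, `n_<group>`, `rate_<group>`), `gmr` (named
#'   vector of group median rates), `min_n`, `excluded` (ids of dropped
#'   providers).
#' @export
provider_rates <- function(classified, role = c("pathologist", "sps"),
                           min_n = 250L) {
  role <- match.arg(role)
  id_col <- if (role == "pathologist") "pathologist_id" else "sps_id"
  .assert(id_col %in% names(classified), "corpus lacks column %s", id_col)

  counts <- classified |>
    dplyr::count(provider_id = .data[[id_col]], .data$exclusive_group) |>
    tidyr::pivot_wider(names_from = "exclusive_group", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  for (g in .group_levels) {
    col <- paste0("n_", g)
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts$n <- rowSums(counts[, paste0("n_", .group_levels)])
  excluded <- counts$provider_id[counts$n < min_n]
  counts <- counts[counts$n >= min_n, , drop = FALSE]
  .assert(nrow(counts) >= 2,
          "fewer than 2 providers with n >= %d: no group to compare", min_n)
  for (g in .group_levels) {
    counts[[paste0("rate_", g)]] <- counts[[paste0("n_", g)]] / counts$n
  }
  counts <- counts[order(-counts$n, counts$provider_id),
                   c("provider_id", "n", paste0("n_", .group_levels),
                     paste0("rate_", .group_levels))]
  gmr <- vapply(.group_levels, function(g)
    stats::median(counts[[paste0("rate_", g)]]), numeric(1))
  structure(list(role = role, table = counts, gmr = gmr,
                 min_n = min_n, excluded = excluded),
            class = "mlnqa_rate_table")
}

#' @export
print.mlnqa_rate_table <- function(x, ...) {
  cat(sprintf("<mlnqa_rate_table: %s>  %d providers (min_n = %d, %d excluded)\n",
              x$role, nrow(x$table), x$min_n, length(x$excluded)))
  cat("group median rates:\n")
  print(round(x$gmr, 4))
  invisible(x)
}
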