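# Shared constants and small internal helpers.

# Severity ordering of the mutually exclusive groups: a report matching
# categories in several groups is assigned the highest-severity one.
.severity <- c(malignant = 1L, suspicious = 2L, insufficient = 3L, benign = 4L)

# Display order used in cohort tables.
.group_levels <- c("benign", "suspicious", "malignant", "insufficient",
                   "unclassified")

.UNCLASSIFIED <- "UNCLASSIFIED"
.UNKNOWN_STATION <- "UNKNOWN"

.stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stop(fmt, ...)
  invisible(TRUE)
}

# Severity rank of a group name; unclassified sorts after everything real.
.group_rank <- function(group) {
  r <- unname(.severity[group])
  r[is.na(r)] <- 5L
  r
}
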