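#' Aggregated counts for a 2x2 factorial trial with a binary outcome
#'
#' Constructs a validated `trial_counts` object holding events and totals for
#' the four cells of a two-by-two factorial design.  Factor coding is fixed:
#' `depth = 1` denotes the deeper-cooling level (32.0 degC) and
#' `duration = 1` the longer-cooling level (120 h); level 0 is standard care
#' (33.5 degC, 72 h).  Any other coding is rejected rather than remapped.
#'
#' @param depth integer vector of 0/1 depth codes, one per cell.
#' @param duration integer vector of 0/1 duration codes, one per cell.
#' @param events number of events (e.g. predischarge deaths) in each cell.
#' @param total number of subjects randomized to each cell.
#' @param labels optional character vector of human-readable arm names in the
#'   canonical cell order (0,0), (1,0), (0,1), (1,1).
#'
#' @return An object of class `trial_counts`: a data frame with columns
#'   `depth`, `duration`, `events`, `total` in canonical cell order.
#' @examples
#' counts <- trial_counts(depth    = c(0, 1, 0, 1),
#'                        duration = c(0, 0, 1, 1),
#'                        events   = c(7, 13, 15, 14),
#'                        total    = c(95, 90, 96, 83))
#' margin_rates(counts)
#' @export
trial_counts <- function(depth, duration, events, total, labels = NULL) {
  df <- data.frame(depth = as.integer(depth), duration = as.integer(duration),
                   events = as.integer(events), total = as.integer(total))
  if (anyNA(df))
    stop("trial_counts: missing values are not allowed", call. = FALSE)
  if (!all(df$depth %in% c(0L, 1L)) || !all(df$duration %in% c(0L, 1L)))
    stop("trial_counts: depth and duration must be coded 0/1 ",
         "(1 = 32.0 degC, 1 = 120 h)", call. = FALSE)
  key <- paste(df$depth, df$duration)
  if (anyDuplicated(key))
    stop("trial_counts: duplicated cell (", key[duplicated(key)][1], ")",
         call. = FALSE)
  want <- paste(CELL_ORDER[, "depth"], CELL_ORDER[, "duration"])
  miss <- setdiff(want, key)
  if (length(miss))
    stop(sprintf("trial_counts: missing cell (%s)",
                 gsub(" ", ",", miss[1])), call. = FALSE)
  df <- df[match(want, key), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$events < 0L) || any(df$total < 0L) || any(df$events > df$total))
    stop("trial_counts: need 0 <= events <= total in every cell",
         call. = FALSE)
  if (is.null(labels)) labels <- CELL_LABELS
  stopifnot(length(labels) == 4L)
  structure(df, labels = labels, class = c("trial_counts", "data.frame"))
}

#' Read factorial trial counts from a CSV or JSON file
#'
#' The CSV layout is a header `depth,duration,events,total` and one row per
#' cell; the JSON mirror is an array of objects with the same fields.  The
#' interim predischarge-mortality counts of the Optimizing Cooling Trial ship
#' with the package:
#' `system.file("extdata", "optimizing_cooling_table2.csv", package = "bayesfactorial")`.
#'
#' @param path path to a `.csv` or `.json` file.
#' @return A validated [trial_counts] object.
#' @export
read_trial_counts <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    read.csv(path)
  }
  need <- c("depth", "duration", "events", "total")
  if (!all(need %in% names(df)))
    stop("expected columns depth, duration, events, total in ", path,
         call. = FALSE)
  trial_counts(df$depth, df$duration, df$events, df$total)
}

#' Write factorial trial counts to CSV
#'
#' Rows are emitted in canonical cell order so that reading a file and writing
#' it back is byte-stable.
#'
#' @param x a [trial_counts] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_counts <- function(x, path) {
  stopifnot(inherits(x, "trial_counts"))
  write.csv(as.data.frame(x)[, c("depth", "duration", "events", "total")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate per-subject records into cell counts
#'
#' @param records data frame with 0/1 columns `depth`, `duration`, `outcome`
#'   (1 = event), one row per subject, e.g. as produced by [simulate_trial()].
#' @return A [trial_counts] object.  Cells with no subjects get `total = 0`
#'   and are flagged via the `"empty_cells"` attribute; such counts are
#'   accepted here but rejected by [fit_trial()].
#' @export
aggregate_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("aggregate_records: need a non-empty data frame of subject records",
         call. = FALSE)
  need <- c("depth", "duration", "outcome")
  if (!all(need %in% names(records)))
    stop("aggregate_records: records need columns depth, duration, outcome",
         call. = FALSE)
  if (!all(unlist(records[need]) %in% c(0, 1)))
    stop("aggregate_records: depth, duration and outcome must be 0/1",
         call. = FALSE)
  ev <- tot <- integer(4)
  for (c_i in seq_len(4)) {
    in_cell <- records$depth == CELL_ORDER[c_i, "depth"] &
      records$duration == CELL_ORDER[c_i, "duration"]
    tot[c_i] <- sum(in_cell)
    ev[c_i] <- sum(records$outcome[in_cell])
  }
  out <- trial_counts(CELL_ORDER[, "depth"], CELL_ORDER[, "duration"], ev, tot)
  attr(out, "empty_cells") <- CELL_LABELS[tot == 0L]
  out
}

#' Marginal event rates of a factorial trial
#'
#' Each margin pools the two cells sharing a factor level:
#' e.g. the 120 h margin is (events at 33.5 degC/120 h + events at
#' 32.0 degC/120 h) / (corresponding totals).
#'
#' @param counts a [trial_counts] object.
#' @return Named numeric vector with elements `depth_33.5C`, `depth_32.0C`,
#'   `duration_72h`, `duration_120h`.
#' @export
margin_rates <- function(counts) {
  stopifnot(inherits(counts, "trial_counts"))
  pool <- function(sel) {
    n <- sum(counts$total[sel])
    if (n == 0L) stop("margin_rates: margin has zero total", call. = FALSE)
    sum(counts$events[sel]) / n
  }
  c(depth_33.5C   = pool(counts$depth == 0L),
    depth_32.0C   = pool(counts$depth == 1L),
    duration_72h  = pool(counts$duration == 0L),
    duration_120h = pool(counts$duration == 1L))
}

#' @export
print.trial_counts <- function(x, ...) {
  cat("2x2 factorial trial counts (events/total):\n")
  lab <- attr(x, "labels")
  for (i in seq_len(4)) {
    pct <- if (x$total[i] > 0) sprintf(" (%.0f%%)", 100 * x$events[i] / x$total[i]) else ""
    cat(sprintf("  %-11s depth=%d duration=%d  %d/%d%s\n",
                lab[i], x$depth[i], x$duration[i], x$events[i], x$total[i], pct))
  }
  cat(sprintf("  total n = %d\n", sum(x$total)))
  invisible(x)
}

#' Interim counts of the Optimizing Cooling Trial
#'
#' Convenience loader for the packaged fixture: predischarge deaths over
#' subjects randomized at the interim analysis that stopped the trial
#' (7/95, 13/90, 15/96, 14/83; n = 364).
#'
#' @return A [trial_counts] object.
#' @export
optimizing_cooling_counts <- function() {
  read_trial_counts(system.file("extdata", "optimizing_cooling_table2.csv",
                                package = "bayesfactorial", mustWork = TRUE))
}
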