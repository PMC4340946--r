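## Tabular I/O for urine samples and behavioural events.
## Dialect: comma-separated, UTF-8, header required, "." decimal separator.

sample_required_cols <- c("subject_id", "event_id", "collection_time",
                          ugc_analytes, "creatinine", "recovery_deviation")

event_required_cols <- c("event_id", "subject_id", "behaviour", "start_time",
                         "duration", "role", "intensity", "rank")

check_columns <- function(d, required, what) {
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(d)
}

check_numeric_rows <- function(d, cols, what) {
  for (col in cols) {
    v <- d[[col]]
    if (is.numeric(v)) next
    conv <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(conv) & !is.na(v) & trimws(v) != "")
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s' at row %d ('%s')",
                   what, col, bad[1], v[bad[1]]), call. = FALSE)
    d[[col]] <- conv
  }
  d
}

#' Read urine samples from a delimited text file
#'
#' Reads one urine collection per row. Column names can be mapped from a
#' non-canonical schema via `column_map`. Collection times may be given as
#' absolute clock minutes; if `events` is supplied, times are converted to
#' minutes relative to the start of the event each sample belongs to
#' (matched on `event_id`). All samples are returned with
#' `qc_status = "pending"`; run [qc_samples()] before any quantification.
#'
#' @param file path to a CSV file (or a connection).
#' @param column_map optional named character vector mapping canonical
#'   column names (names) to the file's column names (values), e.g.
#'   `c(collection_time = "time_min")`. Unmapped canonical names are taken
#'   verbatim.
#' @param events optional behavioural-event table (see [read_events()]);
#'   when given, `collection_time` is interpreted as absolute clock minutes
#'   and converted to event-relative minutes using the event `start_time`.
#' @return A data frame of urine samples with canonical columns
#'   (`subject_id`, `event_id`, `collection_time` in event-relative
#'   minutes, the five [ugc_analytes] in ng/ml, `creatinine` in mg/ml,
#'   `recovery_deviation` as a signed fraction, `qc_status`).
#' @seealso [write_samples()], [qc_samples()]
#' @export
read_samples <- function(file, column_map = NULL, events = NULL) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(d))
        stop(sprintf("samples: mapped column '%s' (for '%s') not in file",
                     src, canon), call. = FALSE)
      names(d)[names(d) == src] <- canon
    }
  }
  check_columns(d, sample_required_cols, "samples")
  d <- check_numeric_rows(d, c("collection_time", ugc_analytes, "creatinine",
                               "recovery_deviation"), "samples")
  if (nrow(d)) {
    neg <- ugc_analytes[vapply(ugc_analytes,
                               function(a) any(d[[a]] < 0, na.rm = TRUE),
                               logical(1))]
    if (length(neg))
      stop("samples: negative concentration in column(s): ",
           paste(neg, collapse = ", "), call. = FALSE)
    if (any(d$creatinine < 0, na.rm = TRUE))
      stop("samples: negative creatinine", call. = FALSE)
  }
  if (!is.null(events)) {
    check_columns(events, c("event_id", "start_time"), "events")
    idx <- match(d$event_id, events$event_id)
    if (anyNA(idx) && nrow(d))
      stop("samples: event_id not found in events table: ",
           paste(unique(d$event_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    d$collection_time <- d$collection_time - events$start_time[idx]
  }
  d$qc_status <- rep_len("pending", nrow(d))
  d[c(sample_required_cols, "qc_status")]
}

#' Write urine samples to CSV
#'
#' Inverse of [read_samples()]; the round trip preserves all numeric fields
#' to full precision.
#'
#' @param samples urine-sample data frame.
#' @param file output path.
#' @export
write_samples <- function(samples, file) {
  write_csv_precise(samples, file)
}

## CSV writer that round-trips doubles exactly (17 significant digits)
write_csv_precise <- function(d, file) {
  out <- d
  for (col in names(out))
    if (is.double(out[[col]]))
      out[[col]] <- vapply(out[[col]], function(x)
        format(x, digits = 17, trim = TRUE, scientific = FALSE),
        character(1))
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' Read behavioural events from a delimited text file
#'
#' One target behaviour per row: an aggressive interaction (with the
#' subject's role and the aggression's intensity) or a resting control.
#' Resting rows are assigned `role = "none"` and `intensity = "none"`.
#' Aggression rows must state role and intensity. Resting events shorter
#' than 30 minutes trigger a validation warning (a resting control requires
#' the subject to be sitting or lying for at least its first 30 minutes).
#'
#' @param file path to a CSV file (or a connection).
#' @return Data frame with columns `event_id`, `subject_id`, `behaviour`,
#'   `start_time` (clock minutes), `duration` (minutes), `role`,
#'   `intensity`, `rank`.
#' @seealso [write_events()]
#' @export
read_events <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, encoding = "UTF-8")
  check_columns(d, setdiff(event_required_cols, c("role", "intensity")),
                "events")
  d <- check_numeric_rows(d, c("start_time", "duration", "rank"), "events")
  if (!"role" %in% names(d)) d$role <- NA_character_
  if (!"intensity" %in% names(d)) d$intensity <- NA_character_
  if (nrow(d)) {
    if (!all(d$behaviour %in% c("aggression", "resting")))
      stop("events: behaviour must be 'aggression' or 'resting'",
           call. = FALSE)
    if (any(d$duration <= 0))
      stop("events: non-positive duration", call. = FALSE)
    if (any(d$rank < 1))
      stop("events: rank must be >= 1", call. = FALSE)
    rest <- d$behaviour == "resting"
    d$role[rest] <- "none"
    d$intensity[rest] <- "none"
    agg <- !rest
    bad_role <- agg & (is.na(d$role) | !d$role %in% c("aggressor", "victim"))
    if (any(bad_role))
      stop(sprintf("events: aggression row %d missing/invalid role",
                   which(bad_role)[1]), call. = FALSE)
    bad_int <- agg & (is.na(d$intensity) |
                        !d$intensity %in% c("contact", "non_contact"))
    if (any(bad_int))
      stop(sprintf("events: aggression row %d missing/invalid intensity",
                   which(bad_int)[1]), call. = FALSE)
    if (any(rest & d$duration < 30))
      warning("events: resting event(s) shorter than 30 min: row(s) ",
              paste(which(rest & d$duration < 30), collapse = ", "),
              call. = FALSE)
  }
  d[event_required_cols]
}

#' Write behavioural events to CSV
#' @param events behavioural-event data frame.
#' @param file output path.
#' @export
write_events <- function(events, file) {
  write_csv_precise(events, file)
}

#' Write an event-level relative-uGC table to CSV
#'
#' Emits the event-level result schema (one row per complete event series)
#' with `relative_ugc` rounded half-up to one decimal, the reporting
#' precision; all other columns are written verbatim.
#'
#' @param results event-level table from [process_events()].
#' @param file output path.
#' @export
write_event_results <- function(results, file) {
  out <- results
  if ("relative_ugc" %in% names(out))
    out$relative_ugc <- round_half_up(out$relative_ugc, 1)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

## round-half-up at `digits` decimals (base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
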