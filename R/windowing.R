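#' Window parameters for sample-to-period assignment
#'
#' Urinary glucocorticoid metabolites appear in urine with a clearance lag:
#' the peak excretion window for a behavioural event starting at `t0` (of
#' duration `d`) runs from `t1 = t0 + pre_window_len` to
#' `t2 = t0 + d + peak_clearance_len`. Samples voided in `[t0, t1)` reflect
#' the pre-event hormonal state; samples in `[t1, t2)` reflect the event's
#' response. Because urine accumulates in the bladder between voids, a
#' sample voided within `overlap_len` minutes after either boundary may
#' contain urine from both sides; see [assign_periods()] for the
#' resolution rule. `pre_exclusion` and `post_abort` parametrize the
#' behavioural QC of [qc_event()].
#'
#' @param pre_window_len length of the pre-event window, minutes.
#' @param peak_clearance_len clearance span after the end of the behaviour,
#'   minutes; the peak window ends `peak_clearance_len` after the event ends.
#' @param overlap_len length of the overlap zone after each boundary, minutes.
#' @param pre_exclusion minutes before the event during which prior
#'   aggression or grooming disqualifies the event.
#' @param post_abort minutes after the end of the event during which new
#'   aggression or grooming aborts the series.
#' @return An object of class `window_params`.
#' @export
window_params <- function(pre_window_len = 135, peak_clearance_len = 270,
                          overlap_len = 30, pre_exclusion = 60,
                          post_abort = 120) {
  p <- list(pre_window_len = pre_window_len,
            peak_clearance_len = peak_clearance_len,
            overlap_len = overlap_len,
            pre_exclusion = pre_exclusion,
            post_abort = post_abort)
  if (any(unlist(p) <= 0))
    stop("window_params: all parameters must be strictly positive",
         call. = FALSE)
  if (overlap_len >= peak_clearance_len)
    stop("window_params: overlap_len must be smaller than peak_clearance_len",
         call. = FALSE)
  structure(p, class = "window_params")
}

#' Window bounds for one behavioural event
#'
#' Returns `(t0, t1, t2)` in event-relative minutes: `t0 = 0`,
#' `t1 = pre_window_len`, `t2 = duration + peak_clearance_len`.
#'
#' @param event a one-row behavioural-event data frame, or a list with a
#'   `duration` element (minutes).
#' @param params a [window_params()] object.
#' @return Named numeric vector `c(t0, t1, t2)`.
#' @examples
#' event_window_bounds(list(duration = 2))   # 0, 135, 272
#' @export
event_window_bounds <- function(event, params = window_params()) {
  d <- as.numeric(event$duration)
  if (length(d) != 1 || is.na(d) || d <= 0)
    stop("event_window_bounds: event duration must be a positive scalar",
         call. = FALSE)
  c(t0 = 0, t1 = params$pre_window_len,
    t2 = d + params$peak_clearance_len)
}

#' Assign urine samples to pre- and peak-excretion periods
#'
#' Implements the window-assignment rule. With bounds `t0 < t1 < t2` from
#' [event_window_bounds()], a sample voided at event-relative time `s` is
#' provisionally labelled by the period in which it was excreted:
#' `pre` for `s` in `[t0, t1)`, `peak` for `[t1, t2)`, `excluded` before
#' `t0` or at/after `t2`. A sample voided in an overlap zone
#' `(t, t + overlap_len]` for a boundary `t` in `{t1, t2}` may contain
#' mostly urine accumulated before the boundary: let `p` be the time of the
#' latest sample strictly before `t`; if `p` exists and `s - t < t - p`,
#' the sample is relabelled to the period ending at `t` (`pre` at `t1`,
#' `peak` at `t2`). In all other cases (no previous sample, or a tie) the
#' sample keeps the period in which it was excreted — which for the `t2`
#' overlap zone means `excluded`, as the study window ends at `t2`.
#'
#' Assignment uses the void times of all supplied samples (a QC-failed
#' collection is still a urination and anchors the latency comparison), but
#' series completeness counts only QC-passing samples: the series is
#' `complete` when at least one passing sample falls in each of the pre and
#' peak periods.
#'
#' @param samples urine-sample data frame with event-relative
#'   `collection_time`; a `qc_status` column is honoured if present.
#' @param event the behavioural event (needs `duration`).
#' @param params a [window_params()] object.
#' @return An object of class `sample_series`: a list with `event`,
#'   `samples` (the input plus a `period` factor and the `delta_s`/`delta_p`
#'   latencies used for overlap decisions), `t0`, `t1`, `t2`, `complete`.
#' @export
assign_periods <- function(samples, event, params = window_params()) {
  b <- event_window_bounds(event, params)
  s <- samples$collection_time
  ord <- order(s)
  s_sorted <- s[ord]

  label <- rep("excluded", length(s))
  label[s >= b["t0"] & s < b["t1"]] <- "pre"
  label[s >= b["t1"] & s < b["t2"]] <- "peak"

  delta_s <- rep(NA_real_, length(s))
  delta_p <- rep(NA_real_, length(s))
  for (tb in c(b[["t1"]], b[["t2"]])) {
    in_zone <- which(s > tb & s <= tb + params$overlap_len)
    if (!length(in_zone)) next
    prev <- s_sorted[s_sorted < tb]
    if (!length(prev)) next
    p <- max(prev)
    relabel <- (s[in_zone] - tb) < (tb - p)
    delta_s[in_zone] <- s[in_zone] - tb
    delta_p[in_zone] <- tb - p
    label[in_zone[relabel]] <- if (tb == b[["t1"]]) "pre" else "peak"
  }

  out <- samples
  out$period <- factor(label, levels = c("pre", "peak", "excluded"))
  out$delta_s <- delta_s
  out$delta_p <- delta_p
  pass <- if ("qc_status" %in% names(out)) out$qc_status == "pass"
          else rep(TRUE, nrow(out))
  complete <- any(pass & out$period == "pre") &&
    any(pass & out$period == "peak")
  structure(list(event = event, samples = out,
                 t0 = b[["t0"]], t1 = b[["t1"]], t2 = b[["t2"]],
                 complete = complete),
            class = "sample_series")
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("sample series: %d samples, windows [%g, %g) / [%g, %g), %s\n",
              nrow(x$samples), x$t0, x$t1, x$t1, x$t2,
              if (x$complete) "complete" else "incomplete"))
  print(table(x$samples$period))
  invisible(x)
}

#' Behavioural QC of an event series
#'
#' An event series is only usable if the subject's hormonal state was not
#' contaminated by other arousing interactions: sample collection does not
#' commence if the subject engaged in aggression or grooming within
#' `pre_exclusion` minutes before the event, and is aborted if the subject
#' engages in additional aggression or grooming within `post_abort` minutes
#' after the end of the event.
#'
#' @param event the behavioural event (needs `start_time` and `duration` on
#'   the same clock as the log).
#' @param behaviour_log data frame with columns `time` and `behaviour` for
#'   the subject's other interactions (e.g. `"aggression"`, `"grooming"`);
#'   only aggression and grooming entries are considered contaminating.
#' @param params a [window_params()] object.
#' @return One of `"keep"`, `"reject_pre_contamination"`,
#'   `"abort_post_contamination"`.
#' @export
qc_event <- function(event, behaviour_log, params = window_params()) {
  t0 <- as.numeric(event$start_time)
  d <- as.numeric(event$duration)
  if (is.null(behaviour_log) || !nrow(behaviour_log)) return("keep")
  contam <- behaviour_log$behaviour %in% c("aggression", "grooming")
  tt <- behaviour_log$time[contam]
  if (any(tt >= t0 - params$pre_exclusion & tt < t0))
    return("reject_pre_contamination")
  if (any(tt > t0 + d & tt <= t0 + d + params$post_abort))
    return("abort_post_contamination")
  "keep"
}
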