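#' Quality-control parameters for urine samples
#'
#' Two sample-level filters: the LC-MS/MS internal-standard recovery must
#' deviate by less than `recovery_tolerance` (as a fraction) from its
#' expected value, and creatinine must be at least `creatinine_floor`
#' (very dilute samples carry unreliable creatinine-corrected values).
#'
#' @param recovery_tolerance maximum absolute fractional deviation of the
#'   internal-standard recovery (default 0.50, i.e. +/- 50%).
#' @param creatinine_floor minimum creatinine, mg per ml urine
#'   (default 0.05).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(recovery_tolerance = 0.50, creatinine_floor = 0.05) {
  if (!(recovery_tolerance > 0 && recovery_tolerance < 1))
    stop("qc_params: recovery_tolerance must be in (0, 1)", call. = FALSE)
  if (creatinine_floor <= 0)
    stop("qc_params: creatinine_floor must be positive", call. = FALSE)
  structure(list(recovery_tolerance = recovery_tolerance,
                 creatinine_floor = creatinine_floor), class = "qc_params")
}

#' Resolve sample QC status
#'
#' Marks each pending sample `fail_recovery` if the absolute
#' internal-standard recovery deviation is at or beyond the tolerance,
#' otherwise `fail_creatinine` if creatinine is below the floor, otherwise
#' `pass`. The two filters are independent predicates; `fail_recovery`
#' takes precedence only in the reported reason. A sample with a `fail_*`
#' status never enters any downstream mean.
#'
#' @param samples urine-sample data frame (`recovery_deviation`,
#'   `creatinine` columns).
#' @param params a [qc_params()] object.
#' @return The input with `qc_status` resolved.
#' @export
qc_samples <- function(samples, params = qc_params()) {
  status <- rep("pass", nrow(samples))
  status[samples$creatinine < params$creatinine_floor] <- "fail_creatinine"
  status[abs(samples$recovery_deviation) >= params$recovery_tolerance] <-
    "fail_recovery"
  samples$qc_status <- status
  samples
}

#' Total urinary glucocorticoids
#'
#' Total uGC is the arithmetic sum of cortisol and its four major urinary
#' metabolites (see [ugc_analytes]), in ng per ml urine.
#'
#' @param analyte_conc a named numeric vector, or a data frame with the
#'   five analyte columns (then summed row-wise).
#' @return Total uGC, ng/ml (vector for data-frame input).
#' @examples
#' sum_ugc(c(cortisol = 9, tetrahydrocortisol = 37, tetrahydrocortisone = 35,
#'           androstane_5b = 5, oxoetiocholanolone_11 = 14))  # 100
#' @export
sum_ugc <- function(analyte_conc) {
  if (is.data.frame(analyte_conc)) {
    missing <- setdiff(ugc_analytes, names(analyte_conc))
    if (length(missing))
      stop("sum_ugc: missing analyte(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    m <- as.matrix(analyte_conc[ugc_analytes])
    if (any(m < 0, na.rm = TRUE))
      stop("sum_ugc: negative analyte concentration", call. = FALSE)
    return(rowSums(m))
  }
  missing <- setdiff(ugc_analytes, names(analyte_conc))
  if (length(missing))
    stop("sum_ugc: missing analyte(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- analyte_conc[ugc_analytes]
  if (any(v < 0)) stop("sum_ugc: negative analyte concentration",
                       call. = FALSE)
  sum(v)
}

#' Creatinine correction
#'
#' Divides total uGC (ng per ml urine) by creatinine (mg per ml urine) to
#' control for differences in urine water content, giving ng uGC per mg
#' creatinine. Dilution-invariant: diluting a sample scales both numerator
#' and denominator identically.
#'
#' @param ugc total uGC, ng/ml.
#' @param creatinine creatinine, mg/ml; must be positive (QC removes
#'   near-zero creatinine samples upstream).
#' @return Corrected uGC, ng per mg creatinine.
#' @export
creatinine_correct <- function(ugc, creatinine) {
  if (any(creatinine <= 0))
    stop("creatinine_correct: creatinine must be positive (QC should have ",
         "removed this sample)", call. = FALSE)
  ugc / creatinine
}

#' Event-level relative uGC
#'
#' The within-event response statistic: the mean creatinine-corrected uGC of
#' peak-period samples as a percentage of the pre-period mean,
#' `100 * mean(peak) / mean(pre)`. Using a within-event ratio cancels
#' between-subject and diurnal baseline differences. Means are unweighted
#' arithmetic means over QC-passing whole samples. The value is kept at
#' full precision; rounding to one decimal happens only at the reporting
#' boundary ([write_event_results()]).
#'
#' @param series a `sample_series` from [assign_periods()] whose samples
#'   carry a `ugc_corrected` column, or any data frame with `period`,
#'   `ugc_corrected` and (optionally) `qc_status` columns.
#' @return Relative uGC, percent (unrounded).
#' @examples
#' d <- data.frame(period = c("pre", "pre", "peak"),
#'                 ugc_corrected = c(50, 70, 90))
#' relative_ugc(d)  # 150
#' @export
relative_ugc <- function(series) {
  d <- if (inherits(series, "sample_series")) series$samples else series
  if (!"ugc_corrected" %in% names(d))
    stop("relative_ugc: samples need a 'ugc_corrected' column", call. = FALSE)
  pass <- if ("qc_status" %in% names(d)) d$qc_status == "pass"
          else rep(TRUE, nrow(d))
  pre <- d$ugc_corrected[pass & d$period == "pre"]
  peak <- d$ugc_corrected[pass & d$period == "peak"]
  if (!length(pre) || !length(peak))
    stop("relative_ugc: incomplete sample set (need >= 1 QC-passing sample ",
         "in each of the pre and peak periods)", call. = FALSE)
  100 * mean(peak) / mean(pre)
}

#' Run the full per-event quantification pipeline
#'
#' For each behavioural event: QC the event's samples ([qc_samples()]),
#' assign them to periods ([assign_periods()]), sum and creatinine-correct
#' uGC, and compute the relative uGC level. Events without at least one
#' QC-passing sample in each period are returned with `complete = FALSE`
#' and `NA` relative uGC.
#'
#' @param samples urine-sample table (event-relative `collection_time`).
#' @param events behavioural-event table.
#' @param wparams a [window_params()] object.
#' @param qparams a [qc_params()] object.
#' @return Event-level data frame: `event_id`, `subject_id`, `behaviour`,
#'   `relative_ugc` (percent, unrounded, `NA` if incomplete), `duration`,
#'   `rank`, `role`, `intensity`, `complete`, `n_pre`, `n_peak`.
#' @export
process_events <- function(samples, events, wparams = window_params(),
                           qparams = qc_params()) {
  stopifnot(nrow(events) >= 1)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    sm <- samples[samples$event_id == ev$event_id, , drop = FALSE]
    sm <- qc_samples(sm, qparams)
    ser <- assign_periods(sm, ev, wparams)
    d <- ser$samples
    pass <- d$qc_status == "pass"
    d$ugc_corrected <- NA_real_
    if (any(pass))
      d$ugc_corrected[pass] <- creatinine_correct(
        sum_ugc(d[pass, , drop = FALSE]), d$creatinine[pass])
    rel <- if (ser$complete) {
      relative_ugc(d)
    } else NA_real_
    data.frame(event_id = ev$event_id, subject_id = ev$subject_id,
               behaviour = ev$behaviour, relative_ugc = rel,
               duration = ev$duration, rank = ev$rank, role = ev$role,
               intensity = ev$intensity, complete = ser$complete,
               n_pre = sum(pass & d$period == "pre"),
               n_peak = sum(pass & d$period == "peak"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
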