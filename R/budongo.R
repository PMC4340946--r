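#' Event-level relative uGC responses of nine wild adult male chimpanzees
#'
#' The package's canonical worked example: 24 complete event series (14
#' aggressive interactions — 4 as aggressor, 10 as victim; 9 contact and 5
#' non-contact — and 10 resting controls) recorded for nine adult male
#' chimpanzees of the Sonso community, Budongo Forest, Uganda. Each row is
#' one behavioural event with its relative uGC level, i.e. the mean
#' creatinine-corrected urinary glucocorticoid level of peak-window samples
#' as a percentage of the pre-window mean.
#'
#' Factor levels are ordered so that treatment contrasts use the
#' conventional reference levels: `resting` for `behaviour` and `role3`,
#' `non_contact` for `intensity`.
#'
#' @return A data frame with 24 rows and columns:
#' \describe{
#'   \item{subject_id}{subject code (9 distinct males)}
#'   \item{behaviour}{factor, `resting` (reference) or `aggression`}
#'   \item{relative_ugc}{relative uGC level, percent}
#'   \item{duration}{duration of the behaviour, minutes (aggression 1–3,
#'     resting 30–125)}
#'   \item{rank}{dominance rank, 1 = highest of the nine males}
#'   \item{role}{factor: `aggressor`, `victim`, or `none` for resting}
#'   \item{intensity}{factor: `contact`, `non_contact`, or `none`}
#'   \item{role3}{factor combining behaviour and role:
#'     `resting` (reference), `aggressor`, `victim`}
#' }
#' @examples
#' d <- budongo_ugc()
#' table(d$behaviour)
#' aggregate(relative_ugc ~ behaviour, d, mean)
#' @export
budongo_ugc <- function() {
  d <- data.frame(
    subject_id = c("HW", "NK", "SQ", "ZF", "BB", "FD", "HW", "KT", "MS",
                   "NK", "NK", "SQ", "ZF", "ZF",
                   "FD", "HW", "HW", "KT", "MS", "NK", "NK", "SQ", "TK", "ZF"),
    behaviour = factor(c(rep("aggression", 14), rep("resting", 10)),
                       levels = c("resting", "aggression")),
    relative_ugc = c(104.5, 122.5, 111.4, 92.5, 146.1, 95.6, 65.6, 115.8,
                     140.6, 170.1, 82.0, 80.4, 128.7, 107.1,
                     54.3, 85.9, 69.4, 145.3, 49.6, 91.4, 99.7, 87.5, 82.9,
                     81.3),
    duration = c(2, 1, 1, 1, 3, 2, 3, 3, 1, 2, 2, 3, 2, 1,
                 30, 115, 60, 125, 45, 50, 30, 45, 60, 60),
    rank = c(7L, 1L, 6L, 4L, 2L, 9L, 7L, 5L, 3L, 1L, 1L, 6L, 4L, 4L,
             9L, 7L, 7L, 5L, 3L, 1L, 1L, 6L, 8L, 4L),
    role = factor(c(rep("aggressor", 4), rep("victim", 10), rep("none", 10)),
                  levels = c("none", "aggressor", "victim")),
    intensity = factor(c("contact", "contact", "contact", "non_contact",
                         "non_contact", "contact", "contact", "non_contact",
                         "contact", "contact", "non_contact", "contact",
                         "non_contact", "contact", rep("none", 10)),
                       levels = c("none", "non_contact", "contact")),
    stringsAsFactors = FALSE
  )
  d$role3 <- factor(ifelse(d$behaviour == "resting", "resting",
                           as.character(d$role)),
                    levels = c("resting", "aggressor", "victim"))
  d
}

#' Number of urine samples behind the worked-example dataset
#'
#' The field study behind [budongo_ugc()] collected 169 urine samples across
#' the 24 event series (94 in the aggression context, 75 in the resting
#' context). `sampling_intensity()` returns the mean number of samples
#' collected per subject per target behaviour, i.e. samples divided by
#' event series.
#'
#' @param n_samples total number of urine samples collected.
#' @param n_events number of event series they cover.
#' @return Mean samples per event series (numeric scalar).
#' @examples
#' sampling_intensity()       # 7.04 for the embedded study
#' @export
sampling_intensity <- function(n_samples = 169, n_events = 24) {
  stopifnot(n_samples >= 0, n_events > 0)
  n_samples / n_events
}
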