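#' Group summaries of event-level relative uGC
#'
#' Mean and SD of relative uGC by target behaviour and by behaviour/role
#' (aggressor, victim, resting).
#'
#' @param data event-level data frame with `behaviour`, `role3` (or `role`
#'   plus `behaviour`), and `relative_ugc` columns; defaults to the
#'   embedded example.
#' @return Data frame with columns `group`, `n`, `mean`, `sd`.
#' @examples
#' group_summaries()
#' @export
group_summaries <- function(data = budongo_ugc()) {
  if (!"role3" %in% names(data))
    data$role3 <- factor(ifelse(data$behaviour == "resting", "resting",
                                as.character(data$role)),
                         levels = c("resting", "aggressor", "victim"))
  one <- function(label, v) data.frame(group = label, n = length(v),
                                       mean = mean(v), sd = stats::sd(v))
  rbind(
    one("aggression", data$relative_ugc[data$behaviour == "aggression"]),
    one("resting", data$relative_ugc[data$behaviour == "resting"]),
    one("aggressor", data$relative_ugc[data$role3 == "aggressor"]),
    one("victim", data$relative_ugc[data$role3 == "victim"])
  )
}

#' Fit the reference suite of mixed models on an event-level table
#'
#' Runs the five-model analysis of behavioural predictors of relative uGC,
#' each as a Gaussian LMM (random intercept per subject, ML) compared
#' against its intercept-only null by likelihood-ratio test:
#'
#' \describe{
#'   \item{behaviour}{aggression vs. resting (reference), all events.}
#'   \item{role}{aggressor / victim / resting (reference), all events.}
#'   \item{rank}{numeric dominance rank (1 = highest), all events. The
#'     rank slope is estimated across aggression and resting events
#'     jointly: relative uGC after any arousing or control event may vary
#'     with rank, and the larger table stabilizes the slope.}
#'   \item{duration}{behaviour duration in minutes, aggression events only
#'     (resting durations are an order of magnitude larger and measure a
#'     different quantity).}
#'   \item{intensity}{contact vs. non-contact (reference), aggression
#'     events only, with a leave-one-subject-out stability check.}
#' }
#'
#' The role model is additionally re-run with aggressor as the reference
#' level (`role_rerun`) so the aggressor–victim contrast is directly
#' estimated; the re-parametrization leaves the likelihood unchanged.
#'
#' @param data event-level data frame in the schema of [budongo_ugc()];
#'   rows with `NA` relative uGC are dropped.
#' @return List of class `ugc_reference` with per-model elements
#'   (`fit`, `null`, `lrt`, and for intensity `stability`), plus
#'   `summaries` ([group_summaries()]) and `vif` (collinearity check of
#'   rank + duration on the aggression rows).
#' @examples
#' rep <- reference_models()
#' rep$behaviour$fit$beta
#' rep$behaviour$lrt$chi2
#' @export
reference_models <- function(data = budongo_ugc()) {
  d <- data[!is.na(data$relative_ugc), , drop = FALSE]
  if (!"role3" %in% names(d))
    d$role3 <- factor(ifelse(d$behaviour == "resting", "resting",
                             as.character(d$role)),
                      levels = c("resting", "aggressor", "victim"))
  d$behaviour <- stats::relevel(factor(d$behaviour), "resting")
  agg <- droplevels(d[d$behaviour == "aggression", , drop = FALSE])
  agg$intensity <- stats::relevel(factor(agg$intensity), "non_contact")

  null_all <- fit_lmm(relative_ugc ~ 1, d, "subject_id")
  null_agg <- fit_lmm(relative_ugc ~ 1, agg, "subject_id")

  mod <- function(formula, dat, null) {
    fit <- fit_lmm(formula, dat, "subject_id")
    list(fit = fit, null = null, lrt = lrt(fit, null))
  }

  behaviour <- mod(relative_ugc ~ behaviour, d, null_all)
  role <- mod(relative_ugc ~ role3, d, null_all)
  d_re <- d
  d_re$role3 <- stats::relevel(d_re$role3, "aggressor")
  role_rerun <- fit_lmm(relative_ugc ~ role3, d_re, "subject_id")
  rank <- mod(relative_ugc ~ rank, d, null_all)
  duration <- mod(relative_ugc ~ duration, agg, null_agg)
  intensity <- mod(relative_ugc ~ intensity, agg, null_agg)
  intensity$stability <- tryCatch(
    stability_check(relative_ugc ~ intensity, agg, "subject_id"),
    error = function(e) e)

  structure(list(
    behaviour = behaviour, role = role, role_rerun = role_rerun,
    rank = rank, duration = duration, intensity = intensity,
    summaries = group_summaries(d),
    vif = vif_check(relative_ugc ~ rank + duration, agg),
    data = d
  ), class = "ugc_reference")
}

#' Tabulate a reference analysis
#'
#' Flattens a [reference_models()] result into one machine-readable table:
#' one row per fixed-effect term with its estimate, SE and t, carrying the
#' model-level likelihood-ratio chi-square, df and p.
#'
#' @param x a `ugc_reference` object.
#' @param ... unused.
#' @return Data frame with columns `model`, `term`, `beta`, `se`, `t`,
#'   `chi2`, `df`, `p`, `stable`.
#' @export
as.data.frame.ugc_reference <- function(x, ...) {
  rows <- lapply(c("behaviour", "role", "rank", "duration", "intensity"),
                 function(nm) {
    m <- x[[nm]]
    keep <- names(m$fit$beta) != "(Intercept)"
    stable <- if (nm == "intensity" && inherits(m$stability, "ugc_stability"))
      m$stability$stable else NA
    data.frame(model = nm, term = names(m$fit$beta)[keep],
               beta = unname(m$fit$beta[keep]), se = unname(m$fit$se[keep]),
               t = unname(m$fit$t[keep]), chi2 = m$lrt$chi2, df = m$lrt$df,
               p = m$lrt$p, stable = stable, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.ugc_reference <- function(x, ...) {
  cat("Relative uGC reference analysis\n\n")
  cat("Group summaries (relative uGC, %):\n")
  s <- x$summaries
  s$mean <- round(s$mean, 1); s$sd <- round(s$sd, 1)
  print(s, row.names = FALSE)
  cat("\nModel comparisons (LMM vs intercept-only null, ML):\n")
  tab <- as.data.frame(x)
  tab$beta <- round(tab$beta, 2); tab$se <- round(tab$se, 2)
  tab$t <- round(tab$t, 2); tab$chi2 <- round(tab$chi2, 2)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  if (inherits(x$intensity$stability, "ugc_stability") &&
      !x$intensity$stability$stable)
    cat("\nnote: the intensity model is unstable under ",
        "leave-one-subject-out refits\n", sep = "")
  invisible(x)
}
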