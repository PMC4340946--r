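test_that("window bounds follow the clearance formula", {
  expect_equal(event_window_bounds(list(duration = 2)),
               c(t0 = 0, t1 = 135, t2 = 272))
  expect_equal(event_window_bounds(list(duration = 30)),
               c(t0 = 0, t1 = 135, t2 = 300))
  expect_equal(event_window_bounds(list(duration = 125))[["t2"]], 395)
  expect_error(event_window_bounds(list(duration = 0)), "positive")
  expect_error(window_params(overlap_len = 300), "overlap_len")
  expect_error(window_params(pre_window_len = -1), "positive")
})

test_that("period assignment matches the stated latency rule", {
  ## plain pre-period sample
  expect_equal(prod_assign(100, d = 2), "pre")
  ## overlap after t1: sample latency 5 < previous-void latency 15 -> pre
  expect_equal(prod_assign(c(120, 140), d = 2), c("pre", "pre"))
  ## overlap after t1: latency 25 > 2 -> stays peak
  expect_equal(prod_assign(c(133, 160), d = 2), c("pre", "peak"))
  ## no previous void: overlap sample keeps its excretion period
  expect_equal(prod_assign(140, d = 2), "peak")
  ## tie keeps the excretion period ("smaller than" is strict)
  expect_equal(prod_assign(c(125, 145), d = 2), c("pre", "peak"))
  ## t2 overlap: close to t2 with distant previous void -> peak
  expect_equal(prod_assign(c(200, 275), d = 2), c("peak", "peak"))
  ## t2 overlap resolved to its excretion side -> excluded
  expect_equal(prod_assign(c(270, 300), d = 2), c("peak", "excluded"))
  ## outside the study window entirely
  expect_equal(prod_assign(c(-10, 310), d = 2), c("excluded", "excluded"))
})

test_that("every sample gets exactly one label and completeness is counted", {
  set.seed(7)
  for (i in 1:50) {
    d <- sample(c(1, 2, 3, 30, 60), 1)
    times <- sort(runif(sample(1:8, 1), -50, 350))
    ser <- assign_periods(data.frame(collection_time = times),
                          list(duration = d))
    expect_false(any(is.na(ser$samples$period)))
    expect_equal(nrow(ser$samples), length(times))
    expect_equal(ser$complete,
                 any(ser$samples$period == "pre") &&
                   any(ser$samples$period == "peak"))
  }
  ## empty sample list: incomplete, not an error
  ser0 <- assign_periods(data.frame(collection_time = numeric(0)),
                         list(duration = 2))
  expect_false(ser0$complete)
})

test_that("shifting an overlap sample later never moves it earlier", {
  ## fixed previous void at 120; sweep the overlap sample across the zone
  labels <- vapply(seq(136, 165, by = 1), function(s)
    prod_assign(c(120, s), d = 2)[2], character(1))
  ## once it leaves 'pre' it must never return
  first_peak <- match("peak", labels)
  if (!is.na(first_peak))
    expect_true(all(labels[first_peak:length(labels)] == "peak"))
})

test_that("clock-time inputs and event-relative inputs give identical labels", {
  times_rel <- c(50, 120, 140, 280)
  ev_abs <- data.frame(event_id = "E1", subject_id = "S1",
                       behaviour = "aggression", start_time = 412,
                       duration = 2, role = "victim", intensity = "contact",
                       rank = 3)
  s_abs <- make_samples(times_rel + 412, event_id = "E1")
  f <- tempfile(fileext = ".csv")
  utils::write.csv(s_abs, f, row.names = FALSE, quote = FALSE)
  s_conv <- read_samples(f, events = ev_abs)
  expect_equal(s_conv$collection_time, times_rel)
  expect_equal(prod_assign(s_conv$collection_time, d = 2),
               prod_assign(times_rel, d = 2))
  unlink(f)
})

test_that("behavioural event QC applies the contamination windows", {
  ev <- list(start_time = 500, duration = 2)
  log1 <- data.frame(time = 470, behaviour = "grooming")
  expect_equal(qc_event(ev, log1), "reject_pre_contamination")
  log2 <- data.frame(time = 500 + 2 + 90, behaviour = "aggression")
  expect_equal(qc_event(ev, log2), "abort_post_contamination")
  expect_equal(qc_event(ev, data.frame(time = numeric(0),
                                       behaviour = character(0))), "keep")
  ## just outside both windows, or non-contaminating behaviour
  expect_equal(qc_event(ev, data.frame(time = 430, behaviour = "grooming")),
               "keep")
  expect_equal(qc_event(ev, data.frame(time = 640, behaviour = "grooming")),
               "keep")
  expect_equal(qc_event(ev, data.frame(time = 470, behaviour = "feeding")),
               "keep")
})
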