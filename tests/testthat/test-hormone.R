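test_that("sample QC applies recovery and creatinine thresholds", {
  s <- make_samples(c(10, 20, 30, 40),
                    creatinine = c(0.04, 0.5, 0.5, 0.049),
                    recovery = c(0, 0.60, -0.1, -0.75))
  q <- qc_samples(s)
  expect_equal(q$qc_status,
               c("fail_creatinine", "fail_recovery", "pass",
                 "fail_recovery"))
  ## the boundary itself fails: the rule is 'deviating by LESS than 50%'
  s2 <- make_samples(1, recovery = 0.50)
  expect_equal(qc_samples(s2)$qc_status, "fail_recovery")
  s3 <- make_samples(1, creatinine = 0.05)
  expect_equal(qc_samples(s3)$qc_status, "pass")
  expect_error(qc_params(recovery_tolerance = 1.2), "recovery_tolerance")
})

test_that("QC filters are independent predicates: survivors are unchanged by order", {
  set.seed(11)
  s <- make_samples(1:40, creatinine = runif(40, 0, 0.2),
                    recovery = runif(40, -1, 1))
  q <- qc_samples(s)
  survive <- q$qc_status == "pass"
  expect_equal(survive,
               abs(s$recovery_deviation) < 0.5 & s$creatinine >= 0.05)
})

test_that("uGC summation adds the five analytes and names missing ones", {
  expect_equal(sum_ugc(c(cortisol = 9, tetrahydrocortisol = 37,
                         tetrahydrocortisone = 35, androstane_5b = 5,
                         oxoetiocholanolone_11 = 14)), 100)
  expect_equal(sum_ugc(stats::setNames(rep(0, 5), ugc_analytes)), 0)
  expect_equal(sum_ugc(stats::setNames(rep(1, 5), ugc_analytes)), 5)
  expect_error(sum_ugc(c(cortisol = 9)), "tetrahydrocortisol")
  ## data-frame input is row-wise
  s <- make_samples(1:3, ugc = c(100, 50, 10))
  expect_equal(sum_ugc(s), c(100, 50, 10))
})

test_that("creatinine correction divides and is dilution invariant", {
  expect_equal(creatinine_correct(100, 0.5), 200)
  expect_equal(creatinine_correct(0, 2), 0)
  expect_error(creatinine_correct(10, 0), "positive")
  set.seed(3)
  for (i in 1:20) {
    x <- runif(1, 1, 500)
    cr <- runif(1, 0.05, 3)
    expect_equal(creatinine_correct(x * cr, cr), x, tolerance = 1e-12)
  }
})

test_that("relative uGC is the peak/pre mean ratio with stated edge cases", {
  d <- data.frame(period = c("pre", "pre", "peak"),
                  ugc_corrected = c(50, 70, 90))
  expect_equal(relative_ugc(d), 150)
  d2 <- data.frame(period = c("pre", "peak"), ugc_corrected = c(5, 5))
  expect_equal(relative_ugc(d2), 100)
  d3 <- data.frame(period = c("pre", "peak"), ugc_corrected = c(80, 40))
  expect_equal(relative_ugc(d3), 50)
  ## incomplete series is an error, and QC-failed samples never count
  d4 <- data.frame(period = c("pre", "peak"), ugc_corrected = c(80, 40),
                   qc_status = c("pass", "fail_recovery"))
  expect_error(relative_ugc(d4), "incomplete")
  expect_error(relative_ugc(data.frame(period = "pre", ugc_corrected = 1)),
               "incomplete")
})

test_that("relative uGC is scale invariant and swap-reciprocal", {
  set.seed(9)
  for (i in 1:25) {
    n_pre <- sample(1:4, 1); n_peak <- sample(1:4, 1)
    d <- data.frame(period = rep(c("pre", "peak"), c(n_pre, n_peak)),
                    ugc_corrected = runif(n_pre + n_peak, 10, 400))
    r <- relative_ugc(d)
    expect_gt(r, 0)
    k <- runif(1, 0.01, 50)
    d_scaled <- d; d_scaled$ugc_corrected <- d_scaled$ugc_corrected * k
    expect_equal(relative_ugc(d_scaled), r, tolerance = 1e-12)
    d_swap <- d
    d_swap$period <- ifelse(d$period == "pre", "peak", "pre")
    expect_equal(relative_ugc(d_swap), 10000 / r, tolerance = 1e-9)
  }
})

test_that("reported values round half up at one decimal only at the boundary", {
  tab <- data.frame(relative_ugc = c(104.25, 99.94999, 100.05))
  f <- tempfile(fileext = ".csv")
  write_event_results(tab, f)
  out <- utils::read.csv(f)
  expect_equal(out$relative_ugc, c(104.3, 99.9, 100.1))
  unlink(f)
})

test_that("the per-event pipeline drops QC failures and flags incomplete events", {
  ev <- data.frame(event_id = c("E1", "E2"), subject_id = c("S1", "S2"),
                   behaviour = c("aggression", "resting"),
                   start_time = c(0, 0), duration = c(2, 30),
                   role = c("victim", "none"),
                   intensity = c("contact", "none"), rank = c(1, 2),
                   stringsAsFactors = FALSE)
  ## E1: pre mean 200 (two samples), peak 300 -> 150%
  ## a QC-failing pre sample with a wild value must not change the mean
  s1 <- make_samples(c(60, 120, 130, 200), ugc = c(100, 100, 5000, 150),
                     creatinine = c(0.5, 0.5, 0.04, 0.5), event_id = "E1",
                     subject_id = "S1")
  ## E2: no peak-period sample -> incomplete
  s2 <- make_samples(c(50, 100), ugc = 100, event_id = "E2",
                     subject_id = "S2")
  tab <- process_events(rbind(s1, s2), ev)
  expect_equal(tab$relative_ugc[1], 150)
  expect_equal(tab$n_pre[1], 2)
  expect_false(tab$complete[2])
  expect_true(is.na(tab$relative_ugc[2]))
})
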