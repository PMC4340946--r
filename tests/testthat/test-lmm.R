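test_that("zero-variance boundary reproduces the OLS/ML closed form", {
  d <- budongo_ugc()
  fit <- fit_lmm(relative_ugc ~ behaviour, d, "subject_id")
  expect_equal(fit$sigma2_subject, 0)
  oracle <- ols_ml_oracle(relative_ugc ~ behaviour, d)
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-6)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  expect_equal(fit$sigma2_resid, oracle$sigma2, tolerance = 1e-6)
  ## the group-mean difference closed form
  expect_equal(unname(fit$beta["behaviouraggression"]),
               mean(d$relative_ugc[d$behaviour == "aggression"]) -
                 mean(d$relative_ugc[d$behaviour == "resting"]),
               tolerance = 1e-9)
})

test_that("an interior variance optimum matches lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  set.seed(21)
  n_subj <- 12
  subj <- rep(sprintf("S%02d", 1:n_subj), each = 15)
  b <- rnorm(n_subj, 0, 10)[as.integer(factor(subj))]
  x <- rnorm(length(subj))
  y <- 50 + 4 * x + b + rnorm(length(subj), 0, 5)
  d <- data.frame(y = y, x = x, subj = subj)
  fit <- fit_lmm(y ~ x, d, "subj")
  expect_gt(fit$sigma2_subject, 0)
  ref <- lme4::lmer(y ~ x + (1 | subj), data = d, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_subject, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$se),
               unname(coef(summary(ref))[, "Std. Error"]), tolerance = 1e-4)
})

test_that("estimates are invariant to row permutation and reference recoding", {
  d <- budongo_ugc()
  fit <- fit_lmm(relative_ugc ~ role3, d, "subject_id")
  set.seed(5)
  d_perm <- d[sample(nrow(d)), ]
  fit_perm <- fit_lmm(relative_ugc ~ role3, d_perm, "subject_id")
  expect_equal(fit_perm$beta, fit$beta, tolerance = 1e-9)
  expect_equal(fit_perm$loglik, fit$loglik, tolerance = 1e-9)
  ## recoding the reference changes the parametrization only
  d_re <- d
  d_re$role3 <- stats::relevel(d_re$role3, "aggressor")
  fit_re <- fit_lmm(relative_ugc ~ role3, d_re, "subject_id")
  expect_equal(fit_re$loglik, fit$loglik, tolerance = 1e-9)
  expect_equal(sort(unname(fit_re$fitted)), sort(unname(fit$fitted)),
               tolerance = 1e-9)
  ## aggressor -> victim contrast equals the difference of the main betas
  expect_equal(unname(fit_re$beta["role3victim"]),
               unname(fit$beta["role3victim"] - fit$beta["role3aggressor"]),
               tolerance = 1e-9)
})

test_that("degenerate and invalid designs are handled as specified", {
  d <- budongo_ugc()
  ## identical responses: zero effects and zero variances
  d0 <- d; d0$relative_ugc <- 100
  fit0 <- fit_lmm(relative_ugc ~ behaviour, d0, "subject_id")
  expect_equal(unname(fit0$beta["behaviouraggression"]), 0)
  expect_equal(fit0$sigma2_resid, 0)
  expect_equal(fit0$sigma2_subject, 0)
  ## collinear design names the offending column
  d2 <- d; d2$dup <- as.integer(d2$behaviour == "aggression")
  expect_error(fit_lmm(relative_ugc ~ behaviour + dup, d2, "subject_id"),
               "dup")
  ## single group
  d3 <- d[d$subject_id == "NK", ]
  expect_error(fit_lmm(relative_ugc ~ behaviour, d3, "subject_id"),
               "2 groups")
})

test_that("likelihood-ratio test validates nesting and data identity", {
  d <- budongo_ugc()
  full <- fit_lmm(relative_ugc ~ behaviour, d, "subject_id")
  null <- fit_lmm(relative_ugc ~ 1, d, "subject_id")
  lt <- lrt(full, null)
  expect_equal(lt$df, 1)
  ## likelihood never decreases when adding a fixed effect
  expect_gte(lt$chi2, -1e-8)
  ## identical models: no extra parameters
  expect_error(lrt(full, full), "extra parameters")
  ## different data
  null14 <- fit_lmm(relative_ugc ~ 1, d[d$behaviour == "aggression", ],
                    "subject_id")
  expect_error(lrt(full, null14), "same data")
  ## non-nested fixed effects
  other <- fit_lmm(relative_ugc ~ rank, d, "subject_id")
  expect_error(lrt(full, other), "nested")
})

test_that("variance inflation factors match the auxiliary-regression oracle", {
  d <- budongo_ugc()
  agg <- d[d$behaviour == "aggression", ]
  ## single predictor: definitional 1
  expect_equal(unname(vif_check(relative_ugc ~ rank, agg)), 1)
  ## orthogonal predictors: both 1
  dd <- data.frame(y = rnorm(8), a = rep(c(-1, 1), 4),
                   b = rep(c(-1, -1, 1, 1), 2))
  expect_equal(unname(vif_check(y ~ a + b, dd)), c(1, 1))
  ## duplicated predictor: infinite, not an error
  dd$a2 <- dd$a
  expect_equal(unname(vif_check(y ~ a + a2, dd)), c(Inf, Inf))
  ## cross-check against car on the rank+duration design
  skip_if_not_installed("car")
  v <- vif_check(relative_ugc ~ rank + duration, agg)
  vref <- car::vif(stats::lm(relative_ugc ~ rank + duration, agg))
  expect_equal(unname(v), unname(vref), tolerance = 1e-8)
  expect_true(all(v < 2))
})

test_that("leave-one-subject-out stability flags sign flips", {
  d <- budongo_ugc()
  st <- stability_check(relative_ugc ~ behaviour, d, "subject_id")
  expect_true(st$stable)
  expect_equal(length(st$refits), 9)
  ## every refit keeps a positive aggression effect
  est <- st$estimates[, "behaviouraggression"]
  expect_true(all(est > 0, na.rm = TRUE))

  ## intensity model on the aggression rows is unstable
  agg <- droplevels(d[d$behaviour == "aggression", ])
  agg$intensity <- stats::relevel(agg$intensity, "non_contact")
  st2 <- stability_check(relative_ugc ~ intensity, agg, "subject_id")
  expect_false(st2$stable)

  ## constructed outlier subject that flips the sign
  dd <- data.frame(
    subj = rep(c("A", "B", "C", "D"), each = 2),
    x = rep(c(0, 1), 4),
    y = c(10, 11, 10, 12, 10, 11, 10, -40))
  st3 <- stability_check(y ~ x, dd, "subj")
  expect_false(st3$stable)
  expect_true(any(grepl("sign flip", st3$reasons)))
})
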