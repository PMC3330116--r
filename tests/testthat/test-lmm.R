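test_that("inverse normal transform produces Blom scores and is rank-invariant", {
  got <- inverse_normal_transform(c(1, 2, 3))
  expected <- qnorm((1:3 - 3 / 8) / (3 + 1 / 4))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got[2], 0)

  set.seed(12)
  x <- rnorm(50)
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(exp(x)),
               tolerance = 1e-12)

  z <- inverse_normal_transform(rnorm(100))
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(sd(z) - 1), 0.05)

  x2 <- c(1, NA, 3, 2)
  t2 <- inverse_normal_transform(x2)
  expect_true(is.na(t2[2]))
  expect_equal(sum(is.na(t2)), 1)

  const <- inverse_normal_transform(c(2, 2, 2))
  expect_true(all(is.na(const)))
  expect_true(attr(const, "degenerate"))
  expect_error(inverse_normal_transform(c(1, 2)), ">= 3")
})

test_that("twin LMM matches lme4 on ML log-likelihood and fixed effects", {
  skip_if_not_installed("lme4")
  set.seed(21)
  co <- pairs_cohort(40, 60)
  y <- sim_twin_response(co, s2f = 0.5, s2z = 0.4, s2e = 1, beta_age = 0.05)
  fit <- fit_lmm(y, co, covariates = "chip_position",
                 extra = list(age = co$age))
  df <- data.frame(y = y, age = co$age, cp = co$chip_position,
                   fam = co$family_id,
                   mz = as.numeric(co$zygosity == "MZ"))
  ref <- lme4::lmer(y ~ cp + age + (1 | fam) + (0 + mz | fam), data = df,
                    REML = FALSE)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-5)
  expect_equal(fit$coefficients$estimate,
               unname(lme4::fixef(ref))[c(1, 2, 3)], tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(unname(fit$varcomp["s2f"]), vc$vcov[1], tolerance = 1e-3)
  expect_equal(unname(fit$varcomp["s2z"]), vc$vcov[2], tolerance = 1e-3)
})

test_that("variance components are recovered at scale", {
  set.seed(22)
  co <- pairs_cohort(400, 400)
  y <- sim_twin_response(co, s2f = 0.5, s2z = 0.3, s2e = 1)
  fit <- fit_lmm(y, co, covariates = "chip_position")
  expect_lt(abs(fit$varcomp["s2f"] - 0.5), 0.1)
  expect_lt(abs(fit$varcomp["s2z"] - 0.3), 0.1)
  expect_lt(abs(fit$varcomp["s2e"] - 1.0), 0.1)
})

test_that("zero-variance truth degenerates to ordinary least squares", {
  set.seed(23)
  co <- pairs_cohort(50, 50)
  y <- sim_twin_response(co, s2f = 0, s2z = 0, s2e = 1, beta_age = 0.1)
  fit <- fit_lmm(y, co, covariates = "chip_position",
                 extra = list(age = co$age))
  ols <- lm(y ~ co$chip_position + co$age)
  expect_lt(max(abs(fit$coefficients$estimate - unname(coef(ols)))), 1e-2)
  expect_lt(fit$varcomp["s2f"], 0.05)
  expect_lt(fit$varcomp["s2z"], 0.05)
})

test_that("planted fixed effects are covered by +-3 SE in most simulations", {
  set.seed(24)
  co <- pairs_cohort(60, 60)
  hit <- logical(100)
  for (r in seq_len(100)) {
    y <- sim_twin_response(co, s2f = 0.4, s2z = 0.3, s2e = 1) +
      2.0 * scale(co$age)[, 1]
    names(y) <- co$individual_id
    fit <- fit_lmm(y, co, covariates = "chip_position",
                   extra = list(age = scale(co$age)[, 1]))
    est <- fit$coefficients[term == "age"]
    hit[r] <- abs(est$estimate - 2.0) <= 3 * est$se
  }
  expect_gte(mean(hit), 0.95)
})

test_that("LRT follows chi-square arithmetic and is scale invariant", {
  f <- list(logLik = -100, n_used = 50, mode = "ML", ids = letters[1:5],
            coefficients = data.table::data.table(term = c("a", "b")))
  n <- f; n$coefficients <- f$coefficients[1]
  class(f) <- class(n) <- "twin_lmm_fit"
  expect_equal(lrt_compare(f, n)$p, 1)
  f2 <- f; f2$logLik <- -100 + 3.84 / 2
  expect_equal(lrt_compare(f2, n)$p, pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(lrt_compare(f2, n)$p, 2), 0.05)

  set.seed(25)
  co <- pairs_cohort(40, 40)
  y <- sim_twin_response(co, s2f = 0.3, s2z = 0.2, s2e = 1, beta_age = 0.02)
  full1 <- fit_lmm(y, co, extra = list(age = co$age))
  null1 <- fit_lmm(y, co)
  y2 <- 7 + 3.2 * y
  names(y2) <- names(y)
  full2 <- fit_lmm(y2, co, extra = list(age = co$age))
  null2 <- fit_lmm(y2, co)
  expect_equal(lrt_compare(full1, null1)$statistic,
               lrt_compare(full2, null2)$statistic, tolerance = 1e-4)

  expect_error(lrt_compare(null1, full1), "not nested")
})

test_that("MZ-only designs absorb the pair variance without NaN", {
  set.seed(26)
  co <- pairs_cohort(60, 0)
  y <- sim_twin_response(co, s2f = 0.3, s2z = 0.3, s2e = 1)
  fit <- fit_lmm(y, co)
  expect_true(fit$varcomp_aliased["mz"])
  expect_equal(unname(fit$varcomp["s2z"]), 0)
  # the pair covariance lands in the family component
  expect_lt(abs(fit$varcomp["s2f"] - 0.6), 0.25)
  expect_false(anyNA(fit$coefficients$se))
})

test_that("rank-deficient fixed designs drop aliased columns with a warning", {
  set.seed(27)
  co <- pairs_cohort(30, 30)
  y <- sim_twin_response(co, s2e = 1)
  expect_warning(
    fit <- fit_lmm(y, co, covariates = "chip_position",
                   extra = list(dup = co$chip_position)),
    "aliased")
  expect_equal(length(fit$aliased_terms), 1L)
})
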