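test_that("record log likelihood matches hand-computed truncated values", {
  fix <- const_coefs(r = 2, p = 0.5)
  rec <- function(y) data.frame(age_band = "20-25", gender = "male",
                                usual_drinks = 2, drinking_days = 5,
                                last_occasion_drinks = y)
  expect_equal(occasion_loglik(rec(1), fix), log(1 / 3))   # 0.25 / 0.75
  expect_equal(occasion_loglik(rec(2), fix), log(0.25))
  expect_equal(occasion_loglik(rec(20), fix),
               censored_mass(2, 0.5, bound = 20, log = TRUE))
  cohort <- simulate_cohort(100, coeffs = fix, seed = 3)
  expect_true(all(occasion_loglik(cohort, fix) <= 0))
})

test_that("summed likelihood equals the convolution brute force", {
  # integer-r fixture so the oracle pmf can be built by exhaustive
  # convolution, independent of dnbinom
  fix <- const_coefs(r = 3, p = 0.45)
  cohort <- simulate_cohort(200, coeffs = fix, seed = 9)
  pmf <- conv_nb_pmf(3, 0.45, ymax = 60)
  cond <- pmf / (1 - pmf[1])
  brute <- vapply(cohort$last_occasion_drinks, function(y) {
    if (y >= 20) log((1 - sum(pmf[1:20])) / (1 - pmf[1]))
    else log(cond[y + 1])
  }, numeric(1))
  expect_equal(sum(occasion_loglik(cohort, fix)), sum(brute),
               tolerance = 1e-8)
})

test_that("intercept-only truth is recovered within 3 SE", {
  truth <- const_coefs(r = 2.6, p = 0.55)
  cohort <- simulate_cohort(6000, coeffs = truth, seed = 21)
  fit <- nbdrink(cohort, terms = list(r = "const", p = "const"))
  expect_true(fit$converged)
  expect_lt(abs(fit$par["r:const"] - log(1.6)) / fit$se["r:const"], 3)
  expect_lt(abs(fit$par["p:const"] - qlogis(0.55)) / fit$se["p:const"], 3)
  # optimiser improved on its own starting point
  expect_gte(fit$logLik, fit$logLik_start)
  # observed information is positive definite at the optimum
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("fits are reproducible and carry Wald intervals", {
  cohort <- simulate_cohort(3000, seed = 33)
  tm <- list(r = c("const", "log_inv_K", "log_M"),
             p = c("const", "log_inv_K", "log_M"))
  f1 <- nbdrink(cohort, terms = tm)
  f2 <- nbdrink(cohort, terms = tm)
  expect_identical(serialize(f1[c("par", "se", "logLik")], NULL),
                   serialize(f2[c("par", "se", "logLik")], NULL))
  ci <- f1$coefficients$r_ci
  expect_true(all(ci[, 1] <= f1$coefficients$r & f1$coefficients$r <= ci[, 2]))
})

test_that("degenerate all-ones outcome is flagged, not silently fitted", {
  cohort <- simulate_cohort(400, seed = 2)
  cohort$last_occasion_drinks <- 1L
  expect_warning(
    fit <- nbdrink(cohort, terms = list(r = "const", p = "const")),
    "convergence|caution")
  expect_false(fit$converged)
  # stopping probability is driven to the boundary
  expect_gt(plogis(fit$par["p:const"]), 0.99)
})

test_that("sample-size guard refuses underdetermined fits", {
  cohort <- simulate_cohort(100, seed = 4)
  expect_error(nbdrink(cohort), "too few records")
})

test_that("alpha = 1 elimination removes nothing and equals the plain fit", {
  cohort <- simulate_cohort(3000, seed = 14)
  tm <- list(r = c("const", "log_inv_K", "log_M"),
             p = c("const", "log_inv_K", "log_M"))
  plain <- nbdrink(cohort, terms = tm)
  elim <- nbdrink(cohort, terms = tm, eliminate = TRUE, alpha = 1)
  expect_equal(elim$par, plain$par)
  expect_equal(nrow(elim$elimination), 1)
  expect_equal(elim$elimination$removed, "")
})

test_that("elimination drops a null term and keeps strong ones", {
  # usual-drinks effect truly present in r only; drinking-days effect
  # absent everywhere, so the added log_M unit should be swept out
  gen <- nbdrink_coefs(r = c(const = 0.6, log_inv_K = -1.5),
                       p = c(const = 1.0))
  cohort <- simulate_cohort(12000, coeffs = gen, seed = 77)
  tm <- list(r = c("const", "log_inv_K"), p = c("const", "log_M"))
  fit <- nbdrink(cohort, terms = tm, eliminate = TRUE)
  su <- summary(fit)$wald_units
  expect_true(all(su$p_value < 0.05))           # stopping condition held
  expect_true("log_inv_K" %in% fit$terms$r)
  expect_false("log_M" %in% fit$terms$p)
  expect_gte(nrow(fit$elimination), 1)
})

test_that("linked parameters feed the probability chain end to end", {
  coeffs <- reference_coefficients()
  prof <- data.frame(age_band = "35-49", gender = "female",
                     usual_drinks = 3, drinking_days = 20)
  rp <- link_rp(prof, coeffs)
  manual <- dnbinom(3, size = rp$r, prob = rp$p) /
    (1 - dnbinom(0, size = rp$r, prob = rp$p))
  expect_equal(dtruncnb(3, rp$r, rp$p), manual, tolerance = 1e-12)
  risk <- predict_risk(prof, coeffs, thresholds = 5)
  expect_equal(risk$days_5, exceedance_prob(5, rp$r, rp$p) * 20)
})

test_that("pearson residuals are centred near zero under the truth", {
  truth <- const_coefs(r = 2, p = 0.5)
  cohort <- simulate_cohort(4000, coeffs = truth, seed = 8)
  fit <- nbdrink(cohort, terms = list(r = "const", p = "const"))
  res <- residuals(fit, cohort)
  expect_lt(abs(mean(res)), 0.1)
})
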