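test_that("pmf matches closed-form and convolution values", {
  expect_equal(dnbocc(0, r = 2, p = 0.5), 0.25)
  expect_equal(dnbocc(2, r = 2, p = 0.5), 0.1875)          # C(3,2) 0.25 0.25
  expect_equal(dnbocc(1, r = 3, p = 0.9), 3 * 0.9^3 * 0.1) # 0.2187
  # non-integer r goes through log-gamma, not factorials
  expect_equal(dnbocc(3, r = 2.5, p = 0.4),
               exp(lgamma(5.5) - lgamma(2.5) - lfactorial(3) +
                   2.5 * log(0.4) + 3 * log(0.6)))
})

test_that("pmf and cdf reject invalid parameters", {
  expect_error(dnbocc(1, r = -1, p = 0.5), "'r'")
  expect_error(dnbocc(1, r = 2, p = 0), "'p'")
  expect_error(dnbocc(1, r = 2, p = 1), "'p'")
  expect_error(dnbocc(-1, r = 2, p = 0.5), "integer")
  expect_error(dnbocc(1.5, r = 2, p = 0.5), "integer")
  expect_error(pnbocc(1, r = 2, p = NA_real_), "missing")
})

test_that("cdf accumulates the pmf and normalises", {
  expect_equal(pnbocc(0, r = 2, p = 0.5), 0.25)
  expect_equal(pnbocc(1, r = 2, p = 0.5), 0.5)  # 0.25 + 2 * 0.25 * 0.5
  expect_equal(pnbocc(1e6, r = 2, p = 0.5), 1, tolerance = 1e-12)
  for (r in c(1.3, 2, 4.7)) for (p in c(0.2, 0.6, 0.9)) {
    ys <- 0:40
    expect_equal(pnbocc(40, r, p), sum(dnbocc(ys, r, p)), tolerance = 1e-12)
  }
})

test_that("pmf sums to one over a tail-bounded support", {
  for (r in c(1.1, 2, 5.5)) for (p in c(0.1, 0.5, 0.9)) {
    ymax <- 0
    while (pnbocc(ymax, r, p, lower.tail = FALSE) > 1e-14) ymax <- ymax + 50
    expect_equal(sum(dnbocc(0:ymax, r, p)), 1, tolerance = 1e-10)
  }
})

test_that("integer-r pmf equals the geometric-convolution oracle", {
  for (r in 1:5) for (p in c(0.25, 0.5, 0.75)) {
    expect_equal(dnbocc(0:50, r, p), conv_nb_pmf(r, p, 50),
                 tolerance = 1e-10)
  }
})

test_that("cdf agrees with the regularized incomplete beta", {
  # P(Y <= y) = I_p(r, y + 1)
  for (r in c(1.7, 3, 6.2)) for (p in c(0.3, 0.65)) for (y in c(0, 4, 19))
    expect_equal(pnbocc(y, r, p), pbeta(p, r, y + 1), tolerance = 1e-12)
})

test_that("zero-truncated pmf matches the published worked probabilities", {
  expect_equal(dtruncnb(2, r = 2, p = 0.5), 0.25)
  expect_equal(round(dtruncnb(3, r = 2, p = 0.5), 3), 0.167)
  expect_equal(round(dtruncnb(4, r = 2, p = 0.5), 3), 0.104)
  expect_error(dtruncnb(0, r = 2, p = 0.5), "integer")
})

test_that("conditional exceedance matches worked values and is monotone", {
  expect_equal(exceedance_prob(1, r = 2, p = 0.5), 1)
  expect_equal(exceedance_prob(1, r = 4.2, p = 0.123), 1)
  expect_equal(round(exceedance_prob(2, r = 2, p = 0.5), 3), 0.667)
  expect_equal(round(exceedance_prob(3, r = 2, p = 0.5), 3), 0.417)
  expect_equal(exceedance_prob(4, r = 2, p = 0.5), 0.25)
  ex <- exceedance_prob(1:30, r = 2.5, p = 0.4)
  expect_true(all(diff(ex) < 0))
  # decreasing in p at fixed y, r
  ps <- seq(0.05, 0.95, by = 0.05)
  for (y in c(2, 5, 12))
    expect_true(all(diff(exceedance_prob(y, r = 3, p = ps)) < 0))
})

test_that("censored tail mass completes the conditional distribution", {
  expect_equal(censored_mass(r = 2, p = 0.5, bound = 2),
               exceedance_prob(2, 2, 0.5))
  cm <- censored_mass(r = 2, p = 0.5, bound = 20)
  expect_gt(cm, 0); expect_lt(cm, 1)
  for (r in c(1.4, 2, 5.1)) for (p in c(0.2, 0.5, 0.8)) {
    total <- sum(dtruncnb(1:19, r, p)) + censored_mass(r, p, bound = 20)
    expect_equal(total, 1, tolerance = 1e-12)
  }
  expect_error(censored_mass(2, 0.5, bound = 1), "bound")
})

test_that("truncated sampler reproduces truncated-NB moments and shape", {
  set.seed(42)
  r <- 2; p <- 0.5
  y <- rtruncnb(2e5, r, p)
  expect_true(all(y >= 1))
  m_true <- (r * (1 - p) / p) / (1 - p^r)             # E[Y | Y >= 1]
  v_true <- (r * (1 - p) / p^2 + (r * (1 - p) / p)^2) / (1 - p^r) - m_true^2
  expect_lt(abs(mean(y) - m_true), 3 * sqrt(v_true / length(y)))
  # chi-square goodness of fit against the analytic conditional pmf
  ycap <- pmin(y, 15)
  probs <- c(dtruncnb(1:14, r, p),
             1 - sum(dtruncnb(1:14, r, p)))
  gof <- suppressWarnings(chisq.test(tabulate(ycap, 15), p = probs))
  expect_gt(gof$p.value, 0.001)
})
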