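test_that("design vector applies the drinking-norm transforms", {
  X <- build_design(data.frame(age_band = "35-49", gender = "female",
                               usual_drinks = 3, drinking_days = 20))
  expect_equal(unname(X[1, "log_inv_K"]), log(1 / 3), tolerance = 1e-10)
  expect_equal(unname(X[1, "log_inv_K_sq"]), log(1 / 3)^2, tolerance = 1e-10)
  expect_equal(unname(X[1, "log_M"]), log(20), tolerance = 1e-10)
  expect_equal(unname(X[1, "log_M_sq"]), log(20)^2, tolerance = 1e-10)
  expect_equal(unname(X[1, "female"]), 1)
  expect_equal(unname(X[1, "age35-49"]), 1)
  expect_equal(sum(X[1, grep("^age", colnames(X))]), 1)

  # reference category with K = M = 1: only the intercept column is non-zero
  X0 <- build_design(data.frame(age_band = "20-25", gender = "male",
                                usual_drinks = 1, drinking_days = 1))
  expect_equal(unname(X0[1, ]), c(1, rep(0, ncol(X0) - 1)))

  Xb <- build_design(data.frame(age_band = "65+", gender = "female",
                                usual_drinks = 24, drinking_days = 30))
  expect_equal(unname(Xb[1, "log_inv_K"]), log(1 / 24))
  expect_equal(unname(Xb[1, "log_M"]), log(30))
  expect_equal(unname(Xb[1, "age65+"]), 1)
})

test_that("design transforms respect their sign constraints", {
  grid <- expand.grid(usual_drinks = c(1, 2, 13, 24),
                      drinking_days = c(1, 2, 17, 30))
  grid$age_band <- "30-34"; grid$gender <- "male"
  X <- build_design(grid)
  expect_true(all(X[, "log_inv_K"] <= 0))
  expect_true(all((X[, "log_inv_K"] == 0) == (grid$usual_drinks == 1)))
  expect_true(all(X[, "log_M"] >= 0))
  expect_true(all((X[, "log_M"] == 0) == (grid$drinking_days == 1)))
})

test_that("profile validation names the offending field", {
  base <- data.frame(age_band = "20-25", gender = "male",
                     usual_drinks = 2, drinking_days = 5)
  bad <- base; bad$usual_drinks <- 25
  expect_error(build_design(bad), "usual_drinks")
  bad <- base; bad$drinking_days <- 0
  expect_error(build_design(bad), "drinking_days")
  bad <- base; bad$gender <- "other"
  expect_error(build_design(bad), "gender")
  bad <- base; bad$age_band <- "17-19"
  expect_error(build_design(bad), "age_band")
})

test_that("ages in years map onto the nine bands", {
  expect_equal(as.character(age_to_band(c(12, 14, 15, 17, 18, 19, 20, 25,
                                          26, 29, 30, 34, 35, 49, 50, 64,
                                          65, 90))),
               rep(age_bands(), each = 2))
  expect_error(age_to_band(11), "age_years")
  # en-dash labels are accepted
  X <- build_design(data.frame(age_band = "35–49", gender = "male",
                               usual_drinks = 2, drinking_days = 2))
  expect_equal(unname(X[1, "age35-49"]), 1)
})

test_that("reference coefficients reproduce the published worked example", {
  coeffs <- reference_coefficients()
  prof <- data.frame(age_band = "35-49", gender = "female",
                     usual_drinks = 3, drinking_days = 20)
  expect_equal(compute_r(prof, coeffs), 5.49, tolerance = 0.01 / 5.49)
  expect_equal(compute_p(prof, coeffs), 0.648, tolerance = 0.002 / 0.648)

  # the male counterpart simply drops the age and gender offsets from r
  male <- transform(prof, age_band = "20-25", gender = "male")
  eta_f <- log(compute_r(prof, coeffs) - 1)
  expect_equal(compute_r(male, coeffs),
               1 + exp(eta_f + 0.081 + 0.079), tolerance = 1e-10)
  # and p carries no age/gender terms at all in this set
  expect_equal(compute_p(male, coeffs), compute_p(prof, coeffs))
})

test_that("all-zero coefficients give the link reference point", {
  zero <- nbdrink_coefs(r = c(const = 0), p = c(const = 0))
  prof <- demo_profiles()
  expect_equal(compute_r(prof, zero), rep(2, nrow(prof)))
  expect_equal(compute_p(prof, zero), rep(0.5, nrow(prof)))
})

test_that("model-implied mean occasion size increases with usual drinks", {
  coeffs <- reference_coefficients()
  for (M in c(2, 10, 20, 30)) {
    grid <- data.frame(age_band = "30-34", gender = "male",
                       usual_drinks = 1:24, drinking_days = M)
    rp <- link_rp(grid, coeffs)
    mu <- rp$r * (1 - rp$p) / rp$p
    expect_true(all(diff(mu) > 0))
  }
})

test_that("coefficient sets validate their term names", {
  expect_error(nbdrink_coefs(r = c(const = 1, bogus = 2),
                             p = c(const = 0)), "bogus")
  expect_error(nbdrink_coefs(r = c(female = 1), p = c(const = 0)), "const")
  expect_error(nbdrink_coefs(r = c(1, 2), p = c(const = 0)), "named")
})

test_that("coefficient JSON round-trips losslessly", {
  coeffs <- reference_coefficients()
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients(coeffs, path)
  back <- read_coefficients(path)
  expect_equal(back$r, coeffs$r)
  expect_equal(back$p, coeffs$p)
  expect_equal(back$r_ci, coeffs$r_ci)
  expect_equal(back$p_ci, coeffs$p_ci)
})
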