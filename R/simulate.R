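#' Simulate a survey-like drinker cohort from the occasion model
#'
#' Generates microdata with exactly the statistical structure the model
#' assumes, so that estimation, prediction and validation can be exercised
#' without survey data.  Per respondent: covariates are drawn from
#' configurable marginal distributions; the linked \eqn{(r_j, p_j)} follow
#' from `coeffs`; the last-occasion drink count is drawn from the
#' zero-truncated negative binomial and right-censored at `bound`; the
#' count of days with 5+ drinks is Binomial(M, \eqn{P(Y \ge 5 | Y \ge 1)}),
#' and for females the 4+ count is Binomial(M, \eqn{P(Y \ge 4 | Y \ge 1)})
#' (males get NA, mirroring the survey instrument).
#'
#' The default covariate marginals are fixture choices, not estimates of
#' any survey population: age weights roughly uniform over adult bands
#' with small mass on the minor bands, P(female) = 0.5,
#' K ~ 1 + Poisson(2) truncated at 24, and M ~ 1 + Binomial(29, 0.25).
#'
#' @param n Number of respondents (>= 1).
#' @param coeffs Generating `nbdrink_coefs` (default
#'   [reference_coefficients()]).
#' @param seed Optional integer seed; when supplied the cohort is a pure
#'   function of the arguments.
#' @param age_weights Named numeric weights over [age_bands()]
#'   (normalised internally).
#' @param p_female Probability a respondent is female.
#' @param K_sampler,M_sampler Functions `n -> integer vector` drawing
#'   usual drinks (1..24) and drinking days (1..30).
#' @param bound Censoring bound applied to the last-occasion count.
#' @return A cohort data.frame with columns `age_band`, `gender`,
#'   `usual_drinks`, `drinking_days`, `last_occasion_drinks`,
#'   `days_5plus`, `days_4plus` — the schema [nbdrink()] and
#'   [read_cohort()] use.
#' @examples
#' head(simulate_cohort(5, seed = 1))
#' @export
simulate_cohort <- function(n, coeffs = reference_coefficients(),
                            seed = NULL,
                            age_weights = default_age_weights(),
                            p_female = 0.5,
                            K_sampler = default_K_sampler,
                            M_sampler = default_M_sampler,
                            bound = 20) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != floor(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(age_weights)) ||
      !setequal(names(age_weights), age_bands()) ||
      any(age_weights < 0) || sum(age_weights) <= 0)
    stop("'age_weights' must be non-negative weights named by age_bands()",
         call. = FALSE)
  age <- sample(age_bands(), n, replace = TRUE,
                prob = age_weights[age_bands()] / sum(age_weights))
  gender <- ifelse(stats::runif(n) < p_female, "female", "male")
  K <- K_sampler(n)
  M <- M_sampler(n)
  data <- data.frame(age_band = age, gender = gender,
                     usual_drinks = as.integer(K),
                     drinking_days = as.integer(M))
  data <- validate_profiles(data)
  rp <- link_rp(data, coeffs)
  y <- rtruncnb(n, rp$r, rp$p)
  data$last_occasion_drinks <- as.integer(pmin(y, bound))
  data$days_5plus <- stats::rbinom(n, size = M,
                                   prob = exceedance_prob(5, rp$r, rp$p))
  data$days_4plus <- ifelse(
    data$gender == "female",
    stats::rbinom(n, size = M, prob = exceedance_prob(4, rp$r, rp$p)),
    NA_integer_)
  data
}

#' @rdname simulate_cohort
#' @export
default_age_weights <- function() {
  w <- c("12-14" = 0.02, "15-17" = 0.04, "18-19" = 0.06, "20-25" = 0.16,
         "26-29" = 0.12, "30-34" = 0.12, "35-49" = 0.22, "50-64" = 0.16,
         "65+" = 0.10)
  w
}

#' @rdname simulate_cohort
#' @export
default_K_sampler <- function(n) pmin(1 + stats::rpois(n, 2), 24)

#' @rdname simulate_cohort
#' @export
default_M_sampler <- function(n) 1 + stats::rbinom(n, 29, 0.25)

#' Simulate method for fitted occasion models
#'
#' Draws new censored last-occasion counts (and risky-day counts) for the
#' covariate rows of `newdata` under the fitted coefficients.
#'
#' @param object A fitted `nbdrink` model.
#' @param nsim Number of simulated cohorts.
#' @param seed Optional integer seed.
#' @param newdata Covariate data.frame (defaults must be supplied; the
#'   model object does not retain its training data).
#' @param ... Unused.
#' @return A list of `nsim` cohort data.frames.
#' @export
simulate.nbdrink <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  newdata <- validate_profiles(newdata)
  rp <- link_rp(newdata, object$coefficients)
  n <- nrow(newdata)
  lapply(seq_len(nsim), function(i) {
    out <- newdata
    out$last_occasion_drinks <-
      as.integer(pmin(rtruncnb(n, rp$r, rp$p), object$bound))
    out$days_5plus <- stats::rbinom(n, out$drinking_days,
                                    exceedance_prob(5, rp$r, rp$p))
    out$days_4plus <- ifelse(out$gender == "female",
                             stats::rbinom(n, out$drinking_days,
                                           exceedance_prob(4, rp$r, rp$p)),
                             NA_integer_)
    out
  })
}

#' Parameter-recovery experiment for the occasion likelihood
#'
#' Standard operating-characteristic check for a bespoke likelihood:
#' repeatedly simulate a cohort from known coefficients, refit the model
#' with the same active terms, and summarise (estimate - truth)/SE and
#' 95% CI coverage per term across replicates.
#'
#' @param reps Number of replicates.
#' @param n Cohort size per replicate (default 30000, large enough for
#'   Wald asymptotics with the full term set).
#' @param coeffs Generating coefficient set.
#' @param seed Integer seed governing the whole experiment.
#' @param ... Passed to [simulate_cohort()].
#' @return A list with `z` (replicates x terms matrix of z-scores),
#'   `covered` (logical matrix of CI coverage), `coverage` (per-term
#'   coverage rate) and `truth`.
#' @export
recovery_experiment <- function(reps = 10, n = 30000,
                                coeffs = reference_coefficients(),
                                seed = 1, ...) {
  terms <- active_terms(coeffs)
  truth <- c(stats::setNames(coeffs$r, paste0("r:", names(coeffs$r))),
             stats::setNames(coeffs$p, paste0("p:", names(coeffs$p))))
  z <- covered <- matrix(NA_real_, reps, length(truth),
                         dimnames = list(NULL, names(truth)))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  for (i in seq_len(reps)) {
    cohort <- simulate_cohort(n, coeffs = coeffs, seed = rep_seeds[i], ...)
    fit <- nbdrink(cohort, terms = terms)
    z[i, ] <- (fit$par[names(truth)] - truth) / fit$se[names(truth)]
    covered[i, ] <- abs(z[i, ]) <= 1.96
  }
  list(z = z, covered = covered == 1,
       coverage = colMeans(covered), truth = truth)
}
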