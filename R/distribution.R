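#' Negative binomial occasion distribution
#'
#' Probability machinery for the per-occasion drink count \eqn{Y}, modelled
#' as the sum of \eqn{r} independent geometric "mini drinking episodes":
#' each episode contributes the number of drinks consumed before the drinker
#' stops, where stopping has per-drink probability \eqn{p}.  \eqn{Y} is then
#' negative binomial in the failures-before-the-r-th-success
#' parameterization,
#' \deqn{P(Y = y \mid r, p) = \frac{\Gamma(y + r)}{\Gamma(r)\, y!}\,
#'       p^r (1 - p)^y,}
#' with mean \eqn{r(1-p)/p}.  \eqn{r} need not be an integer (the covariate
#' link makes it continuous).
#'
#' `dnbocc()` and `pnbocc()` are the unconditional pmf and cdf.  Because
#' only people who drank at least once in the observation window are
#' modelled, the workhorse quantities condition on \eqn{Y \ge 1}:
#' `dtruncnb()` is the zero-truncated pmf
#' \eqn{P(Y = y \mid Y \ge 1) = P(Y = y)/(1 - P(Y = 0))},
#' `exceedance_prob()` is \eqn{P(Y \ge y \mid Y \ge 1)}, and
#' `censored_mass()` is the right-censoring tail
#' \eqn{P(Y \ge c \mid Y \ge 1)} for a reporting bound \eqn{c}
#' (20 drinks in the survey instrument the model was built for).
#'
#' All arguments recycle to a common length.  Probability arithmetic is
#' carried out on the log scale and exponentiated at the boundary.
#'
#' @param y Non-negative integer drink counts.  `dtruncnb()` and
#'   `exceedance_prob()` require `y >= 1` (zero is excluded by the
#'   conditioning event).
#' @param r Number of mini episodes; positive real, non-integer allowed.
#' @param p Per-drink probability of stopping; in (0, 1).
#' @param log,log.p Logical; return log probabilities?
#' @param bound Censoring bound \eqn{c \ge 2}; counts at or above it are
#'   reported as the bound.
#' @param lower.tail Logical; if `FALSE`, `pnbocc()` returns
#'   \eqn{P(Y > y)}.
#' @return A numeric vector of probabilities (or log probabilities).
#' @examples
#' dnbocc(0, r = 2, p = 0.5)          # p^r = 0.25
#' dtruncnb(2, r = 2, p = 0.5)        # 0.25
#' exceedance_prob(2:4, r = 2, p = 0.5)
#' censored_mass(r = 2, p = 0.5, bound = 20)
#' @name occasion-distribution
NULL

check_rp <- function(r, p, r_floor = 0) {
  if (!is.numeric(r) || !is.numeric(p))
    stop("'r' and 'p' must be numeric", call. = FALSE)
  if (anyNA(r) || anyNA(p))
    stop("'r' and 'p' must not contain missing values", call. = FALSE)
  if (any(r <= r_floor))
    stop(sprintf("'r' must be > %g", r_floor), call. = FALSE)
  if (any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  invisible(TRUE)
}

check_count <- function(y, lower = 0, name = "y") {
  if (!is.numeric(y) || anyNA(y) || any(y < lower) || any(y != floor(y)))
    stop(sprintf("'%s' must be integer-valued and >= %d", name, lower),
         call. = FALSE)
  invisible(TRUE)
}

#' @rdname occasion-distribution
#' @export
dnbocc <- function(y, r, p, log = FALSE) {
  check_rp(r, p)
  check_count(y)
  stats::dnbinom(y, size = r, prob = p, log = log)
}

#' @rdname occasion-distribution
#' @export
pnbocc <- function(y, r, p, lower.tail = TRUE, log.p = FALSE) {
  check_rp(r, p)
  check_count(y)
  stats::pnbinom(y, size = r, prob = p, lower.tail = lower.tail,
                 log.p = log.p)
}

# log P(Y >= 1) = log(1 - p^r), computed without cancellation
log_ptrunc <- function(r, p) {
  log1mexp(r * log(p))
}

# log(1 - exp(x)) for x < 0, numerically stable both near 0 and -Inf
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

#' @rdname occasion-distribution
#' @export
dtruncnb <- function(y, r, p, log = FALSE) {
  check_rp(r, p)
  check_count(y, lower = 1)
  lp <- stats::dnbinom(y, size = r, prob = p, log = TRUE) - log_ptrunc(r, p)
  if (log) lp else exp(lp)
}

#' @rdname occasion-distribution
#' @export
exceedance_prob <- function(y, r, p, log = FALSE) {
  check_rp(r, p)
  check_count(y, lower = 1)
  lp <- stats::pnbinom(y - 1, size = r, prob = p, lower.tail = FALSE,
                       log.p = TRUE) - log_ptrunc(r, p)
  lp <- pmin(lp, 0)  # guard rounding at y = 1, where the ratio is exactly 1
  if (log) lp else exp(lp)
}

#' @rdname occasion-distribution
#' @export
censored_mass <- function(r, p, bound = 20, log = FALSE) {
  check_count(bound, lower = 2, name = "bound")
  exceedance_prob(bound, r, p, log = log)
}

#' Draw zero-truncated negative binomial occasion counts
#'
#' Samples from \eqn{P(Y = y \mid Y \ge 1)} by the inverse-cdf method:
#' a uniform variate is drawn on \eqn{(P(Y = 0), 1)} and passed through the
#' negative binomial quantile function, which is exact and rejection-free
#' even when \eqn{P(Y = 0)} is large.  `r` and `p` may be vectors of length
#' `n` for individual-specific parameters.
#'
#' @param n Number of draws.
#' @inheritParams occasion-distribution
#' @return Integer vector of `n` positive counts.
#' @examples
#' set.seed(1)
#' table(rtruncnb(1000, r = 2, p = 0.5))
#' @export
rtruncnb <- function(n, r, p) {
  check_rp(r, p)
  if (length(n) != 1 || n < 1 || n != floor(n))
    stop("'n' must be a positive integer", call. = FALSE)
  p0 <- exp(r * log(p))
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(u, size = r, prob = p)
}
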