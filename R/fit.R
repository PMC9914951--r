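#' Per-record log likelihood of the truncated, censored occasion model
#'
#' The sampling model for the observed last-occasion drink count is the
#' negative binomial conditioned on drinking at all (\eqn{Y \ge 1}) and
#' right-censored at the reporting bound: a record with
#' `last_occasion_drinks` \eqn{y < } `bound` contributes
#' \eqn{\log P(Y = y \mid Y \ge 1)}, and a record at the bound contributes
#' the tail mass \eqn{\log P(Y \ge \mathrm{bound} \mid Y \ge 1)}.
#'
#' @param data Cohort data.frame (see [read_cohort()] for the schema);
#'   must contain `last_occasion_drinks` alongside the covariates.
#' @param coeffs An `nbdrink_coefs` object.
#' @param bound Censoring bound (drinks); counts at or above it are
#'   treated as censored.
#' @return Numeric vector of per-record log-likelihood contributions
#'   (all \eqn{\le 0}).
#' @examples
#' cohort <- simulate_cohort(50, seed = 1)
#' sum(occasion_loglik(cohort, reference_coefficients()))
#' @export
occasion_loglik <- function(data, coeffs, bound = 20) {
  data <- validate_records(data, bound = bound)
  rp <- link_rp(data, coeffs)
  y <- data$last_occasion_drinks
  ll <- numeric(nrow(data))
  cen <- y >= bound
  if (any(!cen))
    ll[!cen] <- dtruncnb(y[!cen], rp$r[!cen], rp$p[!cen], log = TRUE)
  if (any(cen))
    ll[cen] <- censored_mass(rp$r[cen], rp$p[cen], bound = bound, log = TRUE)
  if (any(!is.finite(ll)))
    stop("non-finite log likelihood for record(s) ",
         paste(utils::head(which(!is.finite(ll)), 5), collapse = ", "),
         call. = FALSE)
  ll
}

# Validate a cohort data.frame: covariates plus outcome columns.
validate_records <- function(data, bound = 20) {
  data <- validate_profiles(data)
  y <- data$last_occasion_drinks
  if (is.null(y))
    stop("missing required column 'last_occasion_drinks'", call. = FALSE)
  if (anyNA(y) || any(y < 1) || any(y > bound) || any(y != floor(y)))
    stop("'last_occasion_drinks' must be an integer in 1..", bound,
         " (recode larger values to the bound; drop non-drinkers)",
         call. = FALSE)
  for (col in c("days_5plus", "days_4plus")) {
    d <- data[[col]]
    if (!is.null(d)) {
      ok <- is.na(d) | (d >= 0 & d <= data$drinking_days & d == floor(d))
      if (!all(ok))
        stop("'", col, "' must be an integer in 0..drinking_days; ",
             "offending row(s): ",
             paste(utils::head(which(!ok), 5), collapse = ", "),
             call. = FALSE)
    }
  }
  data
}

ETA_R_CAP <- 50  # exp() overflow guard on the r linear predictor
P_EPS <- 1e-12   # keep p strictly inside (0, 1)

# Map the stacked parameter vector to per-observation (r, p).
par_to_rp <- function(par, Xr, Xp) {
  nr <- ncol(Xr)
  eta_r <- pmin(drop(Xr %*% par[seq_len(nr)]), ETA_R_CAP)
  eta_p <- drop(Xp %*% par[nr + seq_len(ncol(Xp))])
  list(r = 1 + exp(eta_r),
       p = pmin(pmax(stats::plogis(eta_p), P_EPS), 1 - P_EPS))
}

# Closures for the negative log likelihood and its analytic gradient.
# y: observed counts, cen: censored flags, Xr/Xp: active design matrices.
make_objective <- function(y, cen, Xr, Xp, bound) {
  unc <- !cen
  y_u <- y[unc]
  ygrid <- 0:(bound - 1)

  nll <- function(par) {
    rp <- par_to_rp(par, Xr, Xp)
    r <- rp$r; p <- rp$p
    ll <- -sum(log1mexp(r * log(p)))  # zero-truncation divisor
    if (any(unc))
      ll <- ll + sum(stats::dnbinom(y_u, size = r[unc], prob = p[unc],
                                    log = TRUE))
    if (any(cen))  # far from the optimum the tail can underflow; the
      ll <- ll +   # non-finite guard below turns that into a rejection
        sum(suppressWarnings(
          stats::pnbinom(bound - 1, size = r[cen], prob = p[cen],
                         lower.tail = FALSE, log.p = TRUE)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  grad <- function(par) {
    rp <- par_to_rp(par, Xr, Xp)
    r <- rp$r; p <- rp$p
    lp <- log(p)
    dldr <- numeric(length(y))
    dldp <- numeric(length(y))
    if (any(unc)) {
      r_u <- r[unc]; p_u <- p[unc]
      dldr[unc] <- digamma(y_u + r_u) - digamma(r_u) + log(p_u)
      dldp[unc] <- r_u / p_u - y_u / (1 - p_u)
    }
    if (any(cen)) {
      r_c <- r[cen]; p_c <- p[cen]
      # d log S / d theta with S = P(Y >= bound): differentiate the finite
      # head sum F(bound-1) term by term
      nc <- length(r_c)
      fmat <- wr <- wp <- matrix(0, nc, length(ygrid))
      for (k in seq_along(ygrid)) {
        yk <- ygrid[k]
        fmat[, k] <- stats::dnbinom(yk, size = r_c, prob = p_c)
        wr[, k] <- digamma(yk + r_c) - digamma(r_c) + log(p_c)
        wp[, k] <- r_c / p_c - yk / (1 - p_c)
      }
      S <- suppressWarnings(stats::pnbinom(bound - 1, size = r_c,
                                           prob = p_c, lower.tail = FALSE))
      dldr[cen] <- -rowSums(fmat * wr) / S
      dldp[cen] <- -rowSums(fmat * wp) / S
    }
    # truncation term -log(1 - p^r), shared by all records
    q <- exp(r * lp)
    denom <- -expm1(r * lp)
    dldr <- dldr + q * lp / denom
    dldp <- dldp + r * q / (p * denom)
    g_etar <- dldr * (r - 1)
    g_etap <- dldp * p * (1 - p)
    g <- c(colSums(Xr * g_etar), colSums(Xp * g_etap))
    if (any(!is.finite(g))) g[!is.finite(g)] <- 0
    -g
  }

  list(nll = nll, grad = grad)
}

# Moment-matching starting intercepts from the raw outcome, slopes at zero.
start_values <- function(y, terms) {
  m <- mean(y); v <- stats::var(y)
  p0 <- if (is.finite(v) && v > m) m / v else 0.5
  p0 <- min(max(p0, 0.05), 0.95)
  r0 <- max(m * p0 / (1 - p0), 1.1)
  par <- c(stats::setNames(numeric(length(terms$r)), paste0("r:", terms$r)),
           stats::setNames(numeric(length(terms$p)), paste0("p:", terms$p)))
  par["r:const"] <- log(r0 - 1)
  par["p:const"] <- stats::qlogis(p0)
  par
}

fit_one <- function(data, terms, start_par, bound, control) {
  X <- build_design(data)
  Xr <- X[, terms$r, drop = FALSE]
  Xp <- X[, terms$p, drop = FALSE]
  y <- data$last_occasion_drinks
  cen <- y >= bound
  obj <- make_objective(y, cen, Xr, Xp, bound)
  ctrl <- utils::modifyList(list(maxit = 1000, reltol = 1e-12), control)
  nll0 <- obj$nll(start_par)
  opt <- stats::optim(start_par, obj$nll, obj$grad, method = "BFGS",
                      control = ctrl)
  hess_vcov <- function(par) {
    H <- stats::optimHess(par, obj$nll, obj$grad)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    list(vc = vc, pd = !is.null(vc) && all(diag(vc) > 0))
  }
  hv <- hess_vcov(opt$par)
  if (opt$convergence != 0 || !hv$pd) {
    # restart from the incumbent: BFGS curvature information is rebuilt,
    # which resolves most premature stops on flat ridges
    opt2 <- stats::optim(opt$par, obj$nll, obj$grad, method = "BFGS",
                         control = ctrl)
    if (opt2$value <= opt$value) {
      opt <- opt2
      hv <- hess_vcov(opt$par)
    }
  }
  vc <- hv$vc
  pd <- hv$pd
  se <- if (pd) sqrt(diag(vc)) else rep(NA_real_, length(opt$par))
  names(se) <- names(opt$par)
  list(par = opt$par, se = se, vcov = vc, logLik = -opt$value,
       logLik_start = -nll0,
       converged = opt$convergence == 0 && opt$value <= nll0 && pd,
       optim = opt[c("convergence", "counts", "message")],
       n_censored = sum(cen))
}

# Wald tests per removable unit: the eight age dummies are tested jointly
# (one chi-square per predictor), every other non-constant term singly.
wald_units <- function(fit_terms, par, vc) {
  out <- list()
  for (blk in c("r", "p")) {
    terms <- setdiff(fit_terms[[blk]], "const")
    if (length(terms) == 0) next
    age <- intersect(terms, age_term_names())
    single <- setdiff(terms, age)
    if (length(age) > 0) {
      idx <- paste0(blk, ":", age)
      b <- par[idx]
      W <- tryCatch(drop(t(b) %*% solve(vc[idx, idx, drop = FALSE]) %*% b),
                    error = function(e) NA_real_)
      out[[length(out) + 1]] <- data.frame(
        predictor = blk, unit = "age", df = length(age), statistic = W,
        p_value = stats::pchisq(W, df = length(age), lower.tail = FALSE))
    }
    for (tm in single) {
      idx <- paste0(blk, ":", tm)
      vd <- vc[idx, idx]
      z <- if (is.finite(vd) && vd > 0) par[idx] / sqrt(vd) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        predictor = blk, unit = tm, df = 1, statistic = z^2,
        p_value = 2 * stats::pnorm(-abs(z)))
    }
  }
  do.call(rbind, out)
}

#' Fit the per-occasion drinking model by maximum likelihood
#'
#' Estimates the covariate-linked negative binomial occasion model from a
#' cohort of past-30-day drinkers.  Each respondent's last-occasion drink
#' count is modelled as zero-truncated negative binomial with
#' \eqn{r_j = 1 + \exp(x_{rj}' \beta_r)} mini episodes and stopping
#' probability \eqn{p_j = \mathrm{plogis}(x_{pj}' \beta_p)}; counts at the
#' reporting bound enter through the censored tail mass.  The summed log
#' likelihood is maximised by BFGS with an analytic gradient, and Wald
#' standard errors come from the inverse observed information (numerical
#' Hessian at the optimum).
#'
#' With `eliminate = TRUE` the full model is pruned iteratively: after
#' each fit, every removable unit whose Wald p-value is at least `alpha`
#' is deactivated in one sweep and the model refitted, until all remaining
#' units are significant.  The eight age-band dummies form a single unit
#' (joint chi-square test, kept or removed as a block); intercepts are
#' never removed.
#'
#' @param data Cohort data.frame with columns `age_band` (or `age_years`),
#'   `gender`, `usual_drinks`, `drinking_days`, `last_occasion_drinks`.
#' @param terms Optional list with character vectors `r` and `p` naming
#'   the active terms of each linear predictor (default: all fourteen
#'   terms in both).
#' @param eliminate Logical; prune non-significant terms?
#' @param alpha Significance level for elimination (default 0.05).
#' @param start Optional named numeric vector of starting values
#'   (`r:const`, `p:log_M`, ...).  By default intercepts are moment-matched
#'   from the outcome and slopes start at zero.
#' @param bound Censoring bound on `last_occasion_drinks` (default 20).
#' @param control Passed to [stats::optim()] (`maxit`, `reltol`, ...).
#' @return An object of class `nbdrink`: a list with components
#'   `coefficients` (an [nbdrink_coefs] set with Wald 95% CIs), `par`,
#'   `se`, `vcov`, `logLik`, `n`, `n_censored`, `converged`, `terms`,
#'   `elimination` (history data.frame, or NULL), `bound` and `call`.
#' @examples
#' cohort <- simulate_cohort(2000, seed = 7)
#' fit <- nbdrink(cohort, terms = list(
#'   r = c("const", "log_inv_K", "log_inv_K_sq", "log_M", "log_M_sq"),
#'   p = c("const", "log_inv_K", "log_inv_K_sq", "log_M", "log_M_sq")))
#' summary(fit)
#' @export
nbdrink <- function(data, terms = NULL, eliminate = FALSE, alpha = 0.05,
                    start = NULL, bound = 20, control = list()) {
  cl <- match.call()
  data <- validate_records(data, bound = bound)
  if (is.null(terms))
    terms <- list(r = model_terms(), p = model_terms())
  check_terms <- function(tm, which) {
    bad <- setdiff(tm, model_terms())
    if (length(bad) > 0)
      stop("unknown term(s) in '", which, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    union("const", tm)
  }
  terms$r <- check_terms(terms$r, "terms$r")
  terms$p <- check_terms(terms$p, "terms$p")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  n_active <- length(terms$r) + length(terms$p)
  if (nrow(data) < 10 * n_active)
    stop("too few records (", nrow(data), ") for ", n_active,
         " active terms; need at least ", 10 * n_active, call. = FALSE)

  par0 <- start_values(data$last_occasion_drinks, terms)
  if (!is.null(start)) {
    keep <- intersect(names(start), names(par0))
    par0[keep] <- start[keep]
  }

  fit <- fit_one(data, terms, par0, bound, control)
  history <- NULL
  if (eliminate) {
    iter <- 0
    repeat {
      iter <- iter + 1
      if (is.null(fit$vcov))
        stop("cannot run term elimination: observed information matrix ",
             "is singular at the optimum", call. = FALSE)
      units <- wald_units(terms, fit$par, fit$vcov)
      drop_units <- units[!is.na(units$p_value) & units$p_value >= alpha, ]
      history <- rbind(history,
                       data.frame(iteration = iter,
                                  removed = if (nrow(drop_units) == 0) ""
                                    else paste(drop_units$predictor,
                                               drop_units$unit,
                                               sep = ":", collapse = ", "),
                                  logLik = fit$logLik,
                                  n_active = length(terms$r) +
                                    length(terms$p)))
      if (nrow(drop_units) == 0) break
      for (i in seq_len(nrow(drop_units))) {
        blk <- drop_units$predictor[i]
        gone <- if (drop_units$unit[i] == "age") age_term_names()
                else drop_units$unit[i]
        terms[[blk]] <- setdiff(terms[[blk]], gone)
      }
      if (all(terms$r == "const") && all(terms$p == "const"))
        warning("elimination removed every non-constant term; ",
                "returning the intercept-only model", call. = FALSE)
      par1 <- start_values(data$last_occasion_drinks, terms)
      keep <- intersect(names(fit$par), names(par1))
      par1[keep] <- fit$par[keep]
      fit <- fit_one(data, terms, par1, bound, control)
    }
  }
  if (!fit$converged)
    warning("optimizer did not report clean convergence; ",
            "inspect $optim and treat estimates with caution",
            call. = FALSE)

  split_coefs <- function(par, se, blk, terms_blk) {
    idx <- paste0(blk, ":", terms_blk)
    est <- stats::setNames(par[idx], terms_blk)
    ci <- cbind(est - 1.96 * se[idx], est + 1.96 * se[idx])
    list(est = est, ci = ci)
  }
  rr <- split_coefs(fit$par, fit$se, "r", terms$r)
  pp <- split_coefs(fit$par, fit$se, "p", terms$p)

  structure(list(
    coefficients = nbdrink_coefs(rr$est, pp$est, r_ci = rr$ci, p_ci = pp$ci),
    par = fit$par, se = fit$se, vcov = fit$vcov,
    logLik = fit$logLik, logLik_start = fit$logLik_start,
    n = nrow(data), n_censored = fit$n_censored,
    converged = fit$converged, optim = fit$optim,
    terms = terms, elimination = history, alpha = if (eliminate) alpha,
    bound = bound, call = cl), class = "nbdrink")
}

#' @export
print.nbdrink <- function(x, ...) {
  cat("Per-occasion drinking model",
      sprintf("(n = %d, %d censored at %d drinks)\n",
              x$n, x$n_censored, x$bound))
  cat(sprintf("log likelihood: %.2f; converged: %s\n",
              x$logLik, x$converged))
  if (!is.null(x$elimination))
    cat("term elimination:", nrow(x$elimination), "iteration(s)\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.nbdrink <- function(object, ...) object$par

#' @export
vcov.nbdrink <- function(object, ...) object$vcov

#' @export
logLik.nbdrink <- function(object, ...) {
  structure(object$logLik, df = length(object$par), nobs = object$n,
            class = "logLik")
}

#' @export
summary.nbdrink <- function(object, ...) {
  z <- object$par / object$se
  tab <- data.frame(estimate = object$par, se = object$se, z = z,
                    p_value = 2 * stats::pnorm(-abs(z)))
  units <- wald_units(object$terms, object$par, object$vcov)
  structure(list(coef_table = tab, wald_units = units,
                 logLik = object$logLik, n = object$n,
                 n_censored = object$n_censored,
                 converged = object$converged,
                 elimination = object$elimination),
            class = "summary.nbdrink")
}

#' @export
print.summary.nbdrink <- function(x, digits = 4, ...) {
  cat(sprintf("Per-occasion drinking model: n = %d (%d censored), logLik = %.2f\n\n",
              x$n, x$n_censored, x$logLik))
  printCoefmat(as.matrix(x$coef_table), digits = digits,
               cs.ind = 1:2, tst.ind = 3, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nWald tests per removable unit (age dummies tested as a block):\n")
  print(x$wald_units, digits = digits, row.names = FALSE)
  if (!is.null(x$elimination)) {
    cat("\nElimination history:\n")
    print(x$elimination, row.names = FALSE)
  }
  invisible(x)
}

#' @export
residuals.nbdrink <- function(object, data, type = c("pearson", "response"),
                              ...) {
  type <- match.arg(type)
  data <- validate_records(data, bound = object$bound)
  rp <- link_rp(data, object$coefficients)
  # truncated-NB moments in closed form: E[Y | Y >= 1] = E[Y]/(1 - p0)
  p0 <- exp(rp$r * log(rp$p))
  m1 <- rp$r * (1 - rp$p) / rp$p
  m2 <- rp$r * (1 - rp$p) / rp$p^2 + m1^2
  mu <- m1 / (1 - p0)
  vv <- m2 / (1 - p0) - mu^2
  res <- data$last_occasion_drinks - mu
  if (type == "pearson") res <- res / sqrt(pmax(vv, 1e-12))
  res
}
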