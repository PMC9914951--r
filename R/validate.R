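#' Binary exceedance outcome at a drink cutoff
#'
#' Recodes last-occasion drink counts into the indicator
#' \eqn{G_i = 1\{y \ge i\}} used for cutoff-wise discrimination checks.
#'
#' @param y Integer vector of drink counts.
#' @param cutoff Integer cutoff, conventionally 2..12.
#' @return Integer 0/1 vector.
#' @examples
#' binarize_outcome(c(1, 2, 3, 20), 2)
#' @export
binarize_outcome <- function(y, cutoff) {
  check_count(y, lower = 0)
  check_count(cutoff, lower = 1, name = "cutoff")
  if (length(cutoff) != 1) stop("'cutoff' must be scalar", call. = FALSE)
  as.integer(y >= cutoff)
}

#' Area under the ROC curve by the rank statistic
#'
#' Computes AUROC as the Mann-Whitney probability that a random positive
#' is scored above a random negative, with tied pairs counted one half
#' (midranks).  Returns NA with a warning when either class is absent.
#'
#' @param scores Numeric risk scores (higher = more positive).
#' @param labels 0/1 outcome vector.
#' @return AUROC in [0, 1], or NA if undefined.
#' @examples
#' auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: only one outcome class present",
            call. = FALSE)
    return(NA_real_)
  }
  rk <- rank(scores)
  (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cutoff-wise AUROC validation of predicted exceedance probabilities
#'
#' For each drink cutoff \eqn{i}: the per-respondent model probability
#' \eqn{P(Y \ge i \mid Y \ge 1)} is computed from the coefficients, its
#' natural logarithm taken, and a univariate logistic regression of the
#' binary outcome \eqn{G_i} on that log probability fitted to the training
#' sample; the fitted score is applied to both samples and AUROC computed
#' for each.  (AUROC is invariant to monotone transforms, so the logistic
#' refit cannot change the training AUROC; it is the transported score for
#' the test sample.)
#'
#' @param coeffs An `nbdrink_coefs` object (or the `$coefficients` of a
#'   fit).
#' @param train,test Cohort data.frames with `last_occasion_drinks`.
#' @param cutoffs Integer cutoffs (default 2..12).
#' @return A data.frame with columns `cutoff`, `auroc_train`,
#'   `auroc_test`.
#' @export
auroc_pipeline <- function(coeffs, train, test, cutoffs = 2:12) {
  check_count(cutoffs, lower = 2, name = "cutoffs")
  train <- validate_records(train)
  test <- validate_records(test)
  rp_tr <- link_rp(train, coeffs)
  rp_te <- link_rp(test, coeffs)
  out <- data.frame(cutoff = cutoffs, auroc_train = NA_real_,
                    auroc_test = NA_real_)
  for (k in seq_along(cutoffs)) {
    i <- cutoffs[k]
    lp_tr <- exceedance_prob(i, rp_tr$r, rp_tr$p, log = TRUE)
    lp_te <- exceedance_prob(i, rp_te$r, rp_te$p, log = TRUE)
    g_tr <- binarize_outcome(train$last_occasion_drinks, i)
    g_te <- binarize_outcome(test$last_occasion_drinks, i)
    if (length(unique(g_tr)) < 2) next  # logistic fit undefined
    lr <- stats::glm(g_tr ~ lp_tr, family = stats::binomial())
    s_tr <- stats::predict(lr, type = "link")
    s_te <- drop(cbind(1, lp_te) %*% stats::coef(lr))
    out$auroc_train[k] <- suppressWarnings(auroc(s_tr, g_tr))
    out$auroc_test[k] <- suppressWarnings(auroc(s_te, g_te))
  }
  out
}

#' Slope-only calibration regression
#'
#' Regresses observed counts on predicted counts with no intercept:
#' slope \eqn{\hat\beta = \sum o_i p_i / \sum p_i^2} with classical 95%
#' CI, and the uncentered \eqn{R^2 = 1 - \sum(o - \hat\beta p)^2 /
#' \sum o^2} (the no-intercept convention, under which \eqn{R^2 \in
#' [0, 1]}).  A slope near 1 with high \eqn{R^2} indicates the predictions
#' track the observations on the original scale.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2);
#'   `predicted` must not be identically zero.
#' @return A list with `slope`, `ci_low`, `ci_high`, `r_squared`, `n`.
#' @examples
#' slope_only_calibration(c(3, 1, 0, 5), c(2.5, 1.2, 0.4, 4.8))
#' @export
slope_only_calibration <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("'observed' and 'predicted' must have equal length >= 2",
         call. = FALSE)
  if (all(predicted == 0))
    stop("'predicted' is identically zero: slope undefined", call. = FALSE)
  fit <- stats::lm(observed ~ 0 + predicted)
  ci <- stats::confint(fit, level = 0.95)
  list(slope = unname(stats::coef(fit)[1]),
       ci_low = ci[1, 1], ci_high = ci[1, 2],
       r_squared = summary(fit)$r.squared,
       n = length(observed))
}

#' Full validation report for a coefficient set
#'
#' Runs both validation procedures against held-out data: cutoff-wise
#' AUROC for the binary exceedance outcomes ([auroc_pipeline()]), and
#' slope-only calibration of the predicted numbers of days with 5+ drinks
#' (all respondents) and 4+ drinks (females, where observed) against the
#' recorded day counts ([slope_only_calibration()]), assessed on the test
#' sample.
#'
#' @param object A fitted `nbdrink` model or an `nbdrink_coefs` set.
#' @param train,test Cohort data.frames; `test` drives the calibration
#'   results, both samples are scored for AUROC.
#' @param cutoffs Integer AUROC cutoffs (default 2..12).
#' @return An object of class `nbdrink_validation`: list with `auroc`
#'   (data.frame), `calibration` (data.frame with one row per outcome),
#'   `n_train`, `n_test`.
#' @export
validate_model <- function(object, train, test, cutoffs = 2:12) {
  coeffs <- if (inherits(object, "nbdrink")) object$coefficients
            else object
  stopifnot(inherits(coeffs, "nbdrink_coefs"))
  train <- validate_records(train)
  test <- validate_records(test)
  auc <- auroc_pipeline(coeffs, train, test, cutoffs)
  rp <- link_rp(test, coeffs)
  calib <- list()
  if (!is.null(test$days_5plus)) {
    ok <- !is.na(test$days_5plus)
    pred <- exceedance_prob(5, rp$r[ok], rp$p[ok]) * test$drinking_days[ok]
    calib$days_5plus <- slope_only_calibration(test$days_5plus[ok], pred)
  }
  if (!is.null(test$days_4plus)) {
    ok <- !is.na(test$days_4plus) & test$gender == "female"
    if (any(ok)) {
      pred <- exceedance_prob(4, rp$r[ok], rp$p[ok]) * test$drinking_days[ok]
      calib$days_4plus <- slope_only_calibration(test$days_4plus[ok], pred)
    }
  }
  calib_df <- if (length(calib) > 0)
    data.frame(outcome = names(calib),
               slope = vapply(calib, `[[`, numeric(1), "slope"),
               ci_low = vapply(calib, `[[`, numeric(1), "ci_low"),
               ci_high = vapply(calib, `[[`, numeric(1), "ci_high"),
               r_squared = vapply(calib, `[[`, numeric(1), "r_squared"),
               n = vapply(calib, `[[`, numeric(1), "n"),
               row.names = NULL)
  structure(list(auroc = auc, calibration = calib_df,
                 n_train = nrow(train), n_test = nrow(test)),
            class = "nbdrink_validation")
}

#' @export
print.nbdrink_validation <- function(x, digits = 3, ...) {
  cat(sprintf("Occasion-model validation (n_train = %d, n_test = %d)\n\n",
              x$n_train, x$n_test))
  cat("AUROC by drink cutoff:\n")
  print(transform(x$auroc, auroc_train = round(auroc_train, digits),
                  auroc_test = round(auroc_test, digits)),
        row.names = FALSE)
  if (!is.null(x$calibration)) {
    cat("\nSlope-only calibration (test sample):\n")
    tab <- x$calibration
    tab[-1] <- lapply(tab[-1], round, digits)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
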