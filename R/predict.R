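#' Per-occasion risk predictions for respondent profiles
#'
#' Translates covariates into the model's headline outputs.  For each
#' respondent, the linked parameters \eqn{(r, p)} give the per-occasion
#' exceedance probabilities \eqn{P(Y \ge t \mid Y \ge 1)} for each drink
#' threshold \eqn{t}; multiplying by the respondent's number of drinking
#' days M gives the expected number of days per 30-day period on which
#' consumption reaches the threshold (the days count is binomial with M
#' trials under the model, so the product is its mean).
#'
#' A drinking "occasion" and a drinking day are treated as synonymous
#' throughout: the model is built from one occasion per drinking day (the
#' last one), and day counts scale its per-occasion probabilities.
#'
#' @param data A data.frame of respondent covariates (see
#'   [build_design()]).
#' @param coeffs An `nbdrink_coefs` object, e.g.
#'   [reference_coefficients()] or the `$coefficients` of a fitted model.
#' @param thresholds Integer drink thresholds, each in 1..20 (default
#'   2-12, the cutoffs used for discrimination checks, plus 4 and 5, the
#'   conventional risky-day levels).
#' @return A data.frame with one row per respondent: the covariates, `r`,
#'   `p`, one `exceed_<t>` column per threshold, and one `days_<t>` column
#'   per threshold (expected days out of `drinking_days`).
#' @examples
#' predict_risk(data.frame(age_band = "35-49", gender = "female",
#'                         usual_drinks = 3, drinking_days = 20),
#'              reference_coefficients(), thresholds = c(2, 5))
#' @export
predict_risk <- function(data, coeffs, thresholds = sort(unique(c(2:12, 4, 5)))) {
  check_count(thresholds, lower = 1, name = "thresholds")
  if (any(thresholds > 20))
    stop("'thresholds' must lie in 1..20", call. = FALSE)
  data <- validate_profiles(data)
  rp <- link_rp(data, coeffs)
  out <- cbind(data[c("age_band", "gender", "usual_drinks", "drinking_days")],
               rp)
  for (t in thresholds) {
    ex <- exceedance_prob(t, rp$r, rp$p)
    out[[paste0("exceed_", t)]] <- ex
    out[[paste0("days_", t)]] <- ex * data$drinking_days
  }
  out
}

#' Predict method for fitted occasion models
#'
#' @param object A fitted `nbdrink` model.
#' @param newdata Respondent covariates; for `type = "days"` a
#'   `drinking_days` column supplies the binomial trial count.
#' @param type `"parameters"` returns the linked \eqn{(r, p)};
#'   `"exceedance"` the per-occasion exceedance probabilities; `"days"`
#'   the expected days per period at each threshold.
#' @param thresholds Integer drink thresholds (see [predict_risk()]).
#' @param ... Unused.
#' @return A data.frame (see [predict_risk()]).
#' @export
predict.nbdrink <- function(object, newdata,
                            type = c("exceedance", "days", "parameters"),
                            thresholds = sort(unique(c(2:12, 4, 5))), ...) {
  type <- match.arg(type)
  if (type == "parameters") return(link_rp(newdata, object$coefficients))
  out <- predict_risk(newdata, object$coefficients, thresholds)
  keep <- if (type == "exceedance") paste0("exceed_", thresholds)
          else paste0("days_", thresholds)
  out[c("r", "p", keep)]
}

#' Conversion table of predicted drinking risk over a covariate grid
#'
#' Expands a grid of usual-drinks (K) and drinking-days (M) values for
#' given age band(s) and gender(s), and evaluates [predict_risk()] on
#' every combination — the "look-up table" form in which the model is most
#' easily consumed by practitioners.
#'
#' @param coeffs An `nbdrink_coefs` object.
#' @param K_range,M_range Integer vectors within 1..24 and 1..30.
#' @param age_band,gender Band label(s) and gender(s) to tabulate.
#' @param thresholds Integer drink thresholds.
#' @return A data.frame, one row per (age_band, gender, K, M) combination,
#'   with the same prediction columns as [predict_risk()].
#' @examples
#' head(conversion_table(reference_coefficients(), K_range = 1:4,
#'                       M_range = c(4, 10), thresholds = 5))
#' @export
conversion_table <- function(coeffs, K_range = 1:24, M_range = 1:30,
                             age_band = "20-25", gender = "male",
                             thresholds = sort(unique(c(2:12, 4, 5)))) {
  if (length(K_range) == 0 || length(M_range) == 0)
    stop("'K_range' and 'M_range' must be non-empty", call. = FALSE)
  grid <- expand.grid(age_band = age_band, gender = gender,
                      usual_drinks = K_range, drinking_days = M_range,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  predict_risk(grid, coeffs, thresholds)
}
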