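#' Coefficient sets linking covariates to (r, p)
#'
#' A coefficient set holds, for each of the two linear predictors, the
#' named regression coefficients of the active terms (and optionally their
#' 95% confidence limits).  The r predictor drives the number of mini
#' episodes through \eqn{r = 1 + \exp(a_r + x' b_r)} (so \eqn{r > 1}
#' always); the p predictor drives the stopping probability through the
#' logistic \eqn{p = \mathrm{plogis}(a_p + x' b_p)}.  Terms absent from a
#' predictor are inactive and contribute exactly zero.
#'
#' @param r,p Named numeric vectors of coefficients.  Valid names are
#'   `const`, `age12-14`, `age15-17`, `age18-19`, `age26-29`, `age30-34`,
#'   `age35-49`, `age50-64`, `age65+`, `female`, `log_inv_K`,
#'   `log_inv_K_sq`, `log_M`, `log_M_sq`; `const` is required in both.
#' @param r_ci,p_ci Optional two-column matrices (lower, upper) with rows
#'   matching `r` and `p`.
#' @return An object of class `nbdrink_coefs`.
#' @seealso [reference_coefficients()], [compute_r()], [read_coefficients()]
#' @export
nbdrink_coefs <- function(r, p, r_ci = NULL, p_ci = NULL) {
  chk <- function(b, ci, which) {
    if (!is.numeric(b) || is.null(names(b)) || anyNA(b))
      stop("'", which, "' must be a complete named numeric vector",
           call. = FALSE)
    bad <- setdiff(names(b), model_terms())
    if (length(bad) > 0)
      stop("unknown term(s) in '", which, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (!"const" %in% names(b))
      stop("'", which, "' must include a 'const' term", call. = FALSE)
    if (anyDuplicated(names(b)))
      stop("duplicated term names in '", which, "'", call. = FALSE)
    if (!is.null(ci)) {
      ci <- as.matrix(ci)
      if (nrow(ci) != length(b) || ncol(ci) != 2)
        stop("'", which, "_ci' must be a length(", which, ") x 2 matrix",
             call. = FALSE)
      rownames(ci) <- names(b)
      colnames(ci) <- c("ci_low", "ci_high")
    }
    ci
  }
  r_ci <- chk(r, r_ci, "r")
  p_ci <- chk(p, p_ci, "p")
  structure(list(r = r, p = p, r_ci = r_ci, p_ci = p_ci),
            class = "nbdrink_coefs")
}

#' @export
print.nbdrink_coefs <- function(x, digits = 3, ...) {
  cat("Occasion-model coefficient set\n")
  for (blk in c("r", "p")) {
    lab <- if (blk == "r") "number of mini episodes (r)"
           else "probability of stopping (p)"
    cat("\nPredictor for ", lab, ":\n", sep = "")
    tab <- data.frame(estimate = round(x[[blk]], digits))
    ci <- x[[paste0(blk, "_ci")]]
    if (!is.null(ci)) {
      tab$ci_low <- round(ci[, 1], digits)
      tab$ci_high <- round(ci[, 2], digits)
    }
    print(tab)
  }
  invisible(x)
}

active_terms <- function(coeffs) {
  list(r = names(coeffs$r), p = names(coeffs$p))
}

#' Reference coefficient set
#'
#' Loads the coefficient set shipped with the package: maximum-likelihood
#' estimates from pooled 2010-2011 US National Survey on Drug Use and
#' Health (NSDUH) past-30-day drinkers, after elimination of
#' non-significant terms.  In this set the age-band block and the female
#' indicator are active only in the r predictor; both predictors retain
#' the four drinking-norm transforms.  Coefficients for other populations
#' should be re-estimated with [nbdrink()] rather than transported.
#'
#' @return An `nbdrink_coefs` object.
#' @examples
#' compute_r(data.frame(age_band = "35-49", gender = "female",
#'                      usual_drinks = 3, drinking_days = 20),
#'           reference_coefficients())
#' @export
reference_coefficients <- function() {
  path <- system.file("extdata", "reference_coefficients.json",
                      package = "nbdrink", mustWork = TRUE)
  read_coefficients(path)
}

#' Read or write a coefficient set as JSON
#'
#' Coefficient files store one object per predictor (`r`, `p`) mapping
#' term names to `estimate` / `ci_low` / `ci_high`, so that changes in the
#' active-term set cannot silently misalign positional coefficients.
#'
#' @param path File path.
#' @param coeffs An `nbdrink_coefs` object.
#' @return `read_coefficients()` returns an `nbdrink_coefs` object;
#'   `write_coefficients()` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!all(c("r", "p") %in% names(doc)))
    stop("coefficient file must contain 'r' and 'p' blocks", call. = FALSE)
  parse_block <- function(blk) {
    est <- vapply(blk, function(t) as.numeric(t$estimate), numeric(1))
    has_ci <- all(vapply(blk, function(t)
      !is.null(t$ci_low) && !is.null(t$ci_high), logical(1)))
    ci <- if (has_ci)
      cbind(vapply(blk, function(t) as.numeric(t$ci_low), numeric(1)),
            vapply(blk, function(t) as.numeric(t$ci_high), numeric(1)))
    list(est = est, ci = ci)
  }
  r <- parse_block(doc$r)
  p <- parse_block(doc$p)
  nbdrink_coefs(r$est, p$est, r_ci = r$ci, p_ci = p$ci)
}

#' @rdname read_coefficients
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "nbdrink_coefs"))
  as_block <- function(b, ci) {
    out <- lapply(seq_along(b), function(i) {
      t <- list(estimate = unname(b[i]))
      if (!is.null(ci)) {
        t$ci_low <- unname(ci[i, 1])
        t$ci_high <- unname(ci[i, 2])
      }
      t
    })
    names(out) <- names(b)
    out
  }
  doc <- list(r = as_block(coeffs$r, coeffs$r_ci),
              p = as_block(coeffs$p, coeffs$p_ci))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

linear_predictor <- function(X, beta) {
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' Individual model parameters from covariates
#'
#' Evaluates the covariate links for one or more respondents:
#' `compute_r()` returns the number of mini episodes
#' \eqn{r = 1 + \exp(\eta_r)} and `compute_p()` the stopping probability
#' \eqn{p = \mathrm{plogis}(\eta_p)}, where each \eqn{\eta} is the linear
#' predictor of the active terms in `coeffs`.  `link_rp()` returns both as
#' a data.frame.
#'
#' @param data A data.frame of respondent covariates (see
#'   [build_design()]).
#' @param coeffs An `nbdrink_coefs` object.
#' @return `compute_r()` and `compute_p()` return numeric vectors;
#'   `link_rp()` a data.frame with columns `r` and `p`.
#' @examples
#' prof <- data.frame(age_band = "35-49", gender = "female",
#'                    usual_drinks = 3, drinking_days = 20)
#' link_rp(prof, reference_coefficients())
#' @export
link_rp <- function(data, coeffs) {
  stopifnot(inherits(coeffs, "nbdrink_coefs"))
  X <- build_design(data)
  data.frame(r = 1 + exp(linear_predictor(X, coeffs$r)),
             p = stats::plogis(linear_predictor(X, coeffs$p)))
}

#' @rdname link_rp
#' @export
compute_r <- function(data, coeffs) link_rp(data, coeffs)$r

#' @rdname link_rp
#' @export
compute_p <- function(data, coeffs) link_rp(data, coeffs)$p
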