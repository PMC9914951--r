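#' Age bands used by the model
#'
#' The nine ordered age categories the covariate link is defined over.
#' Band `20-25` is the dummy-coding reference.
#'
#' @return Character vector of the nine band labels, youngest first.
#' @export
age_bands <- function() {
  c("12-14", "15-17", "18-19", "20-25", "26-29",
    "30-34", "35-49", "50-64", "65+")
}

AGE_REF <- "20-25"

# canonical term names for each linear predictor
model_terms <- function() {
  c("const",
    paste0("age", setdiff(age_bands(), AGE_REF)),
    "female", "log_inv_K", "log_inv_K_sq", "log_M", "log_M_sq")
}

age_term_names <- function() paste0("age", setdiff(age_bands(), AGE_REF))

#' Map age in years to the model's age band
#'
#' @param years Integer vector of ages, 12 or older.
#' @return Factor of band labels with levels `age_bands()`.
#' @examples
#' age_to_band(c(12, 19, 25, 40, 70))
#' @export
age_to_band <- function(years) {
  check_count(years, lower = 12, name = "age_years")
  cuts <- c(12, 15, 18, 20, 26, 30, 35, 50, 65, Inf)
  cut(years, breaks = cuts, right = FALSE, labels = age_bands())
}

# normalise en-dashes and whitespace in band labels; error on unknown levels
canon_age_band <- function(x) {
  x <- gsub("–", "-", trimws(as.character(x)))
  bad <- setdiff(unique(x), age_bands())
  if (length(bad) > 0)
    stop("unknown age_band value(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(age_bands(), collapse = ", "),
         call. = FALSE)
  factor(x, levels = age_bands())
}

canon_gender <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("m", "male")] <- "male"
  x[x %in% c("f", "female")] <- "female"
  bad <- setdiff(unique(x), c("male", "female"))
  if (length(bad) > 0)
    stop("gender must be coded male/female; offending value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  factor(x, levels = c("male", "female"))
}

# Validate and canonicalise profile columns in place.  `data` needs either
# age_band or age_years, plus gender, usual_drinks (K) and drinking_days (M).
validate_profiles <- function(data) {
  if (!is.data.frame(data)) stop("'data' must be a data.frame", call. = FALSE)
  if (is.null(data$age_band)) {
    if (is.null(data$age_years))
      stop("need an 'age_band' or 'age_years' column", call. = FALSE)
    data$age_band <- age_to_band(data$age_years)
  } else {
    data$age_band <- canon_age_band(data$age_band)
  }
  for (col in c("gender", "usual_drinks", "drinking_days"))
    if (is.null(data[[col]]))
      stop("missing required column '", col, "'", call. = FALSE)
  data$gender <- canon_gender(data$gender)
  K <- data$usual_drinks
  M <- data$drinking_days
  if (anyNA(K) || any(K < 1) || any(K > 24) || any(K != floor(K)))
    stop("'usual_drinks' (K) must be an integer in 1..24; recode values ",
         "above 24 down before modelling (see read_cohort)", call. = FALSE)
  if (anyNA(M) || any(M < 1) || any(M > 30) || any(M != floor(M)))
    stop("'drinking_days' (M) must be an integer in 1..30 ",
         "(past-30-day drinkers only)", call. = FALSE)
  data
}

#' Build the model design matrix from respondent covariates
#'
#' Expands each respondent's covariates into the term basis shared by the
#' two linear predictors: an intercept, eight age-band dummies (reference
#' `20-25`), a female indicator, and the drinking-norm transforms
#' \eqn{u_1 = \ln(1/K)}, \eqn{u_2 = u_1^2}, \eqn{v_1 = \ln(M)},
#' \eqn{v_2 = v_1^2}, where K is the usual number of drinks per drinking
#' day (1-24) and M the number of drinking days in the past 30 days (1-30).
#'
#' @param data A data.frame with columns `age_band` (or `age_years`),
#'   `gender`, `usual_drinks`, `drinking_days`.
#' @return Numeric matrix, one row per respondent, with column names
#'   `const`, `age12-14` ... `age65+`, `female`, `log_inv_K`,
#'   `log_inv_K_sq`, `log_M`, `log_M_sq`.
#' @examples
#' build_design(data.frame(age_band = "35-49", gender = "female",
#'                         usual_drinks = 3, drinking_days = 20))
#' @export
build_design <- function(data) {
  data <- validate_profiles(data)
  n <- nrow(data)
  X <- matrix(0, nrow = n, ncol = length(model_terms()),
              dimnames = list(NULL, model_terms()))
  X[, "const"] <- 1
  for (band in setdiff(age_bands(), AGE_REF))
    X[, paste0("age", band)] <- as.numeric(data$age_band == band)
  X[, "female"] <- as.numeric(data$gender == "female")
  u1 <- log(1 / data$usual_drinks)
  v1 <- log(data$drinking_days)
  X[, "log_inv_K"] <- u1
  X[, "log_inv_K_sq"] <- u1^2
  X[, "log_M"] <- v1
  X[, "log_M_sq"] <- v1^2
  X
}
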