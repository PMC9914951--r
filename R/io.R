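#' Read a drinker cohort from CSV
#'
#' Reads survey-style microdata with one row per past-30-day drinker and
#' applies the model's recoding rules before validation:
#' `usual_drinks` above 24 and `last_occasion_drinks` above 20 (the
#' reporting bounds) are recoded down to the bound, and rows describing
#' non-drinkers (`drinking_days` = 0 or `last_occasion_drinks` = 0) are
#' excluded.  Recode and exclusion counts are reported via `message()` and
#' attached as the `"recodes"` attribute so a run can be audited.
#'
#' Required columns: `age_band` (or `age_years`), `gender`,
#' `usual_drinks`, `drinking_days`, `last_occasion_drinks`; optional:
#' `days_5plus`, `days_4plus`.
#'
#' @param path CSV file path.
#' @param bound Censoring bound for `last_occasion_drinks` (default 20).
#' @param K_bound Upper bound for `usual_drinks` (default 24).
#' @return Validated cohort data.frame with a `"recodes"` attribute
#'   (named counts: `K_recoded`, `y_recoded`, `nondrinkers_dropped`).
#' @seealso [write_cohort()], [simulate_cohort()]
#' @export
read_cohort <- function(path, bound = 20, K_bound = 24) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gender", "usual_drinks", "drinking_days",
            "last_occasion_drinks")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("cohort file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"age_band" %in% names(data) && !"age_years" %in% names(data))
    stop("cohort file needs an 'age_band' or 'age_years' column",
         call. = FALSE)
  drop <- !is.na(data$drinking_days) & !is.na(data$last_occasion_drinks) &
    (data$drinking_days == 0 | data$last_occasion_drinks == 0)
  n_drop <- sum(drop)
  data <- data[!drop, , drop = FALSE]
  n_K <- sum(data$usual_drinks > K_bound, na.rm = TRUE)
  data$usual_drinks <- pmin(data$usual_drinks, K_bound)
  n_y <- sum(data$last_occasion_drinks > bound, na.rm = TRUE)
  data$last_occasion_drinks <- pmin(data$last_occasion_drinks, bound)
  data <- validate_records(data, bound = bound)
  recodes <- c(K_recoded = n_K, y_recoded = n_y,
               nondrinkers_dropped = n_drop)
  if (sum(recodes) > 0)
    message(sprintf(paste0("read_cohort: recoded %d usual_drinks to %d, ",
                           "%d last_occasion_drinks to %d; ",
                           "dropped %d non-drinker row(s)"),
                    n_K, K_bound, n_y, bound, n_drop))
  attr(data, "recodes") <- recodes
  data
}

#' Write a drinker cohort to CSV
#'
#' @param data Cohort data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Random train/test partition of a cohort
#'
#' Randomly assigns `floor(n * fraction)` rows to the training sample and
#' the remainder to the test sample; deterministic given `seed`.
#'
#' @param data Cohort data.frame with at least 2 rows.
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Optional integer seed.
#' @return A list with data.frames `train` and `test`.
#' @export
split_train_test <- function(data, fraction = 0.75, seed = NULL) {
  if (!is.data.frame(data) || nrow(data) < 2)
    stop("'data' must be a data.frame with at least 2 rows", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  idx <- sample.int(n, floor(n * fraction))
  list(train = data[idx, , drop = FALSE],
       test = data[-idx, , drop = FALSE])
}
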