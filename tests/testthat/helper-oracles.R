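# Independent oracles used across the suite.  These deliberately avoid the
# package's own probability code paths.

# NB pmf for integer r by exhaustive convolution of r geometric
# (failures-before-first-success) pmfs, up to ymax.
conv_nb_pmf <- function(r, p, ymax = 50) {
  geo <- p * (1 - p)^(0:ymax)
  out <- geo
  if (r > 1) for (i in 2:r) {
    nxt <- numeric(ymax + 1)
    for (y in 0:ymax)
      nxt[y + 1] <- sum(out[1:(y + 1)] * geo[(y + 1):1])
    out <- nxt
  }
  out  # out[y + 1] = P(Y = y)
}

# AUROC by brute force over all positive-negative pairs, ties as 1/2.
brute_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# Coefficient set that pins every respondent at the same (r, p):
# r = 1 + exp(const), p = plogis(const).
const_coefs <- function(r, p) {
  nbdrink_coefs(r = c(const = log(r - 1)), p = c(const = stats::qlogis(p)))
}

age_dummy_names <- function() paste0("age", setdiff(age_bands(), "20-25"))

# Small covariate table covering both genders and several bands.
demo_profiles <- function() {
  data.frame(
    age_band = c("35-49", "20-25", "65+", "18-19"),
    gender = c("female", "male", "female", "male"),
    usual_drinks = c(3L, 1L, 24L, 5L),
    drinking_days = c(20L, 1L, 30L, 8L))
}
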