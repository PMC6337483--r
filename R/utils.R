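# Internal helpers shared across modules.

# Stable string hash (polynomial, mod 2^31 - 1). Used to derive independent
# RNG streams per study / per stage from one master seed, so adding a study or
# a stage never perturbs the draws of the others. All intermediates stay below
# 2^53, so the arithmetic is exact in doubles.
hash_label <- function(label) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  h
}

# Derive a child seed (< 2^31) from a master seed and a label.
seed_for <- function(seed, label) {
  m <- 2147483647
  as.integer(((as.double(seed) %% m) * 69069 + hash_label(label)) %% m)
}

# Row variances with the n-1 denominator (no matrixStats dependency).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
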