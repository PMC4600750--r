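# internal numerics shared across modules

# log(sum(exp(x))) guarded against -Inf-only input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# pairwise log-sum-exp of two equally shaped arrays, kept vectorised because
# the E-step calls it on M x N matrices
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(pmin(a, b) - m))
  r[is.infinite(m)] <- m[is.infinite(m)]
  r
}

# deterministic per-stage seed fan-out; keeps derived seeds inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629L)
}

stop_xshadow <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "xshadow_error")))
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

# linear-interpolation (type 7) quartiles used by every boxplot-style fence
tukey_fence <- function(x, multiplier = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7, na.rm = TRUE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - multiplier * iqr, upper = q[2] + multiplier * iqr)
}
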