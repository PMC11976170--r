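# Internal helpers: error classes, seeded evaluation, small numeric utilities.

abort_param <- function(msg) {
  stop(errorCondition(msg, class = c("mepmuscle_param_error", "error", "condition")))
}

abort_format <- function(msg) {
  stop(errorCondition(msg, class = c("mepmuscle_format_error", "error", "condition")))
}

abort_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("mepmuscle_degenerate_error", "error", "condition")))
}

abort_feature <- function(msg) {
  stop(errorCondition(msg, class = c("mepmuscle_feature_error", "error", "condition")))
}

# Evaluate code with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Population standard deviation (divisor n), the convention used for the
# detection threshold and the 2 x SD peak-prominence rule.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Truncated normal draws by rejection; bounds may be +-Inf.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(lower >= upper)) abort_param("empty truncation interval")
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                      if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[out[bad] < (if (length(lower) > 1) lower[bad] else lower) |
               out[bad] > (if (length(upper) > 1) upper[bad] else upper)]
    guard <- guard + 1L
    if (guard > 10000L) abort_param("truncated-normal rejection did not converge")
  }
  out
}

# Largest-remainder apportionment of n items over proportions p (sums to 1).
# Ties broken by vector order, so the result is deterministic.
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
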