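# Independent brute-force oracles, coded separately from the package
# implementations they check.

# Population SD (divisor n), reimplemented here.
oracle_pop_sd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))

# Naive local-maximum + prominence peak finder (O(n^2) scans).
oracle_find_peaks <- function(x, prominence) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i - 1L] < x[i]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)
        i <- j + 1L
        next
      }
      i <- j + 1L
      next
    }
    i <- i + 1L
  }
  keep <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    lmin <- x[p]
    for (j in seq(p - 1L, 1L)) {
      if (x[j] > x[p]) break
      lmin <- min(lmin, x[j])
    }
    rmin <- x[p]
    for (j in seq(p + 1L, n)) {
      if (x[j] > x[p]) break
      rmin <- min(rmin, x[j])
    }
    keep[k] <- (x[p] - max(lmin, rmin)) >= prominence
  }
  peaks[keep]
}

# Brute-force re-implementation of the preselection rule on one raw
# 2000-sample recording; returns the is_mep verdict.
oracle_preselect <- function(samples) {
  x <- samples[401:2000]
  m <- sum(x[1501:1600]) / 100
  s <- oracle_pop_sd(x)
  out <- which(x < m - s | x > m + s)
  peaks <- oracle_find_peaks(x, 2 * s)
  if (length(peaks) < 1) return(FALSE)
  if (length(out) == 0) return(FALSE)
  onset <- (399 + out[1]) / 20 - 1
  endl <- (399 + out[length(out)]) / 20 + 1
  dur <- endl - onset
  span <- (max(peaks) - min(peaks)) / 20
  dur < 40 && span < 35
}

# Brute-force DFT magnitude argmax over positive frequencies (explicit sums).
oracle_dft_argmax <- function(x, fs = 20000) {
  n <- length(x)
  t <- seq_len(n) - 1
  best_k <- 1L
  best <- -Inf
  for (k in seq_len(n %/% 2)) {
    mag <- sqrt(sum(x * cos(2 * pi * k * t / n))^2 +
                sum(x * sin(2 * pi * k * t / n))^2)
    if (mag > best) { best <- mag; best_k <- k }
  }
  best_k * fs / n
}

# Direct-convolution Mexican-hat CWT magnitude at one (scale, sample) point.
oracle_cwt_point <- function(x, scale, center0) {
  h <- ceiling(5 * scale)
  k <- -h:h
  t <- k / scale
  psi <- 2 / (sqrt(3) * pi^0.25) * (1 - t^2) * exp(-t^2 / 2) / sqrt(scale)
  acc <- 0
  for (i in seq_along(k)) {
    s <- center0 + k[i]
    if (s >= 0 && s < length(x)) acc <- acc + x[s + 1] * psi[i]
  }
  abs(acc)
}

# Path-dependent conditional expectation of one flat tree (lists as stored by
# the package's forest extraction), for brute-force Shapley enumeration.
oracle_tree_expectation <- function(tree, S, x, k, node = 1L) {
  if (tree$childL[node] < 0) return(tree$leafval[node, k])
  f <- tree$splitvar[node] + 1L
  L <- tree$childL[node] + 1L
  R <- tree$childR[node] + 1L
  if (f %in% S) {
    if (x[f] <= tree$splitval[node]) {
      oracle_tree_expectation(tree, S, x, k, L)
    } else {
      oracle_tree_expectation(tree, S, x, k, R)
    }
  } else {
    (tree$cover[L] * oracle_tree_expectation(tree, S, x, k, L) +
     tree$cover[R] * oracle_tree_expectation(tree, S, x, k, R)) /
      tree$cover[node]
  }
}

oracle_shapley <- function(tree, x, k) {
  p <- length(x)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (sz in 0:(p - 1)) {
      combs <- if (sz == 0) list(integer(0)) else
        utils::combn(others, sz, simplify = FALSE)
      wgt <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      for (S in combs) {
        phi[i] <- phi[i] + wgt *
          (oracle_tree_expectation(tree, c(S, i), x, k) -
           oracle_tree_expectation(tree, S, x, k))
      }
    }
  }
  phi
}

# Shared small helpers for building fixtures ---------------------------------

# A noiseless burst recording with the given parameters.
make_clean_mep <- function(onset = 30, freq = 300, n_phases = 3, amplitude = 1,
                           muscle = "EXT") {
  generate_mep(waveform_params(onset, freq, amplitude = amplitude,
                               n_phases = n_phases),
               muscle = muscle)
}

# Mixed draws of ground-truth parameters across muscles for a config.
draw_mixed_params <- function(config, n) {
  per <- ceiling(n / 4)
  out <- do.call(rbind, lapply(MUSCLES <- c("EXT", "APB", "TA", "AH"),
                               function(m) {
    cbind(sample_waveform_params(config, m, per), muscle = m)
  }))
  out[seq_len(n), ]
}
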