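# Time-frequency representation: Mexican-hat continuous wavelet transform.

#' @rdname cwt_scalogram
#' @export
cwt_scales <- function(n = 224L) {
  s <- exp(seq(log(2), log(30), length.out = n))
  s[1] <- 2; s[n] <- 30
  s
}

# 0-based sample indices of the 224 retained time columns.
cwt_time_index <- function(n = 224L, len = 1600L) {
  round(seq(1, len, length.out = n)) - 1L
}

#' Mexican-hat wavelet scalogram of one trace
#'
#' Magnitude of the continuous wavelet transform with a Mexican-hat (Ricker)
#' mother wavelet at 224 logarithmically spaced scales from 2 to 30, with the
#' time axis undersampled from 1600 samples to 224 columns by nearest-index
#' decimation: a 224 x 224 array, rows ordered by increasing scale
#' (decreasing frequency).
#'
#' @param filtered Numeric vector of length 1600 (filtered trace).
#' @return A list of class `mep_scalogram` with `magnitude` (224 x 224
#'   matrix), `scale_axis` (length 224, strictly increasing, endpoints 2 and
#'   30) and `time_axis` (ms).
#' @export
cwt_scalogram <- function(filtered) {
  if (is.matrix(filtered)) filtered <- drop(filtered)
  if (length(filtered) != 1600L) abort_format("trace must have 1600 samples")
  scales <- cwt_scales()
  tidx <- cwt_time_index()
  stack <- cpp_cwt_stack(matrix(filtered, nrow = 1), scales, tidx, 1L)
  mag <- matrix(stack, 224L, 224L)  # drop the unit first dimension
  structure(list(magnitude = mag, scale_axis = scales,
                 time_axis = stripped_time_ms(tidx + 1L)),
            class = "mep_scalogram")
}

#' Scalogram stack for a set of traces
#'
#' Computes the wavelet scalogram of every row of `x`, optionally averaging
#' `pool x pool` blocks (the 2D network trains on 8x8-pooled 28 x 28 inputs;
#' `pool = 1` keeps the full 224 x 224 resolution).
#'
#' @param x Numeric matrix of filtered traces (1600 columns).
#' @param pool Block-averaging factor; must divide 224.
#' @return A numeric array `(nrow(x), 224/pool, 224/pool)` with attributes
#'   `scale_axis` and `time_axis` (block centres when pooled).
#' @export
scalogram_stack <- function(x, pool = 8L) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != 1600L) abort_format("traces must have 1600 samples")
  if (224L %% pool != 0L) abort_param("pool must divide 224")
  scales <- cwt_scales()
  tidx <- cwt_time_index()
  out <- cpp_cwt_stack(x, scales, tidx, as.integer(pool))
  if (pool > 1L) {
    grp <- rep(seq_len(224L %/% pool), each = pool)
    attr(out, "scale_axis") <- as.vector(tapply(scales, grp, mean))
    attr(out, "time_axis") <- as.vector(tapply(stripped_time_ms(tidx + 1L), grp, mean))
  } else {
    attr(out, "scale_axis") <- scales
    attr(out, "time_axis") <- stripped_time_ms(tidx + 1L)
  }
  out
}
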