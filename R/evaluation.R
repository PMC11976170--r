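# Evaluation surfaces: accuracy, confusion matrices, confidence-retention
# curves, per-muscle dispersion, and bicentric feature comparisons.

#' Classification accuracy
#'
#' @param predictions,truths Equal-length label vectors.
#' @return Proportion of correct predictions.
#' @export
accuracy <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) == 0) {
    abort_param("predictions and truths must be non-empty and equal length")
  }
  mean(as.character(predictions) == as.character(truths))
}

#' Four-class confusion matrix
#'
#' Counts with rows = true muscle and columns = predicted muscle, plus the
#' row-normalised proportions.
#'
#' @param predictions,truths Label vectors over EXT/APB/TA/AH.
#' @return List of class `mep_confusion` with `counts` and `proportions`.
#' @export
confusion_matrix <- function(predictions, truths) {
  p <- as.character(predictions)
  t <- as.character(truths)
  if (!all(p %in% MUSCLES) || !all(t %in% MUSCLES)) {
    abort_param("labels outside EXT/APB/TA/AH")
  }
  counts <- table(factor(t, MUSCLES), factor(p, MUSCLES))
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(MUSCLES, MUSCLES))
  rs <- rowSums(counts)
  prop <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, proportions = prop), class = "mep_confusion")
}

#' @export
print.mep_confusion <- function(x, ...) {
  cat("<mep_confusion> rows = truth, columns = prediction\n")
  print(x$counts)
  invisible(x)
}

#' Confidence-retention curve
#'
#' For each decision threshold: the fraction of recordings whose maximum class
#' probability reaches the threshold (retained fraction) and the accuracy
#' among those retained. At the 0.25 chance level everything is retained and
#' the curve equals the plain accuracy.
#'
#' @param probabilities n x 4 probability matrix.
#' @param truths True labels.
#' @param thresholds Threshold grid (default 0.25 to 0.90 by 0.05).
#' @return Data.frame of class `confidence_curve` with columns `threshold`,
#'   `accuracy_on_retained` (`NA` when nothing is retained) and
#'   `retained_fraction`.
#' @export
confidence_curve <- function(probabilities, truths,
                             thresholds = seq(0.25, 0.9, by = 0.05)) {
  maxp <- apply(probabilities, 1, max)
  pred <- MUSCLES[max.col(probabilities, ties.method = "first")]
  t <- as.character(truths)
  out <- data.frame(threshold = thresholds,
                    accuracy_on_retained = NA_real_,
                    retained_fraction = NA_real_)
  for (i in seq_along(thresholds)) {
    keep <- maxp >= thresholds[i]
    out$retained_fraction[i] <- mean(keep)
    if (any(keep)) {
      out$accuracy_on_retained[i] <- mean(pred[keep] == t[keep])
    }
  }
  class(out) <- c("confidence_curve", "data.frame")
  out
}

#' Dispersion of per-muscle accuracies
#'
#' Standard deviation (percentage points) and coefficient of variation
#' (`100 * SD / mean`, both on the percent scale) of the four per-class
#' accuracies; used to compare performance consistency across muscles.
#'
#' @param per_class_accuracy Numeric vector of 4 per-muscle accuracies
#'   (fractions or percent).
#' @return Named vector `c(sd, cv)`.
#' @export
performance_dispersion <- function(per_class_accuracy) {
  if (length(per_class_accuracy) != 4) abort_param("need 4 per-class accuracies")
  a <- per_class_accuracy
  if (max(a) <= 1) a <- 100 * a
  s <- sd(a)
  c(sd = s, cv = 100 * s / mean(a))
}

#' Per-muscle comparison of a feature across centers
#'
#' Classic two-sample Student t test (pooled variance) of the feature mean
#' between centers T1 and T2, separately per muscle, at alpha = .05. No
#' multiple-testing correction is applied; the number of tests is reported so
#' readers can account for it.
#'
#' @param values Numeric feature values.
#' @param center Center label per value (`"T1"`/`"T2"`).
#' @param muscle Muscle label per value.
#' @param alpha Significance level.
#' @return Data.frame with one row per muscle: group means, `t`, `df`,
#'   `p_value`, `significant`; attribute `n_tests`.
#' @export
compare_feature_across_centers <- function(values, center, muscle,
                                           alpha = 0.05) {
  stopifnot(length(values) == length(center), length(values) == length(muscle))
  out <- lapply(MUSCLES, function(m) {
    sel <- muscle == m & !is.na(values)
    v1 <- values[sel & center == "T1"]
    v2 <- values[sel & center == "T2"]
    if (length(v1) < 2 || length(v2) < 2) {
      return(data.frame(muscle = m, mean_T1 = mean(v1), mean_T2 = mean(v2),
                        t = NA_real_, df = NA_real_, p_value = NA_real_,
                        significant = NA))
    }
    tt <- tryCatch(t.test(v1, v2, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(tt)) {  # degenerate: zero variance in both groups
      return(data.frame(muscle = m, mean_T1 = mean(v1), mean_T2 = mean(v2),
                        t = NA_real_, df = NA_real_, p_value = NA_real_,
                        significant = NA))
    }
    data.frame(muscle = m, mean_T1 = mean(v1), mean_T2 = mean(v2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, significant = tt$p.value < alpha)
  })
  out <- do.call(rbind, out)
  attr(out, "n_tests") <- sum(!is.na(out$p_value))
  out
}
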