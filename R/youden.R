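#' Youden-optimal probability cutoff
#'
#' Finds the cutoff maximizing Youden's J = sensitivity + specificity - 1
#' for the rule "predict class 1 when probability >= cutoff". Candidate
#' cutoffs are the midpoints between consecutive distinct sorted
#' probabilities, plus one candidate below the minimum and one above the
#' maximum, so every achievable (sensitivity, specificity) pair on the ROC
#' curve is attainable. Ties in J are broken toward the smallest cutoff;
#' the returned value is clamped to the open interval (0, 1).
#'
#' @param probabilities numeric vector of fitted probabilities.
#' @param labels 0/1 (or logical) class labels, both classes present.
#' @return a list with `cutoff`, the achieved `j`, and the `sensitivity`
#'   and `specificity` at the cutoff.
#' @export
compute_youden_cutoff <- function(probabilities, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(probabilities) == length(labels))
  if (length(unique(labels)) < 2) {
    stop_danhi("danhi_single_class", "labels must contain both classes")
  }
  u <- sort(unique(probabilities))
  candidates <- if (length(u) == 1) {
    c(u / 2, (u + 1) / 2)
  } else {
    c(u[1] - (u[2] - u[1]) / 2,
      (u[-length(u)] + u[-1]) / 2,
      u[length(u)] + (u[length(u)] - u[length(u) - 1]) / 2)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  # sensitivity(c) = P(prob >= c | y = 1); specificity(c) = P(prob < c | y = 0)
  j <- vapply(candidates, function(cc) {
    sum(probabilities >= cc & labels == 1L) / n_pos +
      sum(probabilities < cc & labels == 0L) / n_neg - 1
  }, numeric(1))
  best <- which(j == max(j))[1]  # smallest cutoff among ties
  cutoff <- min(max(candidates[best], .Machine$double.eps),
                1 - .Machine$double.neg.eps)
  list(cutoff = cutoff, j = j[best],
       sensitivity = sum(probabilities >= cutoff & labels == 1L) / n_pos,
       specificity = sum(probabilities < cutoff & labels == 0L) / n_neg)
}
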