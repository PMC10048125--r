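#' Confusion counts for +1/-1 predictions
#'
#' @param y_true,y_pred Label vectors of equal length with values in
#'   \{+1, -1\}; +1 is the positive (minority) class.
#' @return An object of class `"confusion"`: list with integer counts `tp`,
#'   `fn`, `tn`, `fp`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have the same length")
  if (!all(y_true %in% c(-1, 1)) || !all(y_pred %in% c(-1, 1)))
    stop("labels must be +1 or -1")
  structure(list(
    tp = sum(y_true == 1 & y_pred == 1),
    fn = sum(y_true == 1 & y_pred == -1),
    tn = sum(y_true == -1 & y_pred == -1),
    fp = sum(y_true == -1 & y_pred == 1)
  ), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("+1", "-1"), predicted = c("+1", "-1")))
  print(m)
  cat(sprintf("sensitivity %.4f, specificity %.4f, G-mean %.4f, accuracy %.4f\n",
              sensitivity(x), specificity(x), gmean(x), accuracy(x)))
  invisible(x)
}

## ratio with the 0/0 -> 0 convention used throughout the evaluation
safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Sensitivity, specificity, accuracy and G-mean
#'
#' `sensitivity` is tp/(tp+fn), `specificity` tn/(tn+fp), `accuracy`
#' (tp+tn)/n, and `gmean` the geometric mean
#' \eqn{\sqrt{\mathrm{sensitivity} \times \mathrm{specificity}}} — the
#' balance-aware score used to evaluate classifiers on imbalanced data.  A
#' ratio with a zero denominator is defined as 0, so a degenerate classifier
#' that never predicts one of the classes scores a G-mean of 0.
#'
#' Each function accepts either a `"confusion"` object or a pair of +1/-1
#' label vectors.
#'
#' @param x A `"confusion"` object, or the true labels.
#' @param y_pred Predicted labels, when `x` is the truth vector.
#' @return A number in \[0, 1\].
#' @examples
#' gmean(confusion(c(1, 1, -1, -1), c(1, -1, -1, 1)))  # sqrt(0.5 * 0.5)
#' @export
gmean <- function(x, y_pred = NULL) {
  cm <- as_confusion(x, y_pred)
  sqrt(sensitivity(cm) * specificity(cm))
}

#' @rdname gmean
#' @export
sensitivity <- function(x, y_pred = NULL) {
  cm <- as_confusion(x, y_pred)
  safe_ratio(cm$tp, cm$tp + cm$fn)
}

#' @rdname gmean
#' @export
specificity <- function(x, y_pred = NULL) {
  cm <- as_confusion(x, y_pred)
  safe_ratio(cm$tn, cm$tn + cm$fp)
}

#' @rdname gmean
#' @export
accuracy <- function(x, y_pred = NULL) {
  cm <- as_confusion(x, y_pred)
  safe_ratio(cm$tp + cm$tn, cm$tp + cm$fn + cm$tn + cm$fp)
}

as_confusion <- function(x, y_pred) {
  if (inherits(x, "confusion")) x else confusion(x, y_pred)
}

#' Paired t-test between two performance traces
#'
#' Two-sided paired t-test on the per-repetition differences `a - b`,
#' as used to declare one classifier significantly better than another
#' across repeated evaluations.  When every difference is numerically zero
#' the test statistic is undefined; by convention the p-value is then 1 and
#' the comparison is not significant (flagged by `degenerate = TRUE`).
#'
#' @param a,b Numeric vectors of equal length (paired by repetition).
#' @param alpha Significance level, default 0.05.
#' @return An object of class `"paired_ttest"`: list with `t_statistic`,
#'   `p_value`, `significant`, `mean_difference`, `n_pairs`, `alpha`,
#'   `degenerate`.
#' @export
paired_ttest <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b))
    stop("'a' and 'b' must have the same length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) < .Machine$double.eps^0.5 * (1 + max(abs(d)))) {
    ## constant differences: t.test would error; all-zero means "no evidence
    ## of a difference", a constant non-zero shift is an exact difference
    all_zero <- all(d == 0)
    out <- list(t_statistic = if (all_zero) 0 else sign(mean(d)) * Inf,
                p_value = if (all_zero) 1 else 0,
                significant = !all_zero,
                mean_difference = mean(d), n_pairs = length(d),
                alpha = alpha, degenerate = TRUE)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    out <- list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
                significant = tt$p.value < alpha,
                mean_difference = unname(tt$estimate), n_pairs = length(d),
                alpha = alpha, degenerate = FALSE)
  }
  class(out) <- "paired_ttest"
  out
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test: mean difference %.4f over %d pairs\n",
              x$mean_difference, x$n_pairs))
  cat(sprintf("  t = %.3f, p = %.4g (%ssignificant at alpha = %g)%s\n",
              x$t_statistic, x$p_value, if (x$significant) "" else "not ",
              x$alpha, if (x$degenerate) " [zero-variance differences]" else ""))
  invisible(x)
}
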