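#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` cross-validation folds, stratifying by
#' class so every fold receives its proportional share of the minority
#' class.  With only a handful of minority samples an unstratified split can
#' place all of them in one fold, making the out-of-fold G-mean undefined.
#'
#' @param y Labels (+1/-1).
#' @param k Number of folds.
#' @param seed Integer seed; the assignment is a deterministic function of
#'   `(y, k, seed)`.
#' @return Integer vector in `1:k`, one entry per sample.
#' @export
stratified_folds <- function(y, k, seed = NULL) {
  y <- as_pm1(y)
  if (k < 2) stop("'k' must be >= 2")
  n_min <- sum(y == 1)
  if (n_min < k)
    stop("minority class has ", n_min, " samples, fewer than k = ", k,
         " folds; use a smaller k")
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(1, -1)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}
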