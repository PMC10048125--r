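#' SMOTE minority oversampling
#'
#' Synthetic Minority Oversampling TEchnique: grows the minority class by
#' interpolating between minority points and their minority-class nearest
#' neighbours.  Each synthetic point is
#' \eqn{x_{new} = x + u\,(x_{nn} - x)} with \eqn{u \sim U(0, 1)} and
#' \eqn{x_{nn}} drawn uniformly among the `min(k, n_min - 1)` nearest
#' minority neighbours of the seed point `x` (Euclidean distance).  Seed
#' points are cycled round-robin through the minority rows so the synthetic
#' mass spreads evenly; enough points are generated to bring the
#' minority/majority ratio up to `target_ratio` (count rounded down).
#'
#' In benchmark flows SMOTE is applied to the *training* portion only, after
#' any train/test or fold split, so no synthetic point leaks into evaluation.
#'
#' @param x Numeric feature matrix.
#' @param y Labels, +1 minority / -1 majority (0/1 recoded).
#' @param k Number of nearest neighbours considered, default 5.
#' @param target_ratio Desired minority/majority ratio, default 1 (balanced).
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return List with components `x` and `y`: the original rows unchanged and
#'   in order, synthetic minority rows (label +1) appended.
#' @examples
#' sim <- simulate_imbalanced("low", mu = 0.5, rho = 0, ir = 3,
#'                            n_train = 60, n_test = 10, seed = 3)
#' bal <- smote(sim$train$x, sim$train$y, seed = 3)
#' table(bal$y)
#' @export
smote <- function(x, y, k = 5, target_ratio = 1, seed = NULL) {
  x <- as_matrix_rows(x)
  y <- as_pm1(y)
  if (k < 1) stop("'k' must be >= 1")
  if (target_ratio <= 0) stop("'target_ratio' must be positive")
  min_idx <- which(y == 1)
  n_min <- length(min_idx)
  n_maj <- sum(y == -1)
  if (n_min < 2L)
    stop("SMOTE needs at least 2 minority samples (no neighbour exists)")

  n_syn <- floor(target_ratio * n_maj) - n_min
  if (n_syn <= 0) return(list(x = x, y = y))

  if (!is.null(seed)) set.seed(seed)
  xm <- x[min_idx, , drop = FALSE]
  ## k nearest minority neighbours of each minority point (self excluded)
  D <- as.matrix(stats::dist(xm))
  diag(D) <- Inf
  k_eff <- min(k, n_min - 1L)
  nn <- t(apply(D, 1L, function(r) order(r)[seq_len(k_eff)]))
  nn <- matrix(nn, nrow = n_min)  # k_eff = 1 collapses apply output

  seeds <- rep_len(seq_len(n_min), n_syn)      # round-robin through minority rows
  picks <- nn[cbind(seeds, sample.int(k_eff, n_syn, replace = TRUE))]
  u <- stats::runif(n_syn)
  x_syn <- xm[seeds, , drop = FALSE] +
    u * (xm[picks, , drop = FALSE] - xm[seeds, , drop = FALSE])

  list(x = rbind(x, x_syn), y = c(y, rep(1, n_syn)))
}
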