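#' Equicorrelated (compound-symmetry) covariance matrix
#'
#' Returns \eqn{\Sigma = (1-\rho) I_k + \rho 1_k 1_k^T}: unit variances with
#' a common pairwise correlation `rho`.  Eigenvalues are \eqn{1 + (k-1)\rho}
#' (once) and \eqn{1-\rho} (k-1 times), so the matrix is positive definite
#' for \eqn{0 \le \rho < 1}.
#'
#' @param k Dimension (number of informative features).
#' @param rho Common correlation in \[0, 1).
#' @return A `k` by `k` covariance matrix.
#' @export
equicorrelated_cov <- function(k, rho) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer")
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("'rho' must be in [0, 1)")
  (1 - rho) * diag(k) + rho * matrix(1, k, k)
}

## minority count under the imbalance-ratio rounding rule; majority = n - minority
class_counts <- function(n, ir) {
  if (ir < 1) stop("'ir' must be >= 1 (majority/minority)")
  n_min <- round(n / (1 + ir))
  n_maj <- n - n_min
  if (n_min < 1L || n_maj < 1L)
    stop("imbalance ratio ", ir, " with n = ", n, " leaves a class empty")
  c(minority = n_min, majority = n_maj)
}

#' Simulate an imbalanced two-class Gaussian benchmark dataset
#'
#' Generates a training/test pair in the equicorrelated-Gaussian design used
#' to benchmark imbalanced SVM classifiers.  In the low-dimensional regime
#' each sample has 30 features of which 10 are informative; in the
#' high-dimensional regime, 1000 features with 100 informative.  The
#' informative block is drawn from \eqn{N_k(+\mu 1, \Sigma)} for the
#' minority class (+1) and \eqn{N_k(-\mu 1, \Sigma)} for the majority class
#' (-1), with \eqn{\Sigma} the [equicorrelated_cov()] matrix; the remaining
#' features are independent N(0, 1) noise for both classes.
#'
#' Class sizes follow the imbalance ratio `ir` (majority/minority) with
#' minority count `round(n/(1+ir))`; the test set uses the same ratio as the
#' training set unless `test_ir` overrides it.  Train and test are drawn
#' independently; the draw is deterministic given `seed`.
#'
#' @param regime `"low"` (d = 30, 10 informative) or `"high"` (d = 1000, 100
#'   informative).
#' @param mu Class-mean shift of each informative feature (the benchmark
#'   design uses 0.25 and 0.5).
#' @param rho Common correlation of the informative features (0 or 0.7 in
#'   the benchmark design).
#' @param ir Imbalance ratio, majority/minority, >= 1 (1, 1.5 or 3 in the
#'   benchmark design).
#' @param n_train Training-set size (60 or 200 in the benchmark design).
#' @param n_test Test-set size, default 2000.
#' @param seed Integer seed.
#' @param test_ir Optional test-set imbalance ratio; defaults to `ir`.
#' @return An object of class `"sim_pair"`: list with `train` and `test`
#'   (each a list with matrix `x` and +1/-1 vector `y`) and `config`
#'   (the generating parameters).
#' @examples
#' sim <- simulate_imbalanced("low", mu = 0.5, rho = 0.7, ir = 3,
#'                            n_train = 60, n_test = 200, seed = 7)
#' table(sim$train$y)   # 15 minority, 45 majority
#' @export
simulate_imbalanced <- function(regime = c("low", "high"), mu, rho, ir,
                                n_train, n_test = 2000, seed = NULL,
                                test_ir = ir) {
  regime <- match.arg(regime)
  d <- if (regime == "low") 30L else 1000L
  k <- if (regime == "low") 10L else 100L
  if (mu <= 0) stop("'mu' must be positive")
  if (!is.null(seed)) set.seed(seed)
  train <- draw_split(n_train, ir, d, k, mu, rho)
  test <- draw_split(n_test, test_ir, d, k, mu, rho)
  structure(list(train = train, test = test,
                 config = list(regime = regime, d = d, k_informative = k,
                               mu = mu, rho = rho, ir = ir, test_ir = test_ir,
                               n_train = n_train, n_test = n_test,
                               seed = seed)),
            class = "sim_pair")
}

draw_split <- function(n, ir, d, k, mu, rho) {
  cc <- class_counts(n, ir)
  sigma <- equicorrelated_cov(k, rho)
  one_class <- function(n_cls, shift) {
    inform <- MASS::mvrnorm(n_cls, mu = rep(shift, k), Sigma = sigma)
    noise <- matrix(stats::rnorm(n_cls * (d - k)), n_cls, d - k)
    cbind(matrix(inform, n_cls, k), noise)
  }
  x <- rbind(one_class(cc["minority"], +mu), one_class(cc["majority"], -mu))
  colnames(x) <- c(paste0("inf", seq_len(k)), paste0("noise", seq_len(d - k)))
  list(x = x, y = c(rep(1, cc["minority"]), rep(-1, cc["majority"])))
}

#' @export
print.sim_pair <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated imbalanced pair (%s-dimensional: d = %d, %d informative)\n",
              cfg$regime, cfg$d, cfg$k_informative))
  cat(sprintf("  mu = %g, rho = %g, IR = %g (test IR %g)\n",
              cfg$mu, cfg$rho, cfg$ir, cfg$test_ir))
  cat(sprintf("  train n = %d (%d/+1), test n = %d (%d/+1)\n",
              length(x$train$y), sum(x$train$y == 1),
              length(x$test$y), sum(x$test$y == 1)))
  invisible(x)
}

#' Full factorial grid of simulation configurations
#'
#' The benchmark design crosses regime (low/high dimension), mean shift
#' mu (0.25, 0.5), correlation rho (0, 0.7), training size (60, 200) and
#' imbalance ratio (1, 1.5, 3): 48 configurations in a fixed, reproducible
#' order.
#'
#' @return Data frame with 48 rows and columns `regime`, `mu`, `rho`,
#'   `n_train`, `ir` and a `config_id` key.
#' @export
simulation_grid <- function() {
  g <- expand.grid(ir = c(1, 1.5, 3), n_train = c(60, 200), rho = c(0, 0.7),
                   mu = c(0.25, 0.5), regime = c("low", "high"),
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("regime", "mu", "rho", "n_train", "ir")]
  g$config_id <- seq_len(nrow(g))
  g
}

## per-configuration, per-repetition seed derived from a base seed by a fixed
## counter scheme (kept well below 2^31)
derive_seed <- function(base_seed, config_id, rep) {
  (base_seed %% 100000L) * 10000L + config_id * 100L + rep
}
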