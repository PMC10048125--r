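# Independent dense QP solve of the SVM dual, used as the correctness oracle
# for the libsvm-backed fit.  kernlab::ipop is an interior-point solver on the
# full Gram matrix -- a different algorithm and code base from libsvm.
#
#   max  sum(alpha) - 1/2 alpha' (yy' * K) alpha
#   s.t. 0 <= alpha <= C,  sum(alpha * y) = 0
qp_oracle_fit <- function(x, y, cost, gamma) {
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  H <- (y %o% y) * K
  sol <- kernlab::ipop(c = rep(-1, n), H = H,
                       A = matrix(as.numeric(y), 1), b = 0, r = 0,
                       l = rep(0, n), u = rep(cost, n),
                       sigf = 9, maxiter = 200)
  alpha <- kernlab::primal(sol)
  f_nob <- drop(K %*% (alpha * y))
  usv <- alpha > 1e-6 * cost & alpha < cost * (1 - 1e-6)
  if (!any(usv)) usv <- alpha > 1e-6 * cost
  bias <- mean(y[usv] - f_nob[usv])
  list(alpha = alpha, bias = bias,
       decision = function(newx)
         drop(rbf_kernel(newx, x, gamma) %*% (alpha * y)) + bias)
}

# small random two-class problem with a mild class shift
random_problem <- function(n = 30, d = 3, imbalance = 0.5, shift = 1) {
  n_pos <- max(2L, round(n * imbalance))
  y <- c(rep(1, n_pos), rep(-1, n - n_pos))
  x <- matrix(stats::rnorm(n * d), n, d) + shift * outer(y, rep(1, d)) / 2
  list(x = x, y = y)
}
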