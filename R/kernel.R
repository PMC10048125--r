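#' Gaussian radial basis kernel matrix
#'
#' Computes the Gram matrix `K[i, j] = exp(-gamma * ||x1_i - x2_j||^2)`
#' between the rows of two matrices.
#'
#' @param x1,x2 Numeric matrices with the same number of columns. Vectors are
#'   treated as single-row matrices.
#' @param gamma Positive kernel width parameter. Larger values shrink the
#'   neighbourhood a support vector influences.
#' @return A `nrow(x1)` by `nrow(x2)` matrix with entries in (0, 1].
#' @examples
#' x <- matrix(rnorm(10), 5, 2)
#' K <- rbf_kernel(x, x, gamma = 0.5)
#' all(diag(K) == 1)
#' @export
rbf_kernel <- function(x1, x2, gamma) {
  x1 <- as_matrix_rows(x1)
  x2 <- as_matrix_rows(x2)
  if (ncol(x1) != ncol(x2))
    stop("'x1' and 'x2' must have the same number of columns (got ",
         ncol(x1), " and ", ncol(x2), ")")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a single positive number")
  exp(-gamma * sq_dist(x1, x2))
}

## squared Euclidean distances via the expansion ||a-b||^2 = a.a + b.b - 2 a.b;
## clamp tiny negatives from cancellation so kernel entries stay <= 1
sq_dist <- function(x1, x2) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  d2[d2 < 0] <- 0
  d2
}

## coerce a vector to a 1-row matrix, pass matrices through
as_matrix_rows <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  x
}
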