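#' Read a delimited dataset with a label column
#'
#' Reads a delimited text file (header row, numeric feature columns plus one
#' label column) into the feature-matrix / label-vector pair the fitting
#' functions consume.  Labels may be coded +1/-1 or 1/0; 0 is recoded to -1.
#' The class coded +1 (or 1) is treated as the minority class of interest.
#'
#' @param path Path to the delimited file.
#' @param label Name of the label column, default `"label"`.
#' @param sep Field separator, default `","`.
#' @return List with `x` (numeric matrix) and `y` (+1/-1 vector).
#' @export
read_dataset <- function(path, label = "label", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!label %in% names(df))
    stop("label column '", label, "' not found; columns are: ",
         paste(names(df), collapse = ", "))
  y <- as_pm1(df[[label]])
  x <- as.matrix(df[, setdiff(names(df), label), drop = FALSE])
  if (!is.numeric(x)) stop("feature columns must all be numeric")
  list(x = x, y = y)
}

#' Write a dataset to delimited text
#'
#' Inverse of [read_dataset()]: features plus a `label` column of +1/-1.
#'
#' @param data List with `x` and `y` (as returned by [read_dataset()],
#'   [smote()] or a [simulate_imbalanced()] split).
#' @param path Output path.
#' @param sep Field separator, default `","`.
#' @export
write_dataset <- function(data, path, sep = ",") {
  x <- as_matrix_rows(data$x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  df <- as.data.frame(x)
  df$label <- as_pm1(data$y)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save and restore a fitted b-SVM model
#'
#' Serializes every component needed to predict (support vectors, dual
#' coefficients, labels, bias, gamma, cost, tuning factor, scaling
#' statistics) to a self-describing JSON file, so a model can be applied
#' without refitting.
#'
#' @param object A fitted `"bsvm"` model.
#' @param path File path.
#' @return `write_bsvm` returns `path` invisibly; `read_bsvm` returns the
#'   restored `"bsvm"` object.
#' @export
write_bsvm <- function(object, path) {
  stopifnot(inherits(object, "bsvm"))
  payload <- list(
    format = "bsvm-model", version = 1L,
    sv = unclass(object$sv), alpha = object$alpha,
    sv_labels = object$sv_labels, index = object$index,
    bias = object$bias, gamma = object$gamma, cost = object$cost,
    delta = object$delta, usv = object$usv,
    n_features = object$n_features, n_train = object$n_train,
    n_minority = object$n_minority, n_majority = object$n_majority,
    center = object$center, spread = object$spread
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_bsvm
#' @export
read_bsvm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "bsvm-model"))
    stop("'", path, "' is not a serialized b-SVM model")
  m <- list(
    call = NULL,
    sv = matrix(as.numeric(p$sv), nrow = length(p$alpha)),
    alpha = as.numeric(p$alpha), sv_labels = as.numeric(p$sv_labels),
    index = as.integer(p$index), bias = p$bias, gamma = p$gamma,
    cost = p$cost, delta = p$delta, usv = as.logical(p$usv),
    n_features = as.integer(p$n_features), n_train = as.integer(p$n_train),
    n_minority = as.integer(p$n_minority),
    n_majority = as.integer(p$n_majority),
    center = if (length(p$center)) as.numeric(p$center) else NULL,
    spread = if (length(p$spread)) as.numeric(p$spread) else NULL
  )
  structure(m, class = "bsvm")
}
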