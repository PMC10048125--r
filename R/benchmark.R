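#' Evaluate SVM variants on one train/test pair
#'
#' Runs the benchmark protocol for a single dataset: gamma selection (unless
#' fixed) and any resampling or threshold tuning happen on the training data
#' only, every variant is then scored on the untouched test set.
#'
#' Variants:
#' * `"standard"` — SVM with the zero-threshold rule;
#' * `"bsvm"` — the same fitted dual solution with the \eqn{\Delta}-shifted
#'   rule (standard and b-SVM share one fit and differ only in the cutoff);
#' * `"smote"` — SMOTE-balanced training set, then a standard SVM (gamma
#'   selection, when requested, runs on the balanced set);
#' * `"cvthr"` — cross-validated threshold tuning with fixed `cost = 10` and
#'   `gamma = 1/d`, skipping gamma selection (that baseline is already the
#'   most expensive).
#'
#' @param train,test Lists with components `x` (matrix) and `y` (+1/-1).
#' @param methods Subset of `c("standard", "smote", "cvthr", "bsvm")`.
#' @param gamma_method `"cv"` (5-fold CV selection), `"minmax"` (training
#'   G-mean heuristic), or `"default"` (fixed `1/d`); both selection
#'   strategies run at cost 10, see [select_gamma()].
#' @param cost Cost used for the final fits, default 10.
#' @param folds Folds for CV gamma selection and CV-THR tuning, default 5.
#' @param seed Integer seed driving fold assignment and SMOTE draws.
#' @return Data frame with one row per method: selected gamma, the tuned
#'   cutoff (`delta` for b-SVM, `theta` for CV-THR, 0 otherwise), accuracy,
#'   G-mean, sensitivity, specificity and elapsed seconds.
#' @export
evaluate_pair <- function(train, test,
                          methods = c("standard", "smote", "cvthr", "bsvm"),
                          gamma_method = c("cv", "minmax", "default"),
                          cost = 10, folds = 5, seed = NULL) {
  gamma_method <- match.arg(gamma_method)
  methods <- match.arg(methods, several.ok = TRUE)
  d <- ncol(train$x)

  pick_gamma <- function(x, y) {
    switch(gamma_method,
           default = 1 / d,
           minmax = select_gamma(x, y, "minmax")$gamma,
           cv = select_gamma(x, y, "cv", cost = cost, folds = folds,
                             seed = seed)$gamma)
  }

  rows <- list()
  add_row <- function(method, gamma, cutoff, y_pred, elapsed) {
    cm <- confusion(test$y, y_pred)
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, gamma_method = gamma_method, gamma = gamma,
      cutoff = cutoff, accuracy = accuracy(cm), gmean = gmean(cm),
      sensitivity = sensitivity(cm), specificity = specificity(cm),
      elapsed = elapsed)
  }

  if (any(c("standard", "bsvm") %in% methods)) {
    t0 <- proc.time()[["elapsed"]]
    g <- pick_gamma(train$x, train$y)
    fit <- bsvm.default(train$x, train$y, cost = cost, gamma = g)
    el <- proc.time()[["elapsed"]] - t0
    if ("standard" %in% methods)
      add_row("standard", g, 0, predict(fit, test$x, rule = "standard"), el)
    if ("bsvm" %in% methods)
      add_row("bsvm", g, fit$delta, predict(fit, test$x, rule = "bsvm"), el)
  }
  if ("smote" %in% methods) {
    t0 <- proc.time()[["elapsed"]]
    bal <- smote(train$x, train$y, seed = seed)
    g <- pick_gamma(bal$x, bal$y)
    fit <- bsvm.default(bal$x, bal$y, cost = cost, gamma = g)
    el <- proc.time()[["elapsed"]] - t0
    add_row("smote", g, 0, predict(fit, test$x, rule = "standard"), el)
  }
  if ("cvthr" %in% methods) {
    t0 <- proc.time()[["elapsed"]]
    fit <- cvthr(train$x, train$y, cost = 10, gamma = 1 / d, folds = folds,
                 seed = seed)
    el <- proc.time()[["elapsed"]] - t0
    add_row("cvthr", 1 / d, fit$theta, predict(fit, test$x), el)
  }
  do.call(rbind, rows)
}

#' Run the simulation benchmark
#'
#' Orchestrates the full experiment flow on simulated data: for every
#' configuration and repetition a fresh train/test pair is generated with a
#' per-(configuration, repetition) derived seed, [evaluate_pair()] scores the
#' requested variants, and everything is collected into one records table.
#' Fit failures are caught and recorded; the run continues.
#'
#' @param grid Data frame of configurations as from [simulation_grid()]
#'   (columns `regime`, `mu`, `rho`, `n_train`, `ir`, `config_id`); subset it
#'   to run a partial design.
#' @param methods,gamma_method,cost,folds Passed to [evaluate_pair()].
#' @param repeats Repetitions per configuration (the full design uses 50).
#' @param n_test Test-set size per repetition, default 2000.
#' @param seed Base seed; all randomness derives from it.
#' @return Data frame of benchmark records: configuration columns plus the
#'   per-method evaluation columns of [evaluate_pair()] and the repetition
#'   index and derived seed.
#' @export
run_simulation_experiment <- function(grid = simulation_grid(),
                                      methods = c("standard", "smote",
                                                  "cvthr", "bsvm"),
                                      gamma_method = "cv", repeats = 50,
                                      cost = 10, folds = 5, n_test = 2000,
                                      seed = 1) {
  out <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- grid[i, ]
    for (r in seq_len(repeats)) {
      s <- derive_seed(seed, cfg$config_id, r)
      rec <- tryCatch({
        sim <- simulate_imbalanced(cfg$regime, mu = cfg$mu, rho = cfg$rho,
                                   ir = cfg$ir, n_train = cfg$n_train,
                                   n_test = n_test, seed = s)
        evaluate_pair(sim$train, sim$test, methods = methods,
                      gamma_method = gamma_method, cost = cost,
                      folds = folds, seed = s)
      }, error = function(e) {
        data.frame(method = methods, gamma_method = gamma_method,
                   gamma = NA_real_, cutoff = NA_real_, accuracy = NA_real_,
                   gmean = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, elapsed = NA_real_,
                   error = conditionMessage(e))
      })
      if (is.null(rec$error)) rec$error <- NA_character_
      rec <- cbind(cfg, repetition = r, rep_seed = s, rec, row.names = NULL)
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Repeated stratified cross-validation on a user dataset
#'
#' Protocol for real tabular datasets: `repeats` rounds of stratified
#' k-fold cross validation.  Within each fold, all tuning (gamma selection,
#' SMOTE, threshold tuning) is a function of the training portion only; the
#' per-fold confusion counts are pooled into one record per (method,
#' repetition), which is robust to folds containing few or no minority test
#' samples.
#'
#' @param x Feature matrix.
#' @param y Labels, +1 minority / -1 majority (0/1 recoded).
#' @param methods,gamma_method,cost Passed to [evaluate_pair()].
#' @param folds Outer CV folds, default 10.
#' @param inner_folds Folds used inside the training portion for CV gamma
#'   selection and CV-THR tuning, default 5.
#' @param repeats Number of CV repetitions, default 30.
#' @param seed Base seed.
#' @return Data frame with one row per (method, repetition): pooled
#'   accuracy, G-mean, sensitivity and specificity.
#' @export
run_cv_experiment <- function(x, y,
                              methods = c("standard", "smote", "cvthr", "bsvm"),
                              gamma_method = "cv", folds = 10,
                              inner_folds = 5, repeats = 30, cost = 10,
                              seed = 1) {
  x <- as_matrix_rows(x)
  y <- as_pm1(y)
  out <- list()
  for (r in seq_len(repeats)) {
    rep_seed <- derive_seed(seed, 0L, r)
    fold <- stratified_folds(y, folds, seed = rep_seed)
    fold_rows <- list()
    for (k in seq_len(folds)) {
      tr <- fold != k
      rec <- evaluate_pair(list(x = x[tr, , drop = FALSE], y = y[tr]),
                           list(x = x[!tr, , drop = FALSE], y = y[!tr]),
                           methods = methods, gamma_method = gamma_method,
                           cost = cost, folds = inner_folds,
                           seed = rep_seed + k)
      n_te <- sum(!tr)
      ## back out confusion counts from the rates to pool across folds
      n_pos <- sum(y[!tr] == 1); n_neg <- n_te - n_pos
      rec$tp <- round(rec$sensitivity * n_pos)
      rec$tn <- round(rec$specificity * n_neg)
      rec$n_pos <- n_pos; rec$n_neg <- n_neg
      fold_rows[[k]] <- rec
    }
    fr <- do.call(rbind, fold_rows)
    for (m in unique(fr$method)) {
      fm <- fr[fr$method == m, ]
      cm <- structure(list(tp = sum(fm$tp), fn = sum(fm$n_pos) - sum(fm$tp),
                           tn = sum(fm$tn), fp = sum(fm$n_neg) - sum(fm$tn)),
                      class = "confusion")
      out[[length(out) + 1L]] <- data.frame(
        method = m, gamma_method = gamma_method, repetition = r,
        accuracy = accuracy(cm), gmean = gmean(cm),
        sensitivity = sensitivity(cm), specificity = specificity(cm),
        elapsed = sum(fm$elapsed))
    }
  }
  do.call(rbind, out)
}

#' Paired comparison of the two gamma-selection strategies
#'
#' For one simulation configuration, generates `repeats` independent
#' train/test pairs and fits the chosen SVM variant twice per pair — once
#' with Min-max gamma selection, once with 5-fold CV gamma selection — so
#' the per-repetition test G-means are paired.  The final fits use
#' `cost = 10`; each selection strategy uses its own internal cost
#' convention (see [select_gamma()]).
#'
#' @param method `"standard"`, `"smote"` or `"bsvm"`.
#' @param regime,mu,rho,n_train,ir,n_test Configuration passed to
#'   [simulate_imbalanced()].
#' @param repeats Number of replicates, default 25.
#' @param cost Final-fit cost, default 10.
#' @param seed Base seed.
#' @return Data frame with one row per replicate: test G-mean under each
#'   selection strategy and the selected gammas.
#' @export
compare_gamma_selection <- function(method = c("standard", "smote", "bsvm"),
                                    regime, mu, rho, n_train, ir = 3,
                                    n_test = 2000, repeats = 25, cost = 10,
                                    seed = 1) {
  method <- match.arg(method)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    s <- derive_seed(seed, 99L, r)
    sim <- simulate_imbalanced(regime, mu = mu, rho = rho, ir = ir,
                               n_train = n_train, n_test = n_test, seed = s)
    g_one <- function(gm) {
      rec <- evaluate_pair(sim$train, sim$test, methods = method,
                           gamma_method = gm, cost = cost, seed = s)
      c(rec$gmean, rec$gamma)
    }
    mm <- g_one("minmax"); cv <- g_one("cv")
    rows[[r]] <- data.frame(repetition = r, rep_seed = s,
                            gmean_minmax = mm[1], gmean_cv = cv[1],
                            gamma_minmax = mm[2], gamma_cv = cv[2])
  }
  do.call(rbind, rows)
}

#' Summarize benchmark records
#'
#' Aggregates a records table to mean (standard deviation) per method, the
#' usual presentation of repeated-CV classification results.
#'
#' @param records Data frame from [run_simulation_experiment()] or
#'   [run_cv_experiment()].
#' @param by Grouping columns, default `c("method", "gamma_method")`.
#' @return Data frame of means and standard deviations of accuracy and
#'   G-mean per group, plus a formatted `pretty` column for each metric.
#' @export
summarize_benchmark <- function(records, by = c("method", "gamma_method")) {
  by <- intersect(by, names(records))
  agg <- function(col) {
    m <- stats::aggregate(records[[col]], records[by], mean, na.rm = TRUE)
    s <- stats::aggregate(records[[col]], records[by], stats::sd, na.rm = TRUE)
    names(m)[ncol(m)] <- paste0(col, "_mean")
    names(s)[ncol(s)] <- paste0(col, "_sd")
    merge(m, s, by = by)
  }
  out <- merge(agg("accuracy"), agg("gmean"), by = by)
  out$accuracy_pretty <- sprintf("%.4f (%.4f)", out$accuracy_mean, out$accuracy_sd)
  out$gmean_pretty <- sprintf("%.4f (%.4f)", out$gmean_mean, out$gmean_sd)
  out
}
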