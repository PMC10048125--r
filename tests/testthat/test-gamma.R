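test_that("gamma grid spans 2^-20 to 1/d with half-power steps", {
  g <- gamma_grid(1024)
  expect_length(g, 21)                  # 1/1024 = 2^-10 lands on the grid
  expect_equal(g[1], 2^-20)
  expect_equal(g[length(g)], 1 / 1024)
  expect_equal(diff(log2(g)), rep(0.5, 20))

  g30 <- gamma_grid(30)
  expect_equal(g30[length(g30)], 1 / 30)          # appended endpoint
  expect_equal(g30[length(g30) - 1], 2^-5)        # last half-power <= 1/30
  expect_true(all(diff(g30) > 0))

  expect_equal(gamma_grid(2^20), 2^-20)           # endpoint equals start
  expect_error(gamma_grid(0), "positive")
})

test_that("tie-breaking picks the smallest gamma among maxima", {
  # injected synthetic fitness traces against an independent scan:
  # sort candidates by (-fitness, gamma) and take the head
  set.seed(33)
  for (i in 1:25) {
    g <- sort(runif(sample(5:30, 1)))
    fit <- sample(round(runif(length(g), 0, 1), 2), replace = TRUE)
    picked <- bsvm:::smallest_argmax(g, fit)
    brute <- g[order(-fit, g)][1]
    expect_identical(picked, brute)
  }
  expect_equal(bsvm:::smallest_argmax(1:4, c(0.6, 0.9, 0.9, 0.7)), 2)
  expect_equal(bsvm:::smallest_argmax(1:4, rep(0.3, 4)), 1)
})

test_that("minmax selection equals a brute-force re-evaluation", {
  set.seed(34)
  for (i in 1:5) {
    sim <- simulate_imbalanced("low", mu = 0.5, rho = 0, ir = 1.5,
                               n_train = 40, n_test = 10, seed = 340 + i)
    sel <- select_gamma(sim$train$x, sim$train$y, "minmax")
    # independent scan: refit every candidate through the full model path
    # (same screening tolerance) and sort by (-gmean, gamma)
    brute <- vapply(sel$trace$gamma, function(g) {
      f <- suppressWarnings(bsvm(sim$train$x, sim$train$y,
                                 cost = sel$cost, gamma = g,
                                 tolerance = 1e-3))
      gmean(sim$train$y, predict(f, sim$train$x, rule = sel$rule))
    }, numeric(1))
    expect_equal(sel$trace$gmean, brute)
    expect_equal(sel$gamma, sel$trace$gamma[order(-brute, sel$trace$gamma)][1])
    expect_true(sel$gamma %in% sel$trace$gamma)
  }
})

test_that("cv selection is deterministic and matches a brute-force loop", {
  set.seed(35)
  sim <- simulate_imbalanced("low", mu = 0.5, rho = 0, ir = 3,
                             n_train = 60, n_test = 10, seed = 35)
  x <- sim$train$x; y <- sim$train$y
  s1 <- select_gamma(x, y, "cv", seed = 99)
  s2 <- select_gamma(x, y, "cv", seed = 99)
  expect_identical(s1$gamma, s2$gamma)
  expect_identical(s1$trace, s2$trace)

  # brute force: materialize all folds x grid fits independently
  fold <- stratified_folds(y, 5, seed = 99)
  brute <- vapply(gamma_grid(ncol(x)), function(g) {
    mean(vapply(1:5, function(k) {
      f <- suppressWarnings(bsvm(x[fold != k, ], y[fold != k],
                                 cost = s1$cost, gamma = g,
                                 tolerance = 1e-3))
      gmean(y[fold == k],
            predict(f, x[fold == k, ], rule = "standard"))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(s1$trace$gmean, brute)
  expect_equal(s1$gamma, s1$trace$gamma[which.max(brute)])
})

test_that("selection respects grid bounds and minority-fold preconditions", {
  set.seed(36)
  sim <- simulate_imbalanced("low", mu = 0.5, rho = 0, ir = 3,
                             n_train = 40, n_test = 10, seed = 36)
  sel <- select_gamma(sim$train$x, sim$train$y, "minmax")
  expect_gte(sel$gamma, 2^-20)
  expect_lte(sel$gamma, 1 / 30)
  expect_true(all(sel$trace$gmean >= 0 & sel$trace$gmean <= 1))

  y_few <- c(rep(1, 3), rep(-1, 37))
  expect_error(select_gamma(sim$train$x, y_few, "cv", seed = 1), "smaller k")
  expect_error(select_gamma(sim$train$x, sim$train$y, cost = "bogus"),
               "preset")
})

test_that("resubstitution G-mean saturates at the large-gamma end", {
  # large gamma memorizes the training set, so the trace reaches its maximum
  # on the right; the smallest-maximizer rule must pick a gamma at or before
  # the saturation point
  set.seed(37)
  sim <- simulate_imbalanced("low", mu = 0.5, rho = 0, ir = 1.5,
                             n_train = 60, n_test = 10, seed = 37)
  sel <- select_gamma(sim$train$x, sim$train$y, "minmax")
  tr <- sel$trace
  expect_equal(tr$gmean[nrow(tr)], max(tr$gmean), tolerance = 1e-9)
  expect_lte(sel$gamma, tr$gamma[nrow(tr)])
})
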