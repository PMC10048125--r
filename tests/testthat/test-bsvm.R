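test_that("decision values match the dense QP oracle on random problems", {
  set.seed(101)
  for (i in 1:10) {
    prob <- random_problem(n = sample(12:40, 1), d = sample(1:5, 1))
    cost <- sample(c(1, 10), 1)
    gamma <- runif(1, 0.1, 1)
    fit <- suppressWarnings(bsvm(prob$x, prob$y, cost = cost, gamma = gamma))
    oracle <- qp_oracle_fit(prob$x, prob$y, cost, gamma)
    grid <- matrix(rnorm(10 * ncol(prob$x)), 10)
    expect_lt(max(abs(decision_values(fit, grid) - oracle$decision(grid))),
              1e-4)
  }
})

test_that("fitted models satisfy the KKT conditions", {
  set.seed(202)
  for (i in 1:8) {
    prob <- random_problem(n = 25, d = 3, imbalance = runif(1, 0.2, 0.5))
    cost <- 10^runif(1, -0.5, 1.5)
    fit <- suppressWarnings(bsvm(prob$x, prob$y, cost = cost,
                                 gamma = runif(1, 0.05, 2)))
    expect_true(all(fit$alpha > 0))
    expect_true(all(fit$alpha <= cost * (1 + 1e-8)))
    expect_lt(abs(sum(fit$alpha * fit$sv_labels)), 1e-6 * cost)
    # unbounded mask consistent with its definition
    expect_equal(fit$usv,
                 fit$alpha > 1e-8 * cost & fit$alpha < cost * (1 - 1e-8))
  }
})

test_that("antisymmetric data give zero bias and delta", {
  set.seed(3)
  xp <- matrix(rnorm(20), 10, 2) + 1
  x <- rbind(xp, -xp)                 # symmetric under (x, y) -> (-x, -y)
  y <- c(rep(1, 10), rep(-1, 10))
  fit <- bsvm(x, y, cost = 10, gamma = 0.5)
  expect_lt(abs(fit$bias), 1e-6)
  expect_lt(abs(fit$delta), 1e-12)
  expect_lt(abs(decision_values(fit, matrix(0, 1, 2))), 1e-6)
})

test_that("label swap negates decision values and delta", {
  set.seed(4)
  prob <- random_problem(n = 30, d = 2, imbalance = 0.3)
  f1 <- bsvm(prob$x, prob$y, cost = 10, gamma = 0.5)
  f2 <- bsvm(prob$x, -prob$y, cost = 10, gamma = 0.5)
  grid <- matrix(rnorm(20), 10, 2)
  expect_equal(decision_values(f1, grid), -decision_values(f2, grid),
               tolerance = 1e-6)
  expect_equal(f1$delta, -f2$delta, tolerance = 1e-9)
})

test_that("delta is the mean label of the unbounded support vectors", {
  set.seed(5)
  for (i in 1:5) {
    prob <- random_problem(n = 40, d = 3, imbalance = 0.25)
    fit <- suppressWarnings(bsvm(prob$x, prob$y, cost = 2, gamma = 0.3))
    usv_lab <- fit$sv_labels[fit$usv]
    if (length(usv_lab) > 0) {
      expect_equal(fit$delta, mean(usv_lab))
      expect_equal(fit$delta,
                   (sum(usv_lab == 1) - sum(usv_lab == -1)) / length(usv_lab))
    }
    expect_gte(fit$delta, -1)
    expect_lte(fit$delta, 1)
    expect_equal(fit$delta, tuning_factor(fit))
  }
})

test_that("bias is reproduced by decision values on the unbounded SVs", {
  set.seed(6)
  prob <- random_problem(n = 30, d = 2)
  fit <- bsvm(prob$x, prob$y, cost = 10, gamma = 0.5)
  f_sv <- decision_values(fit, fit$sv)
  usv <- fit$usv
  expect_equal(mean(fit$sv_labels[usv] - (f_sv[usv] - fit$bias)), fit$bias,
               tolerance = 1e-6)
})

test_that("prediction rules relate as a threshold shift", {
  set.seed(7)
  sim <- simulate_imbalanced("low", mu = 0.5, rho = 0, ir = 3,
                             n_train = 60, n_test = 300, seed = 7)
  fit <- bsvm(sim$train$x, sim$train$y, cost = 10, gamma = 1 / 30)
  expect_lt(fit$delta, 0)  # majority-dominated margin
  p_std <- predict(fit, sim$test$x, rule = "standard")
  p_b <- predict(fit, sim$test$x, rule = "bsvm")
  # lowering the cutoff only adds positive predictions
  expect_true(all(p_b[p_std == 1] == 1))
  expect_gte(sensitivity(sim$test$y, p_b), sensitivity(sim$test$y, p_std))
  expect_lte(specificity(sim$test$y, p_b), specificity(sim$test$y, p_std))
  # hand-checked shift: f = -0.2 with delta = -0.5 flips to +1
  fake <- fit; fake$delta <- -0.5
  f <- decision_values(fit, sim$test$x)
  i <- which(f > -0.5 & f < 0)
  expect_true(all(predict(fake, sim$test$x, rule = "bsvm")[i] == 1))
  expect_true(all(predict(fake, sim$test$x, rule = "standard")[i] == -1))
  # delta = 0 makes the rules identical
  fake$delta <- 0
  expect_equal(predict(fake, sim$test$x, rule = "bsvm"),
               predict(fake, sim$test$x, rule = "standard"))
})

test_that("separable data are classified consistently with the oracle", {
  set.seed(8)
  prob <- random_problem(n = 24, d = 2, shift = 6)   # well separated
  fit <- bsvm(prob$x, prob$y, cost = 10, gamma = 0.5)
  expect_equal(predict(fit, prob$x, rule = "standard"), prob$y)
  oracle <- qp_oracle_fit(prob$x, prob$y, 10, 0.5)
  expect_equal(sign(oracle$decision(prob$x)), prob$y)
})

test_that("input validation catches bad training data", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(bsvm(x, rep(1, 10)), "both classes")
  expect_error(bsvm(x, c(rep(1, 5), rep(2, 5))), "labels")
  expect_error(bsvm(x, rep(c(1, -1), 5), cost = -1), "cost")
  expect_error(bsvm(x, rep(c(1, -1), 5), gamma = 0), "gamma")
  xna <- x; xna[1, 1] <- NA
  expect_error(bsvm(xna, rep(c(1, -1), 5)), "missing")
  expect_error(decision_values(bsvm(x, rep(c(1, -1), 5)),
                               matrix(0, 1, 3)), "features")
})

test_that("0/1 labels are recoded and the formula interface works", {
  set.seed(9)
  d <- data.frame(a = rnorm(20), b = rnorm(20),
                  cls = rep(c(1, 0), 10))
  d$a <- d$a + 2 * as_pm1(d$cls)
  fit <- bsvm(cls ~ a + b, data = d, cost = 10, gamma = 0.5)
  expect_s3_class(fit, "bsvm")
  expect_setequal(unique(fit$sv_labels), c(1, -1))
  expect_equal(as_pm1(c(0, 1, 1)), c(-1, 1, 1))
  expect_equal(as_pm1(factor(c(-1, 1))), c(-1, 1))
  expect_error(as_pm1(c(1, 2)), "coded")
})

test_that("models survive a serialization round trip", {
  set.seed(10)
  prob <- random_problem(n = 30, d = 3)
  fit <- bsvm(prob$x, prob$y, cost = 10, gamma = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_bsvm(fit, path)
  back <- read_bsvm(path)
  grid <- matrix(rnorm(15), 5, 3)
  expect_equal(decision_values(back, grid), decision_values(fit, grid))
  expect_equal(back$delta, fit$delta)
  expect_equal(predict(back, grid), predict(fit, grid))
})
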