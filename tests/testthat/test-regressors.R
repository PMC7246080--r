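linear_data <- function(n = 50, seed = 1, slope = 2, noise = 0) {
  set.seed(seed)
  X <- matrix(runif(n, -2, 2), ncol = 1)
  list(X = X, y = slope * X[, 1] + rnorm(n, sd = noise))
}

test_that("all three network trainers reproduce a constant target", {
  d <- linear_data(40, seed = 2)
  yc <- rep(3.7, 40)
  for (fn in list(train_lm_ann, train_br_ann, train_scg_ann)) {
    m <- fn(d$X, yc, hidden_nodes = 4, seed = 5)
    expect_lt(max(abs(predict(m, d$X) - 3.7)), 1e-3)
  }
})

test_that("networks fit a noiseless linear map to high accuracy", {
  d <- linear_data(50, seed = 1)
  for (fn in list(train_lm_ann, train_br_ann, train_scg_ann)) {
    m <- fn(d$X, d$y, hidden_nodes = 4, seed = 3)
    expect_lt(sqrt(mean((predict(m, d$X) - d$y)^2)), 0.05)
  }
})

test_that("LM accepted-step SSE sequence is non-increasing", {
  d <- linear_data(60, seed = 4, noise = 0.5)
  m <- train_lm_ann(d$X, d$y, hidden_nodes = 5, seed = 2)
  expect_true(all(diff(m$fit$sse_trace) <= 1e-9))
  # SCG: final SSE no worse than the first epoch
  m2 <- train_scg_ann(d$X, d$y, hidden_nodes = 5, seed = 2)
  tr <- m2$fit$sse_trace
  expect_lte(tr[length(tr)], tr[1])
})

test_that("Bayesian regularization keeps alpha and beta positive", {
  d <- linear_data(60, seed = 7, noise = 1)
  m <- train_br_ann(d$X, d$y, hidden_nodes = 6, seed = 1)
  ht <- m$fit$hyper_trace
  expect_gt(nrow(ht), 0)
  expect_true(all(ht[, "alpha"] > 0))
  expect_true(all(ht[, "beta"] > 0))
})

test_that("regularization helps on pure-noise targets more often than not", {
  wins <- 0L
  for (seed in 1:20) {
    set.seed(seed + 400)
    X <- matrix(runif(50, -2, 2), ncol = 1)
    y <- rnorm(50)
    Xte <- matrix(runif(200, -2, 2), ncol = 1)
    yte <- rnorm(200)
    mb <- train_br_ann(X, y, hidden_nodes = 6, seed = seed)
    ml <- train_lm_ann(X, y, hidden_nodes = 6, seed = seed)
    rb <- sqrt(mean((predict(mb, Xte) - yte)^2))
    rl <- sqrt(mean((predict(ml, Xte) - yte)^2))
    if (rb <= rl) wins <- wins + 1L
  }
  expect_gte(wins, 12L)  # >= 60% of 20 seeds
})

test_that("SVR cost follows the IQR rule and handles degenerate targets", {
  expect_equal(svr_cost(c(0, 1, 2, 3.698, 4)), 2, tolerance = 1e-9)
  expect_warning(c1 <- svr_cost(rep(5, 10)), "IQR")
  expect_equal(c1, 1)
  d <- linear_data(50, seed = 3)
  m <- train_svr(d$X, d$y, epsilon = 0.01)
  expect_lt(mean(abs(predict(m, d$X) - d$y)), 0.05)
  # flat target: predictions inside the epsilon tube around the value
  yc <- rep(2.5, 50)
  mc <- suppressWarnings(train_svr(d$X, yc, epsilon = 0.1))
  expect_lt(max(abs(predict(mc, d$X) - 2.5)), 0.1)
})

test_that("random forest respects leaf-mean averaging bounds", {
  set.seed(9)
  X <- matrix(runif(200, -1, 1), ncol = 1)
  y <- ifelse(X[, 1] > 0, 4, 0) # step of height 4
  m <- suppressWarnings(train_rf(X, y, n_trees = 100, seed = 11))
  pr <- predict(m, X)
  expect_true(all(pr >= min(y) - 1e-9 & pr <= max(y) + 1e-9))
  expect_lt(sqrt(mean((pr - y)^2)), 0.2 * 4)
  mc <- suppressWarnings(train_rf(X, rep(1.5, 200), n_trees = 20, seed = 1))
  expect_equal(unique(predict(mc, X)), 1.5)
  expect_error(train_rf(X[1:3, , drop = FALSE], y[1:3]), "at least 5")
})

test_that("predictions are deterministic and row-order equivariant", {
  d <- linear_data(60, seed = 5, noise = 0.3)
  Xn <- matrix(seq(-2, 2, length.out = 11), ncol = 1)
  for (arch in architectures()) {
    m <- train_regressor(arch, d$X, d$y, seed = 8)
    p1 <- predict(m, Xn)
    expect_true(all(is.finite(p1)))
    expect_identical(p1, predict(m, Xn))
    perm <- sample(seq_len(nrow(Xn)))
    expect_equal(predict(m, Xn[perm, , drop = FALSE]), p1[perm],
                 tolerance = 1e-12)
    # refit with the same seed is identical
    m2 <- train_regressor(arch, d$X, d$y, seed = 8)
    expect_equal(predict(m2, Xn), p1, tolerance = 1e-12)
  }
})

test_that("training-row standardization does not leak across a reshuffle", {
  # full-batch LM is order-independent in exact arithmetic; its iterative
  # accept/reject path amplifies floating-point summation reordering, so
  # the check uses a convergent (noiseless) fit where the data pin the
  # function. SVR (SMO working-set order) and RF (bootstrap indexing) are
  # genuinely order-dependent and are covered by fixed-seed determinism.
  d <- linear_data(50, seed = 6)
  Xn <- matrix(seq(-1.5, 1.5, length.out = 9), ncol = 1)
  m1 <- train_lm_ann(d$X, d$y, hidden_nodes = 4, seed = 3)
  set.seed(1)
  perm <- sample(50)
  m2 <- train_lm_ann(d$X[perm, , drop = FALSE], d$y[perm],
                     hidden_nodes = 4, seed = 3)
  expect_equal(predict(m2, Xn), predict(m1, Xn), tolerance = 1e-4)
  # the standardization statistics themselves are exactly order-invariant
  expect_equal(m2$x_center, m1$x_center)
  expect_equal(m2$y_scale, m1$y_scale)
})

test_that("hyperparameter search minimizes training error with ties down", {
  d <- linear_data(60, seed = 12, noise = 0.1)
  s <- select_hyperparameters(d$X, d$y, "svr", grid = 0.3)
  expect_equal(s$value, 0.3)
  # a wide epsilon tube cannot track the target; the narrow one wins
  s <- select_hyperparameters(d$X, d$y, "svr", grid = c(0.01, 1.0))
  expect_equal(s$value, 0.01)
  expect_lt(s$errors[1], s$errors[2])
  s2 <- select_hyperparameters(d$X, d$y, "svr", grid = c(0.01, 1.0))
  expect_identical(s, s2)
  expect_error(select_hyperparameters(d$X, d$y, "svr", grid = numeric(0)),
               "empty")
})

test_that("JSON model round trips reproduce live predictions", {
  d <- linear_data(40, seed = 13, noise = 0.3)
  Xn <- matrix(seq(-1.8, 1.8, length.out = 13), ncol = 1)
  path <- withr::local_tempfile(fileext = ".json")
  for (arch in c("lm_ann", "svr", "rf")) {
    m <- train_regressor(arch, d$X, d$y, seed = 4)
    write_model(m, path)
    m2 <- read_model(path)
    expect_equal(predict(m2, Xn), unname(predict(m, Xn)), tolerance = 1e-8)
  }
})
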