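test_that("log2 target transform and its inverse", {
  expect_equal(drop(target_transform(0.5, 0.0078125)), c(-1, -7),
               ignore_attr = TRUE)
  lv <- concentration_levels()
  y <- target_transform(lv, rev(lv))
  back <- inverse_target_transform(y)
  expect_equal(back[, 1], lv, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back[, 2], rev(lv), tolerance = 1e-12, ignore_attr = TRUE)
  # -3 on the log2 scale is 0.125 % = 1250 ppm; -1 is 5000 ppm
  expect_equal(drop(inverse_target_transform(c(-3, -1))) * 1e4, c(1250, 5000),
               ignore_attr = TRUE)
  expect_error(target_transform(0, 0.1), "positive")
  expect_error(target_transform(0.1, -1), "positive")
})

test_that("split rule: stated sizes and the partition property", {
  s <- split_dataset(169, seed = 4L)
  expect_length(s$learning, 119)
  expect_length(s$test, 25)
  expect_length(s$validation, 25)
  s20 <- split_dataset(20, seed = 4L)
  expect_equal(lengths(s20[c("learning", "test", "validation")]),
               c(learning = 14L, test = 3L, validation = 3L))
  for (n in c(3, 7, 50, 169)) for (seed in c(1, 99)) {
    sp <- split_dataset(n, seed = seed)
    all_idx <- c(sp$learning, sp$test, sp$validation)
    expect_equal(sort(all_idx), seq_len(n))   # disjoint and covering
  }
  expect_identical(split_dataset(169, seed = 8L), split_dataset(169, seed = 8L))
  expect_error(split_dataset(2), "n >= 3")
  expect_error(split_dataset(10, ratios = c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("the four hidden activations and their derivatives", {
  expect_equal(activation("log", 0), 0.5)
  expect_equal(activation("tanh", 0), 0)
  x <- c(-2.5, 0, 1.7)
  expect_identical(activation("lin", x), x)
  expect_equal(activation("exp", x), exp(-x))    # e^0 = 1 at x = 0
  expect_true(all(diff(activation("exp", c(-1, 0, 2))) < 0))
  expect_equal(activation("Tanh", 1), tanh(1))   # names are case-insensitive
  expect_error(activation("relu", 1), "unknown")
  # derivatives vs central finite differences
  h <- 1e-6
  for (a in c("lin", "log", "exp", "tanh"))
    expect_equal(activation_deriv(a, x),
                 (activation(a, x + h) - activation(a, x - h)) / (2 * h),
                 tolerance = 1e-6)
})

test_that("analytic network gradient matches finite differences", {
  set.seed(55)
  X <- matrix(rnorm(10 * 8), 10, 8)
  Tm <- matrix(rnorm(10 * 2), 10, 2)
  for (act in c("lin", "log", "exp", "tanh")) {
    par <- rnorm(thermospline:::n_params(8, 3, 2), sd = 0.3)
    g <- thermospline:::mlp_grad(par, X, Tm, 3L, act)
    num <- vapply(seq_along(par), function(i) {
      e <- numeric(length(par)); e[i] <- 1e-6
      (thermospline:::mlp_loss(par + e, X, Tm, 3L, act) -
         thermospline:::mlp_loss(par - e, X, Tm, 3L, act)) / 2e-6
    }, numeric(1))
    expect_equal(g, num, tolerance = 1e-5)
  }
})

test_that("a linear problem is solved exactly by a linear network", {
  set.seed(66)
  X <- matrix(rnorm(60 * 8), 60, 8)
  A <- matrix(rnorm(16), 8, 2)
  Y <- X %*% A + matrix(c(0.3, -0.2), 60, 2, byrow = TRUE)
  sp <- split_dataset(60, seed = 6L)
  m <- suppressWarnings(train_mlp(X, Y, sp, hidden_size = 3L,
                                  activation = "lin", seed = 6L, maxit = 2000L))
  expect_lt(m$errors$learning, 1e-10)
})

test_that("training is deterministic and reduces the learning loss", {
  set.seed(77)
  X <- matrix(rnorm(40 * 8), 40, 8)
  Y <- cbind(tanh(X[, 1] + 0.5 * X[, 2]), X[, 3]^2 / 3)
  sp <- split_dataset(40, seed = 7L)
  m1 <- suppressWarnings(train_mlp(X, Y, sp, 4L, "tanh", seed = 123L, maxit = 100L))
  m2 <- suppressWarnings(train_mlp(X, Y, sp, 4L, "tanh", seed = 123L, maxit = 100L))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$b2, m2$b2)
  expect_lte(m1$final_learning_loss, m1$initial_loss)
  m3 <- suppressWarnings(train_mlp(X, Y, sp, 4L, "tanh", seed = 124L, maxit = 100L))
  expect_false(identical(m1$W1, m3$W1))
})

test_that("prediction scales back to concentrations; scaler round trip", {
  set.seed(88)
  X <- matrix(rnorm(30 * 8), 30, 8)
  Y <- target_transform(2^runif(30, -7, -1), 2^runif(30, -7, -1))
  sp <- split_dataset(30, seed = 8L)
  m <- suppressWarnings(train_mlp(X, Y, sp, 3L, "tanh", seed = 8L, maxit = 50L))
  pred <- predict(m, X)
  expect_equal(nrow(pred), 30)
  expect_true(all(is.finite(as.matrix(pred))))
  expect_equal(pred$c_ethanol_ppm, pred$c_ethanol_pct * 1e4)
  expect_equal(pred$c_ethanol_pct, 2^pred$log2_ethanol)
  # feature standardization round trip
  Xs <- thermospline:::scale_features(X, m$x_center, m$x_scale)
  back <- sweep(sweep(Xs, 2, m$x_scale, "*"), 2, m$x_center, "+")
  expect_equal(back, X, tolerance = 1e-12)
  expect_error(predict(m, X[, 1:5]), "8 feature columns")
})

test_that("grid enumeration and the shape of the search report", {
  expect_equal(nrow(grid_candidates(2:9, c("lin", "log", "exp", "tanh"), 1000L)),
               32000)
  expect_equal(nrow(grid_candidates(4L, "tanh", 1L)), 1)
  set.seed(99)
  X <- matrix(rnorm(30 * 8), 30, 8)
  Y <- cbind(X[, 1], X[, 2] + 0.1 * X[, 3])
  sp <- split_dataset(30, seed = 9L)
  gs <- grid_search(X, Y, sp, hidden_sizes = 2:3,
                    activations = c("lin", "tanh"), restarts = 2L,
                    seed = 9L, maxit = 40L)
  expect_equal(nrow(gs$report), 4)            # one row per grid cell
  expect_equal(nrow(gs$candidates), 8)
  expect_true(all(gs$report$n_restarts == 2))
  # selected model has the minimal validation error among candidates
  expect_equal(gs$best_cell$validation_err,
               min(gs$candidates$validation_err, na.rm = TRUE))
  gs2 <- grid_search(X, Y, sp, hidden_sizes = 2:3,
                     activations = c("lin", "tanh"), restarts = 2L,
                     seed = 9L, maxit = 40L)
  expect_identical(gs$best_model$W1, gs2$best_model$W1)  # seeded determinism
  expect_equal(gs$report, gs2$report)
})
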