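# batch loss the gradient is taken of: E = mean((yhat - y)^2) / 2
batch_loss <- function(state, X, y) mean((nn_forward(state, X) - y)^2) / 2

# central finite-difference gradient for one named parameter element
fd_grad <- function(state, X, y, field, idx, h = 1e-6) {
  up <- state; up[[field]][idx] <- up[[field]][idx] + h
  dn <- state; dn[[field]][idx] <- dn[[field]][idx] - h
  (batch_loss(up, X, y) - batch_loss(dn, X, y)) / (2 * h)
}

test_that("initialisation is deterministic with the documented shapes", {
  a <- init_network(6, 5, seed = 42)
  b <- init_network(6, 5, seed = 42)
  expect_identical(a, b)
  expect_equal(dim(a$W1), c(5, 6))
  n_params <- length(a$W1) + length(a$b1) + length(a$w2) + length(a$b2)
  expect_equal(n_params, 41)  # the 6-5-1 architecture
  expect_true(all(abs(c(a$W1, a$b1, a$w2, a$b2)) <= 0.3))
  expect_true(all(a$prev$W1 == 0) && all(a$prev$b1 == 0) &&
                all(a$prev$w2 == 0) && a$prev$b2 == 0)
  expect_false(identical(a, init_network(6, 5, seed = 43)))
})

test_that("forward pass evaluates the sigmoid-hidden / linear-output map", {
  net <- init_network(3, 2, seed = 1)
  # zero output layer -> zero output regardless of input
  net0 <- net; net0$w2 <- c(0, 0); net0$b2 <- 0
  expect_equal(nn_forward(net0, c(1, -2, 3)), 0)
  # hand-set 2-2-1 weights against by-hand arithmetic
  net2 <- init_network(2, 2, seed = 1)
  net2$W1 <- matrix(c(0.5, -1, 0.25, 2), 2, 2)  # rows = hidden units
  net2$b1 <- c(0.1, -0.2)
  net2$w2 <- c(1.5, -0.5)
  net2$b2 <- 0.3
  x <- c(0.4, -0.6)
  h1 <- 1 / (1 + exp(-(0.5 * 0.4 + 0.25 * (-0.6) + 0.1)))
  h2 <- 1 / (1 + exp(-(-1 * 0.4 + 2 * (-0.6) - 0.2)))
  expect_equal(nn_forward(net2, x), 1.5 * h1 - 0.5 * h2 + 0.3,
               tolerance = 1e-12)
  # outputs stay finite even for extreme inputs (bounded hidden layer)
  expect_true(is.finite(nn_forward(net2, c(1e6, -1e6))))
  expect_error(nn_forward(net2, c(1, 2, 3)), "shape mismatch")
})

test_that("backprop gradients match central finite differences", {
  withr::with_seed(7, {
    for (rep in 1:3) {
      net <- init_network(3, 4, seed = rep)
      X <- matrix(rnorm(5 * 3), 5, 3)
      y <- rnorm(5)
      # mu = 1, alpha = 0 makes the applied update equal minus the gradient
      cfg <- train_config(learning_rate = 1, momentum = 0, max_epochs = 1)
      new <- train_step(net, X, y, cfg)$state
      for (field in c("W1", "b1", "w2", "b2")) {
        analytic <- net[[field]] - new[[field]]
        for (idx in seq_along(net[[field]])) {
          num <- fd_grad(net, X, y, field, idx)
          denom <- max(abs(num), 1e-8)
          expect_lt(abs(analytic[idx] - num) / denom, 1e-6)
        }
      }
    }
  })
})

test_that("zero learning rate is a fixed point; zero momentum is plain descent", {
  net <- init_network(2, 3, seed = 5)
  X <- withr::with_seed(6, matrix(rnorm(8), 4, 2))
  y <- c(0.2, 0.4, 0.6, 0.8)
  frozen <- train_step(net, X, y,
                       train_config(learning_rate = 0, momentum = 0,
                                    max_epochs = 1))$state
  expect_equal(frozen$W1, net$W1)
  expect_equal(frozen$b1, net$b1)
  expect_equal(frozen$w2, net$w2)
  expect_equal(frozen$b2, net$b2)
  # alpha = 0: two successive steps differ from one with momentum
  cfg_gd <- train_config(learning_rate = 0.5, momentum = 0, max_epochs = 1)
  s1 <- train_step(net, X, y, cfg_gd)$state
  # plain descent: update exactly -mu * gradient (gradient from mu=1 step)
  g <- train_step(net, X, y, train_config(1, 0, 1))$state
  expect_equal(s1$W1 - net$W1, -0.5 * (net$W1 - g$W1), tolerance = 1e-12)
})

test_that("momentum adds the previous update to the current step", {
  net <- init_network(2, 2, seed = 9)
  X <- withr::with_seed(10, matrix(rnorm(6), 3, 2))
  y <- c(0.1, 0.5, 0.9)
  cfg <- train_config(learning_rate = 0.3, momentum = 0.6, max_epochs = 1)
  s1 <- train_step(net, X, y, cfg)
  s2 <- train_step(s1$state, X, y, cfg)
  # recompute the second update from its parts
  grad_state <- train_step(s1$state, X, y, train_config(1, 0, 1))$state
  grad_W1 <- s1$state$W1 - grad_state$W1
  expected <- -0.3 * grad_W1 + 0.6 * s1$state$prev$W1
  expect_equal(s2$state$W1 - s1$state$W1, expected, tolerance = 1e-12)
  expect_equal(s2$state$prev$W1, expected, tolerance = 1e-12)
})

test_that("training converges on a noiseless linear problem", {
  withr::with_seed(11, {
    X <- matrix(rnorm(30 * 2), 30, 2)
    y_raw <- 0.3 * X[, 1] - 0.2 * X[, 2]
    y <- 0.5 + 0.3 * (y_raw - mean(y_raw)) / sd(y_raw)  # keep in (0.1, 0.9)
    net <- init_network(2, 3, seed = 2)
    initial_mse <- mean((nn_forward(net, X) - y)^2)
    res <- train_network(net, X[1:24, ], y[1:24], X[25:30, ], y[25:30],
                         train_config(1, 0.9, 2000, patience = Inf))
    expect_lt(min(res$train_mse), 1e-4 * initial_mse)
  })
})

test_that("early stopping returns the argmin-validation state and honours patience", {
  withr::with_seed(12, {
    X <- matrix(rnorm(20 * 2), 20, 2)
    y <- 0.5 + 0.2 * X[, 1] + withr::with_seed(1, rnorm(20, sd = 0.05))
    net <- init_network(2, 4, seed = 3)
    cfg <- train_config(0.7, 0.2, 400, patience = Inf)
    res <- train_network(net, X[1:14, ], y[1:14], X[15:20, ], y[15:20], cfg)
    expect_equal(res$stop_epoch, 400)  # patience Inf -> runs to max_epochs
    # returned state's validation MSE <= every logged epoch's
    best_mse <- mean((nn_forward(res$state, X[15:20, ]) - y[15:20])^2)
    expect_lte(best_mse, min(res$val_mse) + 1e-12)
    expect_equal(res$best_epoch, which.min(res$val_mse))
    # finite patience can only stop at or before max_epochs
    res2 <- train_network(net, X[1:14, ], y[1:14], X[15:20, ], y[15:20],
                          train_config(0.7, 0.2, 400, patience = 10))
    expect_lte(res2$stop_epoch, 400)
    expect_equal(res2$best_epoch, which.min(res2$val_mse))
  })
})

test_that("scaling round-trips and prediction recovers noiseless targets", {
  withr::with_seed(14, {
    X <- matrix(rnorm(40 * 2), 40, 2)
    y <- 2e-7 + 1e-7 * X[, 1] + 0.5e-7 * X[, 2]
    y <- y - min(y) + 1e-7  # positive concentrations
    scaling <- fit_nn_scaling(X, y)
    expect_equal(unscale_targets(scaling, scale_targets(scaling, y)), y,
                 tolerance = 1e-12)
    expect_equal(range(scale_targets(scaling, y)), c(0.1, 0.9),
                 tolerance = 1e-12)
    Xs <- scale_inputs(scaling, X)
    expect_equal(colMeans(Xs), c(0, 0), tolerance = 1e-12,
                 ignore_attr = TRUE)
    net <- init_network(2, 8, seed = 4)
    res <- train_network(net, Xs[1:32, ], scale_targets(scaling, y)[1:32],
                         Xs[33:40, ], scale_targets(scaling, y)[33:40],
                         train_config(1, 0.9, 12000, patience = Inf))
    pred <- nn_predict(res$state, scaling, X[1:32, ])
    expect_true(all(abs(pred - y[1:32]) / y[1:32] < 0.01))
  })
})

test_that("constant networks predict the inverse-scaled bias", {
  net <- init_network(2, 3, seed = 6)
  net$w2 <- rep(0, 3); net$b2 <- 0.5
  scaling <- fit_nn_scaling(matrix(rnorm(10), 5, 2), 1:5 * 1e-7)
  pred <- nn_predict(net, scaling, matrix(rnorm(6), 3, 2))
  expect_equal(pred, rep(unscale_targets(scaling, 0.5), 3))
})

test_that("serialised networks reload exactly", {
  net <- init_network(3, 4, seed = 20)
  scaling <- fit_nn_scaling(withr::with_seed(21, matrix(rnorm(15), 5, 3)),
                            c(1, 2, 3, 4, 5) * 1e-7)
  path <- withr::local_tempfile(fileext = ".txt")
  write_network(net, scaling, path)
  back <- read_network(path)
  X <- withr::with_seed(22, matrix(rnorm(9), 3, 3))
  expect_identical(nn_predict(net, scaling, X),
                   nn_predict(back$state, back$scaling, X))
  expect_identical(back$state$W1, net$W1)
})
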