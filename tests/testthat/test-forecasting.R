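test_that("regressor construction unrolls the lag definition", {
  reg <- build_regressors(c(1, 2, 3, 4), c(0, 0, 0, 0), c(1, 2, 3, 4),
                          P = 2, tau = 1)
  expect_equal(reg$z, rbind(c(2, 1, 0, 0), c(3, 2, 0, 0)))
  expect_equal(reg$targets, rbind(3, 4))
  reg <- build_regressors(c(1, 2, 3, 4), c(0, 0, 0, 0), c(1, 2, 3, 4),
                          P = 2, tau = 2)
  expect_equal(reg$z, rbind(c(2, 1, 0, 0)))
  expect_equal(reg$targets, rbind(c(3, 4)))
  expect_error(build_regressors(1:4, 1:4, 1:4, P = 3, tau = 2), "too short")
  expect_error(build_regressors(1:4, 1:3, 1:4, P = 1, tau = 1), "length")
})

test_that("row count and row contents match brute-force enumeration", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    P <- sample(1:8, 1)
    tau <- sample(1:6, 1)
    if (n < P + tau) next
    c_L <- rnorm(n); c_H <- rnorm(n); x <- rnorm(n)
    reg <- build_regressors(c_L, c_H, x, P, tau)
    expect_equal(nrow(reg$z), n - P - tau + 1)
    expect_equal(ncol(reg$z), 2 * P)
    # check an arbitrary row against the definition
    r <- sample(nrow(reg$z), 1)
    nn <- reg$row_index[r]
    expect_equal(reg$z[r, ], c(c_L[nn:(nn - P + 1)], c_H[nn:(nn - P + 1)]))
    expect_equal(reg$targets[r, ], x[nn + seq_len(tau)])
  }
})

test_that("chronological split keeps order and the 70/30 proportion", {
  fx <- generate_linear_mimo_fixture(100, 2, 2, seed = 1)
  sp <- split_regressors(fx$reg, 0.7)
  expect_equal(nrow(sp$train$z), 70)
  expect_equal(nrow(sp$test$z), 30)
  expect_lt(max(sp$train$row_index), min(sp$test$row_index))
  fx10 <- generate_linear_mimo_fixture(10, 2, 2, seed = 1)
  sp10 <- split_regressors(fx10$reg, 0.7)
  expect_equal(nrow(sp10$train$z), 7)
  expect_equal(nrow(sp10$test$z), 3)
  expect_error(split_regressors(fx$reg, 1.2), "between 0 and 1")
})

test_that("least-squares fit recovers a noiseless linear map exactly", {
  fx <- generate_linear_mimo_fixture(200, 3, 2, noise_sd = 0, seed = 5)
  fit <- fit_mimo_ar(fx$reg)
  expect_equal(dim(fit$beta), c(2, 6))
  expect_lt(max(abs(fit$beta - fx$beta_true)), 1e-8)
  # in-sample predictions reproduce the targets
  pred <- predict(fit, fx$reg)
  expect_lt(max(abs(pred - fx$reg$targets)), 1e-8)
  # zero targets give the zero (minimum-norm) solution
  reg0 <- fx$reg
  reg0$targets[] <- 0
  expect_equal(fit_mimo_ar(reg0)$beta, matrix(0, 2, 6))
})

test_that("rank-deficient regressors fit via pseudoinverse like a ridge oracle", {
  fx <- generate_linear_mimo_fixture(50, 2, 2, noise_sd = 0.5, seed = 8)
  reg <- fx$reg
  reg$z[, 4] <- reg$z[, 1]              # duplicated column
  fit <- fit_mimo_ar(reg)
  resid_pkg <- reg$targets - predict(fit, reg)
  beta_oracle <- ridge_ls_fit(reg$z, reg$targets)
  resid_oracle <- reg$targets - reg$z %*% beta_oracle
  expect_lt(max(abs(resid_pkg - resid_oracle)), 1e-6)
  # prediction refuses mismatched shapes
  expect_error(predict(fit, matrix(0, 3, 5)), "expects 4")
})

test_that("coefficient error shrinks with sample size under noise", {
  rmse_beta <- function(rows, seed) {
    fx <- generate_linear_mimo_fixture(rows, 3, 2, noise_sd = 1, seed = seed)
    sqrt(mean((fit_mimo_ar(fx$reg)$beta - fx$beta_true)^2))
  }
  med <- vapply(c(100, 400, 1600), function(rows)
    stats::median(vapply(1:3, function(s) rmse_beta(rows, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("perceptron initialisation follows the log2 width rule, seeded", {
  expect_equal(init_mlp(4, 512, 2, seed = 1)$Q, 9L)
  expect_equal(init_mlp(4, 547, 2, seed = 1)$Q, 9L)   # round(log2(547)) = 9
  expect_equal(init_mlp(4, 2, 2, seed = 1)$Q, 1L)
  m1 <- init_mlp(4, 100, 3, seed = 99)
  m2 <- init_mlp(4, 100, 3, seed = 99)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$b, m2$b)
  m3 <- init_mlp(4, 100, 3, seed = 100)
  expect_false(identical(m1$w, m3$w))
})

test_that("perceptron forward pass matches the loop oracle and its symmetries", {
  set.seed(17)
  w <- matrix(rnorm(6), 2, 3)
  b <- matrix(rnorm(6), 3, 2)
  z <- matrix(rnorm(10), 5, 2)
  model <- structure(list(w = w, b = b, Q = 3, center = NULL, scale = NULL),
                     class = "mimo_mlp")
  expect_lt(max(abs(predict(model, z) - naive_mlp_forward(w, b, z))), 1e-12)
  # all-zero weights: hidden all sigmoid(0) = 0.5, outputs zero
  zero_model <- structure(list(w = w * 0, b = b * 0, Q = 3, center = NULL,
                               scale = NULL), class = "mimo_mlp")
  expect_equal(predict(zero_model, z), matrix(0, 5, 2))
  # permuting hidden units with their weights leaves predictions unchanged
  perm <- c(3, 1, 2)
  perm_model <- structure(list(w = w[, perm], b = b[perm, ], Q = 3,
                               center = NULL, scale = NULL),
                          class = "mimo_mlp")
  expect_equal(predict(perm_model, z), predict(model, z))
})

test_that("Levenberg-Marquardt training descends and is reproducible", {
  fx <- generate_linear_mimo_fixture(60, 2, 2, noise_sd = 0, seed = 3)
  fit <- train_mlp_lm(fx$reg, epochs = 200, runs = 3, seed = 7, Q = 5)
  # accepted-step error curves never increase
  for (cv in fit$report$curves) {
    if (length(cv) >= 2) expect_true(all(diff(cv) <= 1e-12))
  }
  # a linear map on bounded inputs is representable to small error
  expect_lt(min(fit$report$final_mse), 1e-4)
  # reproducibility under identical seeds
  fit2 <- train_mlp_lm(fx$reg, epochs = 200, runs = 3, seed = 7, Q = 5)
  expect_identical(fit$w, fit2$w)
  expect_identical(fit$b, fit2$b)
  # trained model predicts the held-in targets closely
  expect_lt(mean((predict(fit, fx$reg) - fx$reg$targets)^2), 1e-3)
})
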