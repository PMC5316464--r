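test_that("skill metrics reproduce hand-computed examples", {
  x <- c(1, 2, 3)
  expect_equal(nrmse(x, x), 0)
  expect_equal(mnse(x, x), 1)
  expect_equal(mia(x, x), 1)
  expect_equal(nrmse(c(2, 2), c(1, 3)), 0.5)           # sqrt(1)/2
  expect_equal(sae_sad(x, c(1, 1, 3)), list(SAE = 1, SAD = 2))
  expect_equal(mnse(x, c(1, 1, 3)), 0.5)               # 1 - 1/2
  # mean predictor: SAE = SAD so mNSE = 0
  expect_equal(mnse(x, rep(2, 3)), 0)
  # second mIA branch: SAE = 8, SAD = 2 -> 2*2/8 - 1
  expect_equal(mia(x, c(5, 2, -1)), -0.5)
  expect_error(nrmse(c(-1, 1), c(0, 0)), "mean")
  expect_error(mnse(c(2, 2), c(1, 3)), "constant")
  expect_error(mia(c(2, 2), c(1, 3)), "constant")
})

test_that("the two mIA branches meet continuously at SAE = 2 SAD", {
  x <- c(1, 2, 3)                       # SAD = 2
  pred <- c(1 - 2, 2, 3 + 2)            # SAE = 4 = 2 SAD exactly
  expect_equal(mia(x, pred), 0)
  eps <- 1e-9
  expect_lt(abs(mia(x, c(1 - 2 - eps, 2, 3 + 2))), 1e-8)
  expect_lt(abs(mia(x, c(1 - 2 + eps, 2, 3 + 2))), 1e-8)
})

test_that("metrics respect their invariances and monotonicity", {
  set.seed(21)
  x <- rnorm(30, 100, 10)
  p <- x + rnorm(30)
  # positive scaling leaves all three unchanged
  expect_equal(nrmse(3 * x, 3 * p), nrmse(x, p))
  expect_equal(mnse(3 * x, 3 * p), mnse(x, p))
  expect_equal(mia(3 * x, 3 * p), mia(x, p))
  # common shift leaves the absolute-value scores unchanged
  expect_equal(mnse(x + 50, p + 50), mnse(x, p))
  expect_equal(mia(x + 50, p + 50), mia(x, p))
  # mNSE and mIA never exceed 1; 1 only for perfection
  expect_lt(mnse(x, p), 1)
  expect_lt(mia(x, p), 1)
  expect_gt(mia(x, p), -1)
  # worsening a single prediction never improves the scores
  worse <- p
  worse[5] <- worse[5] + 10 * sign(worse[5] - x[5] + 1e-9)
  expect_lte(mnse(x, worse), mnse(x, p))
  expect_lte(mia(x, worse), mia(x, p))
})

test_that("per-horizon table computes the labelled aggregations", {
  set.seed(4)
  obs <- matrix(rnorm(40 * 14, 100, 10), 40, 14)
  pred <- obs + matrix(rnorm(40 * 14), 40, 14)
  hm <- evaluate_horizons(obs, pred)
  expect_equal(nrow(hm$per_horizon), 14)
  labs <- hm$summary$label
  expect_setequal(labs, c("Min", "Max", "Mean 1-8", "Mean 1-13", "Mean 1-14"))
  expect_equal(hm$summary$mnse[labs == "Mean 1-8"],
               mean(hm$per_horizon$mnse[1:8]), tolerance = 1e-12)
  expect_equal(hm$summary$nrmse[labs == "Mean 1-13"],
               mean(hm$per_horizon$nrmse[1:13]), tolerance = 1e-12)
  expect_equal(hm$summary$mia[labs == "Min"], min(hm$per_horizon$mia))
  # a perfect forecast scores 1/1/0 everywhere
  hp <- evaluate_horizons(obs, obs)
  expect_true(all(hp$per_horizon$mnse == 1))
  expect_true(all(hp$per_horizon$mia == 1))
  expect_true(all(hp$per_horizon$nrmse == 0))
  expect_error(evaluate_horizons(obs, pred[, 1:3]), "shape")
})

test_that("formatted table round-trips through CSV at reporting precision", {
  set.seed(6)
  obs <- matrix(rnorm(30 * 8, 100, 10), 30, 8)
  pred <- obs + matrix(rnorm(30 * 8), 30, 8)
  hm <- evaluate_horizons(obs, pred)
  tab <- format_horizon_metrics(hm, percent = TRUE, digits = 6)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$nrmse, tab$nrmse)
  expect_equal(back$mnse, tab$mnse)
  expect_equal(back$horizon, tab$horizon)
  unlink(f)
})

test_that("periodogram matches the direct DFT oracle and finds pure tones", {
  set.seed(14)
  x <- rnorm(128, 50, 5)
  sp <- fourier_power_spectrum(x)
  ks <- c(1, 5, 20, 63)
  for (k in ks) {
    expect_equal(sp$table$power[sp$table$k == k], naive_dft_power(x, k),
                 tolerance = 1e-8)
  }
  # pure 26-sample tone over 520 samples peaks at bin 20 -> period 26
  t <- 1:520
  sp26 <- fourier_power_spectrum(sin(2 * pi * t / 26))
  expect_equal(sp26$dominant_period, 26L)
  expect_true(sp26$dominant_significant)
  expect_equal(select_lag_order(sp26), 26L)
  # constant series: zero power, nothing significant, no selectable peak
  spc <- fourier_power_spectrum(rep(5, 64))
  expect_false(any(spc$table$significant))
  expect_error(select_lag_order(spc), "peak")
  expect_error(fourier_power_spectrum(rnorm(10)), "too short")
})

test_that("lag order follows the highest-power peak", {
  t <- 1:520
  # the period-17 tone has the larger amplitude, so it must win
  x <- 3 * sin(2 * pi * t / 17.33) + 1 * sin(2 * pi * t / 26)
  sp <- fourier_power_spectrum(x)
  expect_equal(select_lag_order(sp), 17L)  # round(520/30)
})

test_that("relative gain conventions behave as defined", {
  expect_equal(relative_gain(c(1, 2), c(1, 2)), 0)
  expect_equal(relative_gain(c(2, 2), c(1, 1)), 100)
  # mean convention on summary-style scores
  expect_equal(relative_gain(rep(98.9, 13), rep(84.1, 13)),
               100 * (98.9 - 84.1) / 84.1, tolerance = 1e-12)
  # the two conventions differ when the baseline varies across horizons
  a <- c(2, 4); b <- c(1, 4)
  expect_equal(relative_gain(a, b, "mean"), 20)
  expect_equal(relative_gain(a, b, "per_horizon"), 50)
  expect_error(relative_gain(c(1, 2), c(0, 0)), "zero")
})
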