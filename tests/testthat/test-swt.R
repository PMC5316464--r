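test_that("filter bank has the a trous structure", {
  bank <- swt_filter_bank("db2", 3)
  expect_length(bank$low_pass[[1]], 4)
  # level-j filters hold the same 4 taps with 2^(j-1)-1 zero gaps
  expect_length(bank$low_pass[[2]], 7)
  expect_length(bank$low_pass[[3]], 13)
  expect_equal(bank$low_pass[[3]][seq(1, 13, by = 4)], bank$low_pass[[1]])
  expect_true(all(bank$low_pass[[3]][-seq(1, 13, by = 4)] == 0))
  # analysis normalisation: taps sum to 1 (preserves constants per level)
  expect_equal(sum(bank$low_pass[[1]]), 1)
  expect_equal(sum(bank$high_pass[[1]]), 0)
  # quadrature-mirror relation between the pairs
  h <- bank$low_pass[[1]]
  g <- bank$high_pass[[1]]
  expect_equal(g, (-1)^(0:3) * rev(h))
  expect_error(swt_filter_bank("sym4", 2), "db1, db2, db3")
})

test_that("decomposition matches a direct convolution oracle", {
  set.seed(11)
  x <- rnorm(32)
  bank <- swt_filter_bank("db2", 2)
  dec <- swt_decompose(x, bank)
  expect_equal(dec$a[[1]], naive_circ_conv(x, bank$low_pass[[1]]))
  expect_equal(dec$d[[1]], naive_circ_conv(x, bank$high_pass[[1]]))
  expect_equal(dec$a[[2]], naive_circ_conv(dec$a[[1]], bank$low_pass[[2]]))
  expect_equal(dec$d[[2]], naive_circ_conv(dec$a[[1]], bank$high_pass[[2]]))
})

test_that("analysis plus synthesis reconstructs exactly", {
  for (n in c(8, 64, 512)) {
    for (wavelet in c("db1", "db2", "db3")) {
      set.seed(n)
      x <- rnorm(n, 100, 10)
      bank <- swt_filter_bank(wavelet, 3)
      dec <- swt_decompose(x, bank)
      expect_lt(max(abs(iswt_reconstruct(dec, bank) - x)), 1e-8)
    }
  }
  # a Kronecker delta round-trips too (impulse response sanity)
  delta <- c(1, numeric(63))
  bank <- swt_filter_bank("db2", 3)
  dec <- swt_decompose(delta, bank)
  expect_lt(max(abs(iswt_reconstruct(dec, bank) - delta)), 1e-10)
})

test_that("subband reconstructions are linear and sum to the signal", {
  set.seed(5)
  x <- rnorm(64)
  bank <- swt_filter_bank("db2", 3)
  dec <- swt_decompose(x, bank)
  approx_part <- iswt_reconstruct(dec, bank, keep_approx = TRUE,
                                  keep_details = integer(0))
  detail_parts <- lapply(1:3, function(j)
    iswt_reconstruct(dec, bank, keep_approx = FALSE, keep_details = j))
  expect_lt(max(abs(approx_part + Reduce(`+`, detail_parts) - x)), 1e-8)
  nothing <- iswt_reconstruct(dec, bank, keep_approx = FALSE,
                              keep_details = integer(0))
  expect_equal(nothing, numeric(64))
  # mismatched bank is refused
  expect_error(iswt_reconstruct(dec, swt_filter_bank("db2", 2)), "match")
})

test_that("the undecimated transform is shift-covariant", {
  set.seed(9)
  x <- rnorm(64)
  bank <- swt_filter_bank("db2", 3)
  dec <- swt_decompose(x, bank)
  s <- 5L
  xs <- c(x[(64 - s + 1):64], x[1:(64 - s)])  # circular shift by s
  dec_s <- swt_decompose(xs, bank)
  roll <- function(v) c(v[(64 - s + 1):64], v[1:(64 - s)])
  for (j in 1:3) {
    expect_lt(max(abs(dec_s$a[[j]] - roll(dec$a[[j]]))), 1e-8)
    expect_lt(max(abs(dec_s$d[[j]] - roll(dec$d[[j]]))), 1e-8)
  }
})

test_that("vanishing moments annihilate constants", {
  x <- rep(42, 64)
  bank <- swt_filter_bank("db2", 3)
  dec <- swt_decompose(x, bank)
  for (j in 1:3) {
    expect_lt(max(abs(dec$d[[j]])), 1e-9 * max(abs(x)))
    expect_equal(dec$a[[j]], x, tolerance = 1e-12)
  }
})

test_that("length preconditions and reflection padding work together", {
  expect_error(swt_decompose(rnorm(100), swt_filter_bank("db2", 3)),
               "multiple of 2\\^J")
  p <- pad_to_multiple(1:10, 8)
  expect_equal(p$n, 10L)
  expect_length(p$x, 16L)
  expect_equal(p$x[11:16], c(10, 9, 8, 7, 6, 5))  # mirrored tail
  expect_equal(pad_to_multiple(1:16, 8)$x, 1:16)  # already a multiple
  # component split pads internally and truncates back
  set.seed(2)
  x <- rnorm(100, 50, 5)
  sc <- swt_components(x, J = 3)
  expect_length(sc$c_L, 100L)
  expect_lt(max(abs(sc$c_L + sc$c_H - x)), 1e-8)
})

test_that("component split separates scales additively", {
  set.seed(13)
  t <- 1:512
  x <- 200 + 30 * sin(2 * pi * t / 64) + rnorm(512)
  sc <- swt_components(x, J = 3, wavelet = "db2")
  expect_lt(max(abs(sc$c_L + sc$c_H - x)), 1e-8)
  # the slow sinusoid survives in c_L; the white noise mostly moves to c_H
  expect_gt(stats::sd(sc$c_L), 10)
  expect_lt(stats::sd(sc$c_H), 2.5)
  # constant series: all low frequency
  scc <- swt_components(rep(5, 64), J = 3)
  expect_equal(scc$c_L, rep(5, 64), tolerance = 1e-10)
  expect_lt(max(abs(scc$c_H)), 1e-9 * 5)
})
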