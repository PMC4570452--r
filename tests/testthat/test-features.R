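test_that("band power matches closed-form single-bin values", {
  expect_identical(band_power(numeric(256), c(4, 8)), 0)

  # unit 10 Hz sinusoid sits exactly on one-sided bin 20: (N A / 2)^2
  x <- sin_epoch(10)
  expect_equal(band_power(x, c(8, 13)), 16384, tolerance = 1e-9)
  expect_lt(band_power(x, c(4, 8)), 1e-9)
  expect_lt(band_power(x, c(13, 30), include_upper = TRUE), 1e-9)

  expect_error(band_power(numeric(255), c(4, 8)), "contract error")
  expect_error(band_power(numeric(256), c(10, 70)), "fs/2")
})

test_that("band power equals the brute-force DFT oracle on random epochs", {
  set.seed(42)
  bands <- band_definition()
  for (i in 1:40) {
    x <- rnorm(256, sd = runif(1, 0.5, 30))
    for (b in list(c(bands$theta, 0), c(bands$alpha, 0), c(bands$beta, 1))) {
      got <- band_power(x, b[1:2], include_upper = b[3] == 1)
      want <- dft_band_power(x, b[1:2], include_upper = b[3] == 1)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("relative band power normalises and localises energy", {
  expect_equal(unname(relative_band_power(sin_epoch(10))), c(0, 100, 0),
               tolerance = 1e-6)

  # equal-amplitude tones on exact bins in each band: one third each
  x <- sin_epoch(5) + sin_epoch(10) + sin_epoch(20)
  expect_equal(unname(relative_band_power(x)), rep(100 / 3, 3),
               tolerance = 0.01)

  set.seed(7)
  for (i in 1:50) {
    r <- relative_band_power(rnorm(256))
    expect_true(all(r >= 0 & r <= 100))
    expect_equal(sum(r), 100, tolerance = 1e-9)
  }

  expect_error(relative_band_power(numeric(256)), "degenerate")
})

test_that("movement power is the population std of the axis mean", {
  n <- 256
  expect_identical(movement_power(rep(3, n), rep(-1, n), rep(10, n)), 0)

  # axis mean alternating 0, 2: population std 1
  alt <- rep(c(0, 2), n / 2)
  expect_equal(movement_power(alt, alt, alt), 1)

  set.seed(11)
  gx <- rnorm(n); gy <- rnorm(n); gz <- rnorm(n)
  mp0 <- movement_power(gx, gy, gz)
  expect_equal(movement_power(gx + 5, gy - 2, gz + 100), mp0,
               tolerance = 1e-9)                        # shift invariance
  expect_equal(movement_power(3 * gx, 3 * gy, 3 * gz), 3 * mp0,
               tolerance = 1e-9)                        # gain linearity
  expect_error(movement_power(gx, gy[-1], gz), "differ in length")
})

test_that("window averaging synchronises epochs with minute labels", {
  s <- tiny_session(2, labels = c(-1L, 1L))
  feats <- epoch_features(segment_epochs(s))
  expect_identical(nrow(feats), 60L)

  w <- average_windows(feats, s$minute_labels, "T1")
  expect_identical(nrow(w), 2L)
  expect_identical(w$label, c(-1L, 1L))
  expect_false(any(w$excluded))
  # stationary signal: window mean equals the epoch-feature mean
  expect_equal(w$mp[1], mean(feats$mp[1:30]), tolerance = 1e-12)
  expect_equal(w$rbp_alpha[2], mean(feats$rbp_alpha[31:60]),
               tolerance = 1e-12)

  expect_error(average_windows(feats, -1L, "T1"), "alignment error")
})

test_that("degenerate and dropped epochs are excluded from window means", {
  s <- tiny_session(2, labels = c(-1L, NA_integer_))
  ep <- segment_epochs(s)
  ep$eeg[, 3] <- 0                       # degenerate epoch inside window 1
  feats <- epoch_features(ep)
  expect_true(feats$degenerate[3])
  w <- average_windows(feats, s$minute_labels, "T1", drop_epochs = 1:2)
  expect_false(w$excluded[1])            # 27/30 epochs still usable
  expect_true(w$excluded[2])             # mid/late label
  expect_equal(w$rbp_theta[1], mean(feats$rbp_theta[4:30]),
               tolerance = 1e-12)

  # a window with > 50% unusable epochs is flagged excluded
  ep$eeg[, 1:16] <- 0
  feats2 <- epoch_features(ep)
  w2 <- average_windows(feats2, s$minute_labels, "T1")
  expect_true(w2$excluded[1])
})

test_that("1800 epoch features average into 60 windows", {
  feats <- data.frame(epoch = 1:1800, rbp_theta = 18, rbp_alpha = 40,
                      rbp_beta = 42, mp = 75, degenerate = FALSE)
  w <- average_windows(feats, rep(c(-1L, 1L, NA_integer_), each = 20))
  expect_identical(nrow(w), 60L)
  expect_identical(sum(w$excluded), 20L)
  # averaging 30 identical vectors reproduces the vector
  expect_equal(unique(w$rbp_theta), 18)
  expect_equal(unique(w$mp), 75)
})
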