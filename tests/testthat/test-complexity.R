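test_that("lz76 reproduces hand-parsed phrase counts", {
  expect_identical(lz76(rep(0, 10)), 2L)          # 0 | 000000000
  expect_identical(lz76(c(0, 0, 0, 1, 1, 0, 1, 0, 0, 1, 0, 0, 0, 1, 0, 1)),
                   6L)                            # classic 16-bit example
  expect_identical(lz76(7), 1L)
  expect_identical(lz76(c("a", "b", "a")), 3L)
  expect_error(lz76(integer(0)), "empty")
  expect_error(lz76(c(1, NA)), "NA")
})

test_that("lz76 agrees with the brute-force parser on random alphabets", {
  set.seed(30)
  for (i in 1:60) {
    s <- sample(0:sample(1:3, 1), sample(1:60, 1), replace = TRUE)
    expect_identical(lz76(s), lz_brute(s))
  }
})

test_that("random strings are more complex than periodic ones", {
  set.seed(31)
  n <- 400
  rand_mean <- mean(vapply(1:20, function(i)
    lz76(sample(0:1, n, replace = TRUE)), numeric(1)))
  per_mean <- lz76(rep(c(0, 1), n / 2))
  expect_gt(rand_mean, per_mean)
})

test_that("joint LZC collapses redundancy and single channels coincide", {
  set.seed(32)
  bits <- sample(0:1, 500, replace = TRUE)
  B <- rbind(bits, bits, bits)
  bw <- structure(list(windows = list(B), thresholds = list(c(0, 0, 0)),
                       labels = c("a", "b", "c"), fs_hz = 50, window_s = 10),
                  class = "binary_windows")
  v <- lzc_variants(bw)
  expect_identical(v$per_window$joint, lz76(bits))
  # a single channel makes the three variants coincide
  bw1 <- structure(list(windows = list(rbind(bits)), thresholds = list(0),
                        labels = "a", fs_hz = 50, window_s = 10),
                   class = "binary_windows")
  v1 <- lzc_variants(bw1)
  expect_identical(v1$per_window$univariate_median, v1$per_window$concatenated)
  expect_identical(v1$per_window$joint, v1$per_window$concatenated)
})

test_that("joint stays below concatenated for independent channels", {
  set.seed(33)
  diff <- vapply(1:20, function(i) {
    B <- matrix(sample(0:1, 8 * 400, replace = TRUE), 8)
    bw <- structure(list(windows = list(B), thresholds = list(numeric(8)),
                         labels = paste0("c", 1:8), fs_hz = 40,
                         window_s = 10), class = "binary_windows")
    v <- lzc_variants(bw)
    v$per_window$concatenated - v$per_window$joint
  }, numeric(1))
  expect_gt(mean(diff), 0)
})

test_that("binarization tracks the envelope against its window mean", {
  fs <- 250
  tt <- seq_len(fs * 10) / fs
  env <- rep(c(0.2, 1), each = fs)             # 1-s square-wave envelope
  env <- rep_len(env, length(tt))
  x <- env * cos(2 * pi * 10 * tt)
  bw <- binarize(as_epochs(rbind(x), fs, 10))
  bits <- bw$windows[[1]][1, ]
  inner <- 100:2400                            # away from Hilbert edge ripple
  expect_gt(mean(bits[inner] == (env[inner] > mean(env))), 0.95)
  # constant signal binarizes to all zeros with a warning
  expect_warning(bw0 <- binarize(as_epochs(matrix(1, 1, 2500), fs, 10)),
                 "constant")
  expect_true(all(bw0$windows[[1]] == 0))
})

test_that("phase randomization preserves the power spectrum exactly", {
  set.seed(34)
  x <- matrix(rnorm(2 * 600), 2)
  s1 <- phase_randomize(x, seed = 9)
  s2 <- phase_randomize(x, seed = 9)
  s3 <- phase_randomize(x, seed = 10)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  for (ch in 1:2) {
    p_orig <- Mod(stats::fft(x[ch, ]))^2
    p_sur <- Mod(stats::fft(s1[ch, ]))^2
    expect_equal(p_sur, p_orig, tolerance = 1e-8)
  }
})

test_that("phase-randomized white noise keeps its first two moments", {
  set.seed(35)
  mdiff <- vdiff <- numeric(50)
  for (i in 1:50) {
    x <- rnorm(512)
    s <- phase_randomize(x, seed = i)
    mdiff[i] <- mean(s) - mean(x)
    vdiff[i] <- var(s) / var(x) - 1
  }
  expect_lt(max(abs(mdiff)), 0.2)
  expect_lt(abs(mean(vdiff)), 0.05)
})

test_that("normalized LZC is near 1 for linear Gaussian signals", {
  set.seed(36)
  vals <- vapply(1:50, function(i) {
    x <- matrix(rnorm(3 * 250), 3)
    ep <- as_epochs(x, 125, 2)
    r <- normalized_lzc(ep, n_norm_surrogates = 5, seed = i)
    unname(r$means["univariate_median_norm"])
  }, numeric(1))
  expect_gt(mean(vals), 0.9)
  expect_lt(mean(vals), 1.1)
})

test_that("amplitude structure lowers normalized LZC below 1", {
  r <- gen_complexity_signal(3, 0.02, 125, 30, seed = 37)
  res <- normalized_lzc(epoch(r, 10), n_norm_surrogates = 5, seed = 38)
  expect_lt(res$means[["univariate_median_norm"]], 0.9)
})

test_that("channel relabeling leaves all variants but concatenated intact", {
  set.seed(39)
  x <- matrix(rnorm(4 * 500), 4)
  ep <- as_epochs(x, 125, 4)
  ep_p <- as_epochs(x[c(3, 1, 4, 2), ], 125, 4)
  v <- lzc_variants(binarize(ep))
  v_p <- lzc_variants(binarize(ep_p))
  expect_identical(v$per_window$univariate_median,
                   v_p$per_window$univariate_median)
  expect_identical(v$per_window$joint, v_p$per_window$joint)
})
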