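test_that("vectorized indices match direct summation of the formulas", {
  set.seed(10)
  fs <- 16
  for (case in 1:8) {
    nch <- sample(2:4, 1)
    x <- matrix(rnorm(nch * 64), nch)     # one 4-s window of 64 samples
    ep <- as_epochs(x, fs, 4)
    m <- phase_lag_indices(ep)
    for (i in seq_len(nch - 1)) for (j in (i + 1):nch) {
      ref <- pli_brute(x[i, ], x[j, ])
      expect_equal(m$wpli[i, j, 1], unname(ref["wpli"]), tolerance = 1e-12)
      expect_equal(m$dpli[i, j, 1], unname(ref["dpli"]), tolerance = 1e-12)
    }
  }
})

test_that("constant-lag pair saturates and zero-lag pair vanishes", {
  fs <- 250
  tt <- seq_len(fs * 10) / fs
  base <- sin(2 * pi * 10 * tt)
  m <- phase_lag_indices(as_epochs(rbind(base, sin(2 * pi * 10 * tt - pi / 2)),
                                   fs, 10))
  expect_equal(m$wpli_avg[1, 2], 1, tolerance = 1e-6)
  expect_equal(m$dpli_avg[1, 2], 1, tolerance = 1e-3)
  m0 <- phase_lag_indices(as_epochs(rbind(base, 2 * base), fs, 10))
  expect_identical(m0$wpli_avg[1, 2], 0)
  expect_identical(m0$dpli_avg[1, 2], 0.5)
})

test_that("dPLI is invariant under a common phase rotation of both channels", {
  set.seed(11)
  x <- narrowband <- signal::filtfilt(signal::butter(4, c(8, 13) / 62.5),
                                      rnorm(1250))
  y <- signal::filtfilt(signal::butter(4, c(8, 13) / 62.5), rnorm(1250))
  rot <- function(v, th) Re(analytic_signal(v) * exp(1i * th))
  m1 <- phase_lag_indices(as_epochs(rbind(x, y), 125, 10))
  m2 <- phase_lag_indices(as_epochs(rbind(rot(x, 0.7), rot(y, 0.7)), 125, 10))
  # re-deriving the analytic signal after rotation has finite-window edge
  # leakage, so invariance is near-exact rather than bitwise
  expect_equal(m1$dpli_avg[1, 2], m2$dpli_avg[1, 2], tolerance = 5e-3)
  expect_equal(m1$wpli_avg[1, 2], m2$wpli_avg[1, 2], tolerance = 5e-3)
})

test_that("an all-zero channel yields wPLI 0 / dPLI 0.5 with a warning", {
  set.seed(12)
  x <- rbind(rnorm(1250), 0)
  expect_warning(m <- phase_lag_indices(as_epochs(x, 125, 10)),
                 "all-zero")
  expect_identical(m$wpli_avg[1, 2], 0)
  expect_identical(m$dpli_avg[1, 2], 0.5)
})

test_that("surrogate configuration validates its p-value resolution", {
  expect_error(surrogate_config(n_surrogates = 10, alpha = 0.05),
               "cannot resolve")
  expect_silent(surrogate_config(n_surrogates = 19, alpha = 0.05))
})

test_that("a strong lagged pair survives correction across seeds", {
  vals <- vapply(1:5, function(s) {
    g <- lag_graph(2, rbind(c(1, 2)), pi / 2, 1)
    r <- gen_lagged_oscillators(g, 125, 30, 40, seed = s)
    ep <- bandpass_alpha(epoch(r, 10))
    m <- surrogate_correct(ep, phase_lag_indices(ep),
                           surrogate_config(seed = s + 100))
    m$wpli_avg[1, 2]
  }, numeric(1))
  expect_gt(mean(vals), 0.7)
  expect_true(all(vals > 0))
})

test_that("node degree sums retained connections per electrode", {
  wpli <- array(0, c(4, 4, 1))
  wpli[1, 2, 1] <- wpli[2, 1, 1] <- 0.6
  dpli <- array(0.5, c(4, 4, 1))
  m <- eegpli:::new_conn(wpli, dpli, letters[1:4], corrected = TRUE,
                         window_s = 10, fs_hz = 250)
  deg <- node_degree(m)
  expect_equal(unclass(deg), c(a = 0.6, b = 0.6, c = 0, d = 0))
  m0 <- eegpli:::new_conn(array(0, c(3, 3, 1)), array(0.5, c(3, 3, 1)),
                          letters[1:3], TRUE, 10, 250)
  expect_true(all(node_degree(m0) == 0))
})

test_that("frontoparietal summary separates hemispheres and handles gaps", {
  mont <- make_montage(10)
  n <- nrow(mont)
  dpli <- array(0.5, c(n, n, 1))
  m <- eegpli:::new_conn(array(0, c(n, n, 1)), dpli, mont$label, TRUE, 10,
                         250)
  fp <- frontoparietal_summary(m, mont)
  expect_equal(unname(fp$per_hemisphere), c(0.5, 0.5))
  # frontal leads parietal on the left only
  iF <- which(mont$label == montage_labels(mont, "F", "L"))
  iP <- which(mont$label == montage_labels(mont, "P", "L"))
  dpli[iF, iP, 1] <- 0.9
  dpli[iP, iF, 1] <- 0.1
  m2 <- eegpli:::new_conn(array(0, c(n, n, 1)), dpli, mont$label, TRUE, 10,
                          250)
  fp2 <- frontoparietal_summary(m2, mont)
  expect_gt(fp2$per_hemisphere["L"], 0.5)
  expect_equal(unname(fp2$per_hemisphere["R"]), 0.5)
  # recording without right-parietal coverage: hemisphere reported missing
  keep <- mont$label != montage_labels(mont, "P", "R")
  m3 <- eegpli:::new_conn(array(0, c(n - 1, n - 1, 1)),
                          array(0.5, c(n - 1, n - 1, 1)),
                          mont$label[keep], TRUE, 10, 250)
  fp3 <- frontoparietal_summary(m3, mont)
  expect_true(is.na(fp3$per_hemisphere["R"]))
  expect_false(is.na(fp3$per_hemisphere["L"]))
})

test_that("hub index is the degree-weighted anterior-posterior coordinate", {
  mont <- make_montage(10)
  d <- stats::setNames(numeric(10), mont$label)
  fl <- montage_labels(mont, "F", "L")
  d[fl] <- 2.5
  hi <- hub_index(structure(d, class = "degree_vector"), mont)
  expect_equal(hi$score, mont$y[mont$label == fl])
  expect_identical(hi$hub_channel, fl)
  # uniform degree on the symmetric montage is balanced
  d[] <- 1
  hi2 <- hub_index(structure(d, class = "degree_vector"), mont)
  expect_equal(hi2$score, 0, tolerance = 1e-12)
  d[] <- 0
  expect_warning(hi3 <- hub_index(structure(d, class = "degree_vector"),
                                  mont), "undefined")
  expect_true(is.na(hi3$score))
})

test_that("hub directionality flags sources and targets", {
  n <- 4
  dpli <- array(0.5, c(n, n, 1))
  dpli[1, 2:4, 1] <- 1                  # star: channel 1 leads everyone
  dpli[2:4, 1, 1] <- 0
  m <- eegpli:::new_conn(array(0, c(n, n, 1)), dpli, letters[1:n], TRUE,
                         10, 250)
  hd <- hub_directionality(m)
  expect_equal(unname(hd["a"]), 1)
  expect_true(all(hd[c("b", "c", "d")] < 0.5))
  # all neutral -> all 0.5
  m2 <- eegpli:::new_conn(array(0, c(n, n, 1)), array(0.5, c(n, n, 1)),
                          letters[1:n], TRUE, 10, 250)
  expect_true(all(hub_directionality(m2) == 0.5))
})

test_that("a transitive frontal-central-parietal chain orders directionality", {
  mont <- make_montage(10)
  iF <- which(mont$label == montage_labels(mont, "F", "L"))
  iC <- which(mont$label == montage_labels(mont, "C", "L"))
  iP <- which(mont$label == montage_labels(mont, "P", "L"))
  g <- lag_graph(10, rbind(c(iF, iC), c(iC, iP)), pi / 3, 1)
  r <- gen_lagged_oscillators(g, 125, 30, 30, seed = 21)
  r$labels <- mont$label
  rownames(r$data) <- mont$label
  ep <- bandpass_alpha(epoch(r, 10))
  m <- surrogate_correct(ep, phase_lag_indices(ep),
                         surrogate_config(seed = 22))
  hd <- hub_directionality(m)
  expect_gt(hd[mont$label[iF]], 0.5)
  expect_lt(hd[mont$label[iP]], 0.5)
})
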