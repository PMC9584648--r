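test_that("lag graph validation enforces direction, lag and coupling ranges", {
  expect_error(lag_graph(4, rbind(c(1, 2), c(2, 1))), "one direction")
  expect_error(lag_graph(4, rbind(c(1, 1))), "self-pairs")
  expect_error(lag_graph(4, rbind(c(1, 5))), "out of range")
  expect_error(lag_graph(4, rbind(c(1, 2)), lag_radians = pi), "inside")
  expect_error(lag_graph(4, rbind(c(1, 2)), lag_radians = 0), "inside")
  expect_error(lag_graph(4, rbind(c(1, 2)), coupling = 1.2), "coupling")
  g <- lag_graph(4, rbind(c(1, 2), c(3, 4)), c(pi / 3, pi / 5), c(0.5, 1))
  expect_equal(nrow(g$lead_pairs), 2L)
})

test_that("equal seeds give bit-identical recordings, unequal seeds differ", {
  g <- lag_graph(3, rbind(c(1, 2)), pi / 4, 0.8)
  r1 <- gen_lagged_oscillators(g, 125, 30, 10, seed = 42)
  r2 <- gen_lagged_oscillators(g, 125, 30, 10, seed = 42)
  r3 <- gen_lagged_oscillators(g, 125, 30, 10, seed = 43)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, r3$data))
  expect_error(gen_lagged_oscillators(g, 125, 30, NaN), "NA/NaN")
  p1 <- gen_case_pair(scenario_spec("feedback_increase", fs_hz = 125,
                                    duration_s = 30, seed = 7))
  p2 <- gen_case_pair(scenario_spec("feedback_increase", fs_hz = 125,
                                    duration_s = 30, seed = 7))
  expect_identical(p1$baseline$data, p2$baseline$data)
  expect_identical(p1$anesthesia$data, p2$anesthesia$data)
})

test_that("a strong quarter-cycle pair is recovered as leader/lagger", {
  g <- lag_graph(2, rbind(c(1, 2)), pi / 2, 1)
  r <- gen_lagged_oscillators(g, 250, 40, 40, seed = 5)
  m <- phase_lag_indices(bandpass_alpha(epoch(r, 10)))
  expect_gt(m$dpli_avg[1, 2], 0.9)
  expect_gt(m$wpli_avg[1, 2], 0.9)
})

test_that("uncoupled channels show no connectivity after correction", {
  g <- lag_graph(4)                      # empty lead set
  r <- gen_lagged_oscillators(g, 125, 30, 10, seed = 3)
  ep <- bandpass_alpha(epoch(r, 10))
  m <- surrogate_correct(ep, phase_lag_indices(ep),
                         surrogate_config(seed = 4))
  expect_lt(mean(m$wpli_avg[upper.tri(m$wpli_avg)]), 0.05)
})

test_that("common-source channels have analytically zero imaginary cross-spectrum", {
  r <- gen_common_source(4, 125, 20, seed = 1, gains = c(1, 0.5, 2, 1.3),
                         jitter_sd = 0)
  a1 <- analytic_signal(r$data[1, ])
  for (j in 2:4) {
    aj <- analytic_signal(r$data[j, ])
    rel <- mean(abs(Im(a1 * Conj(aj)))) / mean(Mod(a1 * Conj(aj)))
    expect_lt(rel, 1e-10)
  }
  expect_error(gen_common_source(1, 125, 20), ">= 2")
})

test_that("equal-gain common source pair has dPLI 0.5 after correction", {
  r <- gen_common_source(2, 125, 30, seed = 2, gains = c(1, 1))
  ep <- bandpass_alpha(epoch(r, 10))
  m <- surrogate_correct(ep, phase_lag_indices(ep),
                         surrogate_config(seed = 3))
  expect_identical(m$dpli_avg[1, 2], 0.5)
})

test_that("complexity signal hits the floor at p_flip 0 and grows with p_flip", {
  r0 <- gen_complexity_signal(2, 0, 125, 30, seed = 1)
  counts <- sapply(binarize(epoch(r0, 10))$windows,
                   function(B) apply(B, 1L, lz76))
  expect_true(all(counts == 2L))        # "0|000...0" parse
  mean_lzc <- function(p) mean(vapply(1:10, function(s) {
    r <- gen_complexity_signal(4, p, 125, 20, seed = s)
    mean(lzc_variants(binarize(epoch(r, 10)))$per_window$univariate_median)
  }, numeric(1)))
  expect_gt(mean_lzc(0.4), mean_lzc(0.05))
  expect_error(gen_complexity_signal(2, 0.6, 125, 30), "p_flip")
  expect_error(gen_complexity_signal(2, -0.1, 125, 30), "p_flip")
})

test_that("scenario specs validate and pairs carry ground truth", {
  expect_error(scenario_spec("nonsense"), "arg")
  expect_error(scenario_spec("complexity_up", duration_s = 20), ">= 30")
  expect_error(scenario_spec("complexity_up", fs_hz = 50), ">= 100")
  for (nm in c("feedback_increase", "feedback_decrease", "hub_posteriorize",
               "hub_anteriorize", "complexity_up", "complexity_down")) {
    p <- gen_case_pair(scenario_spec(nm, fs_hz = 125, duration_s = 30,
                                     seed = 1))
    expect_identical(p$baseline$state, "baseline")
    expect_identical(p$anesthesia$state, "anesthesia")
    expect_identical(p$baseline$labels, p$montage$label)
    expect_setequal(names(p$expected_changes),
                    c("fp_dpli", "hub_index", "univariate_median",
                      "concatenated", "joint"))
    expect_true(any(p$expected_changes != 0))
  }
  exp_fi <- gen_case_pair(scenario_spec("feedback_increase", fs_hz = 125,
                                        duration_s = 30))$expected_changes
  expect_identical(unname(exp_fi["fp_dpli"]), 1)
  exp_cd <- gen_case_pair(scenario_spec("complexity_down", fs_hz = 125,
                                        duration_s = 30))$expected_changes
  expect_true(all(exp_cd[c("univariate_median", "concatenated",
                           "joint")] == -1))
})

test_that("simulate() advances seeds between replicate pairs", {
  sp <- scenario_spec("complexity_down", fs_hz = 125, duration_s = 30,
                      seed = 2)
  pairs <- simulate(sp, nsim = 2)
  expect_length(pairs, 2L)
  expect_false(identical(pairs[[1]]$baseline$data,
                         pairs[[2]]$baseline$data))
  one <- simulate(sp, nsim = 1)
  expect_s3_class(one, "case_pair")
})
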