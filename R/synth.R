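#' Directed phase-lag ground-truth graph
#'
#' Specifies which channels share an alpha-band oscillation and who leads
#' whom: pair `(i, j)` means channel `i` phase-leads channel `j` by
#' `lag_radians`, with coupling strength `coupling` in \[0, 1\].
#'
#' @param n_channels number of channels in the recording the graph targets.
#' @param lead_pairs two-column integer matrix (or list of length-2 vectors);
#'   row `(i, j)` = channel `i` leads channel `j`.
#' @param lag_radians numeric vector (recycled), strictly inside `(0, pi)`.
#' @param coupling numeric vector (recycled) in \[0, 1\].
#' @return object of class `lag_graph`.
#' @export
lag_graph <- function(n_channels, lead_pairs = NULL, lag_radians = pi / 4,
                      coupling = 1) {
  if (n_channels < 1L) stop("n_channels must be positive")
  if (is.list(lead_pairs)) lead_pairs <- do.call(rbind, lead_pairs)
  if (is.null(lead_pairs)) lead_pairs <- matrix(integer(0), ncol = 2L)
  lead_pairs <- matrix(as.integer(lead_pairs), ncol = 2L)
  np <- nrow(lead_pairs)
  lag_radians <- rep_len(lag_radians, np)
  coupling <- rep_len(coupling, np)
  if (np > 0L) {
    if (any(lead_pairs < 1L) || any(lead_pairs > n_channels))
      stop("pair indices out of range 1..", n_channels)
    if (any(lead_pairs[, 1L] == lead_pairs[, 2L]))
      stop("self-pairs are not allowed")
    keys <- paste(lead_pairs[, 1L], lead_pairs[, 2L])
    rkeys <- paste(lead_pairs[, 2L], lead_pairs[, 1L])
    if (anyDuplicated(keys) || any(keys %in% rkeys))
      stop("a channel pair may appear in one direction only")
    if (any(lag_radians <= 0) || any(lag_radians >= pi))
      stop("lag_radians must lie strictly inside (0, pi)")
    if (any(coupling < 0) || any(coupling > 1))
      stop("coupling must lie in [0, 1]")
  }
  structure(list(n_channels = as.integer(n_channels),
                 lead_pairs = lead_pairs,
                 lag_radians = lag_radians, coupling = coupling),
            class = "lag_graph")
}

#' Simulate alpha-band recordings with known directed phase lags
#'
#' Each coupled pair shares one stochastic narrowband process spanning the
#' alpha band (8-13 Hz, centered on 10 Hz); the lagging channel receives the
#' analytic signal of
#' that process rotated by `-lag` radians, so the instantaneous phase
#' difference (leader minus lagger) equals the requested lag exactly before
#' noise.  Every channel then receives independent 1/f-shaped Gaussian noise
#' scaled to the requested in-band (8-13 Hz) signal-to-noise ratio.  Channels
#' in no pair carry noise only.
#'
#' @param graph a [lag_graph()].
#' @param fs_hz sampling rate (>= 100 Hz so the alpha band is resolvable).
#' @param duration_s duration in seconds.
#' @param snr_db in-band SNR in dB; `Inf` means noise-free.
#' @param seed integer seed; equal seeds give bit-identical recordings.
#' @return an [eeg_recording()] with state `"synthetic"`.
#' @export
gen_lagged_oscillators <- function(graph, fs_hz, duration_s, snr_db = 10,
                                   seed = 1) {
  stopifnot(inherits(graph, "lag_graph"))
  if (is.na(snr_db) || is.nan(snr_db)) stop("snr_db must not be NA/NaN")
  if (fs_hz < 100) stop("fs_hz must be >= 100 Hz")
  n <- round(fs_hz * duration_s)
  nch <- graph$n_channels
  with_seed(seed, {
    sig <- matrix(0, nch, n)
    for (k in seq_len(nrow(graph$lead_pairs))) {
      i <- graph$lead_pairs[k, 1L]
      j <- graph$lead_pairs[k, 2L]
      a <- analytic_signal(narrowband_noise(n, fs_hz, 8, 13))
      cpl <- graph$coupling[k]
      sig[i, ] <- sig[i, ] + cpl * Re(a)
      sig[j, ] <- sig[j, ] + cpl * Re(a * exp(-1i * graph$lag_radians[k]))
    }
    out <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      noise <- pink_noise(n)
      s_pow <- window_band_power(sig[ch, ], fs_hz, 8, 13)
      if (s_pow > 0 && is.finite(snr_db)) {
        n_pow <- window_band_power(noise, fs_hz, 8, 13)
        noise <- noise * sqrt(s_pow / (n_pow * 10^(snr_db / 10)))
      } else if (s_pow > 0) {
        noise <- noise * 0
      }
      out[ch, ] <- sig[ch, ] + noise
    }
    eeg_recording(out, fs_hz = fs_hz,
                  labels = paste0("ch", seq_len(nch)), state = "synthetic")
  })
}

#' Simulate a zero-lag common-source (volume-conduction) recording
#'
#' Every channel is a positive scalar multiple of one shared band-limited
#' (8-13 Hz) source plus negligible independent jitter, so all channel pairs
#' have exactly zero phase lag by construction and the imaginary
#' cross-spectrum is analytically zero before the jitter.  This is the
#' fixture for zero-lag insensitivity of the weighted phase lag index.
#'
#' @param n_channels at least 2.
#' @param fs_hz,duration_s,seed as in [gen_lagged_oscillators()].
#' @param gains positive per-channel multiples of the shared source;
#'   defaults to deterministic values spread over \[0.5, 2\].
#' @param jitter_sd standard deviation of the independent jitter, relative
#'   to the source (default `1e-6`).
#' @return an [eeg_recording()].
#' @export
gen_common_source <- function(n_channels, fs_hz, duration_s, seed = 1,
                              gains = NULL, jitter_sd = 1e-6) {
  if (n_channels < 2L) stop("a common-source recording needs >= 2 channels")
  if (is.null(gains)) gains <- seq(0.5, 2, length.out = n_channels)
  if (length(gains) != n_channels || any(gains <= 0))
    stop("gains must be ", n_channels, " positive numbers")
  n <- round(fs_hz * duration_s)
  with_seed(seed, {
    src <- narrowband_noise(n, fs_hz, 8, 13)
    data <- outer(gains, src) +
      jitter_sd * matrix(stats::rnorm(n_channels * n), n_channels, n)
    eeg_recording(data, fs_hz = fs_hz,
                  labels = paste0("ch", seq_len(n_channels)),
                  state = "synthetic")
  })
}

#' Simulate amplitude-modulated signals with controllable compressibility
#'
#' Each channel is a 10 Hz carrier (independent random phase per channel)
#' amplitude-modulated by an independent binary Markov chain that switches
#' between a low and a high envelope level with per-sample flip probability
#' `p_flip`.  `p_flip = 0` yields a constant envelope (minimal-complexity
#' signal); expected Lempel-Ziv complexity increases monotonically with
#' `p_flip` up to 0.5.
#'
#' @param n_channels number of channels.
#' @param p_flip per-sample flip probability of the envelope chain, in
#'   \[0, 0.5\].
#' @param fs_hz,duration_s,seed as in [gen_lagged_oscillators()].
#' @param levels length-2 numeric, low and high envelope levels.
#' @return an [eeg_recording()].
#' @export
gen_complexity_signal <- function(n_channels, p_flip, fs_hz, duration_s,
                                  seed = 1, levels = c(0.25, 1)) {
  if (length(p_flip) != 1L || is.na(p_flip) || p_flip < 0 || p_flip > 0.5)
    stop("p_flip must lie in [0, 0.5]")
  n <- round(fs_hz * duration_s)
  tt <- seq_len(n) / fs_hz
  with_seed(seed, {
    data <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      if (p_flip == 0) {
        env <- rep(levels[2L], n)
      } else {
        flips <- stats::runif(n - 1L) < p_flip
        state <- cumsum(c(stats::runif(1) < 0.5, flips)) %% 2L
        env <- levels[1L] + (levels[2L] - levels[1L]) * state
      }
      theta <- stats::runif(1, 0, 2 * pi)
      data[ch, ] <- env * cos(2 * pi * 10 * tt + theta)
    }
    eeg_recording(data, fs_hz = fs_hz,
                  labels = paste0("ch", seq_len(n_channels)),
                  state = "synthetic")
  })
}

scenario_names <- c("feedback_increase", "feedback_decrease",
                    "hub_posteriorize", "hub_anteriorize",
                    "complexity_up", "complexity_down")

#' Specify a paired baseline/anesthesia simulation scenario
#'
#' The six scenarios encode the canonical and paradoxical directions of
#' anesthetic-induced network change: frontoparietal feedback dominance
#' rising or falling, hub topography shifting anterior or posterior, and
#' signal complexity rising or falling.  Passing a `scenario_spec` to
#' [simulate()] (or [gen_case_pair()]) yields a baseline/anesthesia
#' recording pair with a ground-truth record of the expected sign of change
#' per metric.
#'
#' @param name one of `r paste(scenario_names, collapse = ", ")`.
#' @param n_channels montage size (even, >= 10); default 10.
#' @param fs_hz sampling rate, >= 100; default 250.
#' @param duration_s per-state duration, >= 30 s (three 10-s windows);
#'   default 60.
#' @param snr_db in-band SNR for the oscillatory scenarios; default 10.
#' @param seed integer seed.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, n_channels = 10, fs_hz = 250,
                          duration_s = 60, snr_db = 10, seed = 1) {
  name <- match.arg(name, scenario_names)
  if (duration_s < 30) stop("duration_s must be >= 30 (three 10-s windows)")
  if (fs_hz < 100) stop("fs_hz must be >= 100 (alpha band resolvable)")
  structure(list(name = name, n_channels = n_channels, fs_hz = fs_hz,
                 duration_s = duration_s, snr_db = snr_db,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: %d ch, %g Hz, %g s, SNR %g dB, seed %d\n",
              x$name, x$n_channels, x$fs_hz, x$duration_s, x$snr_db, x$seed))
  invisible(x)
}

# lag graph connecting frontal->parietal within each lateral hemisphere
fp_graph <- function(montage, lag = pi / 4, coupling = 0.9) {
  pairs <- list()
  for (h in c("L", "R")) {
    f <- which(montage$region == "F" & montage$hemisphere == h)
    p <- which(montage$region == "P" & montage$hemisphere == h)
    pairs[[h]] <- cbind(f[1L], p[1L])
  }
  lag_graph(nrow(montage), do.call(rbind, pairs), lag, coupling)
}

# lag graph concentrating degree on anterior (F,C) or posterior (P,O) sites
cluster_graph <- function(montage, where = c("anterior", "posterior"),
                          lag = pi / 4, coupling = 0.9) {
  where <- match.arg(where)
  regs <- if (where == "anterior") c("F", "C") else c("P", "O")
  idx <- which(montage$region %in% regs)
  ord <- idx[order(montage$label[idx])]
  # chain through the cluster: each site leads the next
  pairs <- cbind(ord[-length(ord)], ord[-1L])
  lag_graph(nrow(montage), pairs, lag, coupling)
}

#' Generate a baseline/anesthesia recording pair with ground truth
#'
#' @param spec a [scenario_spec()].
#' @return a list of class `case_pair`: `baseline` and `anesthesia`
#'   recordings sharing one montage, the `montage`, and `expected_changes`
#'   — the expected sign (-1, 0, +1) of the anesthesia-minus-baseline change
#'   in mean frontoparietal dPLI (`fp_dpli`), the anterior-posterior hub
#'   index (`hub_index`), and each normalized LZC variant.
#' @export
gen_case_pair <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  mont <- make_montage(spec$n_channels)
  nch <- nrow(mont)
  empty <- lag_graph(nch)
  seeds <- spec$seed + c(0L, 1L)   # baseline, anesthesia
  gen <- function(graph, seed) {
    r <- gen_lagged_oscillators(graph, spec$fs_hz, spec$duration_s,
                                spec$snr_db, seed)
    r$labels <- mont$label
    rownames(r$data) <- mont$label
    r
  }
  genc <- function(p_flip, seed) {
    r <- gen_complexity_signal(nch, p_flip, spec$fs_hz, spec$duration_s,
                               seed)
    r$labels <- mont$label
    rownames(r$data) <- mont$label
    r
  }
  zero_lzc <- c(univariate_median = 0, concatenated = 0, joint = 0)
  sgn_lzc <- function(s) c(univariate_median = s, concatenated = s, joint = s)
  res <- switch(spec$name,
    feedback_increase = list(
      baseline = gen(empty, seeds[1L]),
      anesthesia = gen(fp_graph(mont), seeds[2L]),
      expected = c(fp_dpli = +1, hub_index = 0, zero_lzc)),
    feedback_decrease = list(
      baseline = gen(fp_graph(mont), seeds[1L]),
      anesthesia = gen(empty, seeds[2L]),
      expected = c(fp_dpli = -1, hub_index = 0, zero_lzc)),
    hub_posteriorize = list(
      baseline = gen(cluster_graph(mont, "anterior"), seeds[1L]),
      anesthesia = gen(cluster_graph(mont, "posterior"), seeds[2L]),
      expected = c(fp_dpli = 0, hub_index = -1, zero_lzc)),
    hub_anteriorize = list(
      baseline = gen(cluster_graph(mont, "posterior"), seeds[1L]),
      anesthesia = gen(cluster_graph(mont, "anterior"), seeds[2L]),
      expected = c(fp_dpli = 0, hub_index = +1, zero_lzc)),
    complexity_up = list(
      baseline = genc(0.05, seeds[1L]),
      anesthesia = genc(0.45, seeds[2L]),
      expected = c(fp_dpli = 0, hub_index = 0, sgn_lzc(+1))),
    complexity_down = list(
      baseline = genc(0.45, seeds[1L]),
      anesthesia = genc(0.05, seeds[2L]),
      expected = c(fp_dpli = 0, hub_index = 0, sgn_lzc(-1)))
  )
  res$baseline$state <- "baseline"
  res$anesthesia$state <- "anesthesia"
  structure(list(baseline = res$baseline, anesthesia = res$anesthesia,
                 montage = mont, expected_changes = res$expected,
                 scenario = spec),
            class = "case_pair")
}

#' Simulate a scenario
#'
#' `simulate()` on a [scenario_spec()] returns `nsim` baseline/anesthesia
#' [gen_case_pair()] results, advancing the scenario seed by 1000 between
#' replicates.
#'
#' @param object a `scenario_spec`.
#' @param nsim number of replicate pairs.
#' @param seed overrides the spec's seed when given.
#' @param ... unused.
#' @return a `case_pair` when `nsim = 1`, else a list of them.
#' @export
simulate.scenario_spec <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) object$seed <- as.integer(seed)
  out <- lapply(seq_len(nsim) - 1L, function(k) {
    sp <- object
    sp$seed <- object$seed + 1000L * k
    gen_case_pair(sp)
  })
  if (nsim == 1L) out[[1L]] else out
}

#' @export
print.case_pair <- function(x, ...) {
  cat(sprintf("<case_pair> scenario %s (seed %d)\n", x$scenario$name,
              x$scenario$seed))
  cat("expected sign of change (anesthesia - baseline):\n")
  print(x$expected_changes)
  invisible(x)
}
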