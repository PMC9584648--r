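# Independent reference implementations used as oracles.

# Exhaustive-history Lempel-Ziv parser by literal definition: the next
# phrase is the shortest word not occurring as a substring of everything
# before its last symbol; the trailing word counts regardless.
lz_brute <- function(s) {
  n <- length(s)
  pos <- 1L
  count <- 0L
  while (pos <= n) {
    k <- 1L
    repeat {
      if (pos + k - 1L > n) break
      word <- s[pos:(pos + k - 1L)]
      prefix <- s[seq_len(pos + k - 2L)]
      found <- FALSE
      if (length(prefix) >= k)
        for (st in seq_len(length(prefix) - k + 1L))
          if (all(prefix[st:(st + k - 1L)] == word)) { found <- TRUE; break }
      if (!found) break
      k <- k + 1L
    }
    count <- count + 1L
    pos <- pos + k
  }
  count
}

# Direct per-sample summation of the printed wPLI / dPLI formulas for one
# channel pair, from the analytic signals.
pli_brute <- function(xi, xj) {
  ai <- analytic_signal(xi)
  aj <- analytic_signal(xj)
  num <- 0
  den <- 0
  h <- 0
  N <- length(xi)
  for (t in seq_len(N)) {
    C <- ai[t] * Conj(aj[t])
    num <- num + Im(C)
    den <- den + abs(Im(C))
    dphi <- Arg(ai[t]) - Arg(aj[t])
    dphi <- Arg(exp(1i * dphi))        # wrap to (-pi, pi]
    h <- h + if (dphi > 0) 1 else if (dphi == 0) 0.5 else 0
  }
  c(wpli = abs(num / N) / (den / N), dpli = h / N)
}

# epochs object straight from a channels x samples matrix
as_epochs <- function(m, fs, window_s) {
  epoch(eeg_recording(m, fs_hz = fs), window_s = window_s)
}

# default scaled-down scenario analysis used across scenario tests
run_scenario <- function(name, seed, fs = 125, dur = 30, nn = 5) {
  pair <- gen_case_pair(scenario_spec(name, fs_hz = fs, duration_s = dur,
                                      seed = seed))
  cfg <- case_config(surrogate = surrogate_config(seed = seed + 500L),
                     n_norm_surrogates = nn, seed = seed + 900L)
  rep <- suppressWarnings(suppressMessages(
    run_case(pair$baseline, pair$anesthesia, montage = pair$montage,
             config = cfg)))
  list(report = rep, expected = pair$expected_changes)
}
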