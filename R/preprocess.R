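#' Signal conditioning for a raw recording
#'
#' Applies, in order: removal of listed bad channels, average referencing
#' over the retained channels, anti-aliased downsampling to `fs_target`
#' (only when the input rate is at least 500 Hz; otherwise resampling is
#' skipped with a notice), then zero-phase high-pass, low-pass and notch
#' filtering.  Filters are 4th-order Butterworth run forward-backward
#' (`filtfilt`), so no artificial phase leads can be introduced; the notch
#' is a 2nd-order IIR biquad at `notch_hz` with Q = 30.
#'
#' @param rec an [eeg_recording()].
#' @param drop_labels channel labels to remove before referencing.
#' @param fs_target downsampling target in Hz (default 250).
#' @param hp_hz,lp_hz high-/low-pass cutoffs in Hz (defaults 0.1 and 45).
#' @param notch_hz mains notch frequency (default 60); skipped with a notice
#'   if at or above the post-resampling Nyquist frequency.
#' @return the conditioned [eeg_recording()].
#' @export
preprocess <- function(rec, drop_labels = character(), fs_target = 250,
                       hp_hz = 0.1, lp_hz = 45, notch_hz = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  drop_labels <- as.character(drop_labels)
  unknown <- setdiff(drop_labels, rec$labels)
  if (length(unknown))
    stop("unknown drop labels: ", paste(unknown, collapse = ", "))
  keep <- !(rec$labels %in% drop_labels)
  if (sum(keep) < 2L)
    stop("dropping ", length(drop_labels),
         " channels leaves fewer than 2 channels")
  x <- rec$data[keep, , drop = FALSE]
  labels <- rec$labels[keep]
  # average reference: subtract the instantaneous mean of retained channels
  x <- sweep(x, 2L, colMeans(x))
  fs <- rec$fs_hz
  if (fs >= 500) {
    p <- fs_target
    q <- fs
    g <- gcd_int(p, q)
    x <- t(apply(x, 1L, function(ch) signal::resample(ch, p / g, q / g)))
    fs <- fs_target
  } else if (fs != fs_target) {
    message("input rate ", fs, " Hz < 500 Hz: resampling skipped")
  }
  nyq <- fs / 2
  if (hp_hz > 0) {
    bh <- signal::butter(4, hp_hz / nyq, type = "high")
    x <- t(apply(x, 1L, function(ch) signal::filtfilt(bh, ch)))
  }
  if (lp_hz < nyq) {
    bl <- signal::butter(4, lp_hz / nyq, type = "low")
    x <- t(apply(x, 1L, function(ch) signal::filtfilt(bl, ch)))
  }
  if (!is.null(notch_hz) && is.finite(notch_hz)) {
    if (notch_hz < nyq) {
      nt <- notch_biquad(notch_hz, fs, q_factor = 30)
      x <- t(apply(x, 1L, function(ch) signal::filtfilt(nt, ch)))
    } else {
      message("notch at ", notch_hz, " Hz >= Nyquist (", nyq,
              " Hz): skipped")
    }
  }
  eeg_recording(x, fs_hz = fs, labels = labels, state = rec$state)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# RBJ audio-cookbook notch biquad: unit gain away from f0, zero at f0
notch_biquad <- function(f0, fs, q_factor = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q_factor)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1L], a = a / a[1L])
}

#' Split a recording into non-overlapping fixed-length windows
#'
#' All estimation downstream is per 10-s window.  The trailing remainder
#' shorter than one window is discarded.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds (default 10).
#' @return object of class `eeg_epochs`: list with `windows` (list of
#'   channels x samples matrices), `window_s`, `fs_hz`, `labels`, `state`.
#' @export
epoch <- function(rec, window_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  nw_samp <- round(window_s * rec$fs_hz)
  n <- ncol(rec$data)
  if (n < nw_samp)
    stop("recording (", n / rec$fs_hz, " s) shorter than one window (",
         window_s, " s)")
  nwin <- floor(n / nw_samp)
  windows <- lapply(seq_len(nwin), function(w)
    rec$data[, ((w - 1L) * nw_samp + 1L):(w * nw_samp), drop = FALSE])
  structure(list(windows = windows, window_s = window_s, fs_hz = rec$fs_hz,
                 labels = rec$labels, state = rec$state),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d windows of %g s, %d channels @ %g Hz, state: %s\n",
              length(x$windows), x$window_s, length(x$labels), x$fs_hz,
              x$state))
  invisible(x)
}

#' Reject windows containing out-of-range samples
#'
#' A reproducible stand-in for manual artifact inspection: any window with a
#' sample exceeding `threshold` (absolute value, same units as the data,
#' conventionally microvolts) is dropped, with a notice naming the windows.
#'
#' @param ep an [epoch()] result.
#' @param threshold amplitude bound; default 150.
#' @return `eeg_epochs` with offending windows removed.
#' @export
reject_windows <- function(ep, threshold = 150) {
  stopifnot(inherits(ep, "eeg_epochs"))
  bad <- vapply(ep$windows, function(w) any(abs(w) > threshold), logical(1))
  if (any(bad)) {
    message("rejected ", sum(bad), " window(s) exceeding ", threshold,
            ": ", paste(which(bad), collapse = ", "))
    ep$windows <- ep$windows[!bad]
  }
  if (!length(ep$windows)) stop("all windows rejected")
  ep
}

#' Zero-phase alpha-band filtering
#'
#' 4th-order Butterworth band-pass (default 8-13 Hz) applied
#' forward-backward.  Accepts either a continuous [eeg_recording()]
#' (preferred: windows cut afterwards have no filter edge transients) or
#' [epoch()]s (filtered per window).
#'
#' @param ep an `eeg_recording` or an [epoch()] result.
#' @param band length-2 numeric band edges in Hz.
#' @return object of the same class and shape.
#' @export
bandpass_alpha <- function(ep, band = c(8, 13)) {
  fs <- ep$fs_hz
  if (fs < 2 * band[2L])
    stop("sampling rate ", fs, " Hz too low for a ", band[2L],
         " Hz band edge")
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  filt <- function(m) t(apply(m, 1L, function(ch) signal::filtfilt(bp, ch)))
  if (inherits(ep, "eeg_recording")) {
    ep$data <- filt(ep$data)
    rownames(ep$data) <- ep$labels
  } else if (inherits(ep, "eeg_epochs")) {
    ep$windows <- lapply(ep$windows, filt)
  } else stop("ep must be an eeg_recording or eeg_epochs")
  ep
}

#' Per-channel band power averaged over windows
#'
#' Integrated one-sided periodogram power in \[`lo_hz`, `hi_hz`\] per channel
#' per window, averaged over windows.
#'
#' @param ep an [epoch()] result.
#' @param lo_hz,hi_hz band edges, `0 < lo_hz < hi_hz < fs/2`.
#' @return named nonnegative numeric vector, one entry per channel.
#' @export
band_power <- function(ep, lo_hz, hi_hz) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < ep$fs_hz / 2))
    stop("need 0 < lo_hz < hi_hz < fs/2")
  per_win <- vapply(ep$windows, function(w)
    apply(w, 1L, window_band_power, fs = ep$fs_hz, lo = lo_hz, hi = hi_hz),
    numeric(length(ep$labels)))
  if (is.null(dim(per_win))) per_win <- matrix(per_win, nrow = 1L)
  stats::setNames(rowMeans(per_win), ep$labels)
}
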