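#' Binarize epochs by the mean instantaneous amplitude
#'
#' For every channel of every window the instantaneous amplitude (Hilbert
#' envelope) is computed and each sample mapped to 1 when the envelope
#' strictly exceeds the within-window channel mean envelope, else 0.
#' Complexity is computed on the broadband (0.1-45 Hz) signal, not the
#' alpha-filtered one.
#'
#' @param ep preprocessed [epoch()]s.
#' @return object of class `binary_windows`: list with `windows` (binary
#'   channels x samples matrices), `thresholds` (per-window named vectors),
#'   `labels`, `fs_hz`, `window_s`.
#' @export
binarize <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  flat <- logical(length(ep$labels))
  thresholds <- list()
  wins <- vector("list", length(ep$windows))
  for (w in seq_along(ep$windows)) {
    win <- ep$windows[[w]]
    env <- Mod(analytic_matrix(win))
    thr <- rowMeans(env)
    flat <- flat | apply(win, 1L, function(r) all(r == r[1L]))
    # strict inequality with a relative guard so a constant envelope maps
    # to all zeros despite machine-epsilon FFT ripple
    wins[[w]] <- (env > thr * (1 + 1e-9)) * 1L
    rownames(wins[[w]]) <- ep$labels
    thresholds[[w]] <- stats::setNames(thr, ep$labels)
  }
  if (any(flat))
    warning("constant channel(s) binarized to all zeros: ",
            paste(ep$labels[flat], collapse = ", "))
  structure(list(windows = wins, thresholds = thresholds,
                 labels = ep$labels, fs_hz = ep$fs_hz,
                 window_s = ep$window_s),
            class = "binary_windows")
}

#' Lempel-Ziv 1976 complexity of a symbol sequence
#'
#' The number of phrases in the exhaustive-history parsing of the sequence:
#' each phrase is the shortest continuation that cannot be reproduced by
#' copying from the text already seen (copy sources may overlap the phrase
#' itself); the trailing word counts even when still reproducible.
#' Deterministic; works over any finite alphabet (numeric, logical,
#' integer or character input).
#'
#' @param seq a non-empty vector of symbols.
#' @return positive integer phrase count.
#' @examples
#' lz76(rep(0, 10))                # "0|000000000" -> 2
#' lz76(c(0,0,0,1,1,0,1,0,0,1,0,0,0,1,0,1))  # classic example -> 6
#' @export
lz76 <- function(seq) {
  if (length(seq) == 0L) stop("empty sequence")
  if (anyNA(seq)) stop("sequence contains NA")
  codes <- match(seq, unique(seq))
  lz76_count(as.integer(codes))
}

#' Raw Lempel-Ziv complexity variants of binarized windows
#'
#' Per window: the *median univariate* LZC (median over channels of the
#' per-channel phrase count), the *concatenated* LZC (all channel rows
#' joined end-to-end in label order into one sequence), and the *joint*
#' LZC (the time-ordered sequence of per-sample channel bit-vectors parsed
#' as single symbols, a directly multivariate compression that collapses
#' inter-channel redundancy and reduces to the univariate count for one
#' channel).  Means over windows are reported alongside.
#'
#' @param bw a [binarize()] result.
#' @return object of class `complexity_result` with `per_window` (data
#'   frame) and `means`; raw phrase counts only.
#' @export
lzc_variants <- function(bw) {
  stopifnot(inherits(bw, "binary_windows"))
  rows <- lapply(seq_along(bw$windows), function(w) {
    B <- bw$windows[[w]]
    data.frame(window = w,
               univariate_median = stats::median(
                 apply(B, 1L, function(r) lz76_count(as.integer(r)))),
               concatenated = lz76_count(as.integer(t(B))),
               joint = lz76_count(joint_symbols(B)))
  })
  per_window <- do.call(rbind, rows)
  structure(list(per_window = per_window,
                 means = colMeans(per_window[-1L]),
                 normalized = NULL, n_norm_surrogates = 0L,
                 labels = bw$labels),
            class = "complexity_result")
}

# encode per-sample channel bit-vectors as integer symbols
joint_symbols <- function(B) {
  nch <- nrow(B)
  key <- if (nch <= 50L) {
    drop(crossprod(B, 2^(seq_len(nch) - 1L)))
  } else {
    apply(B, 2L, paste0, collapse = "")
  }
  as.integer(match(key, unique(key)))
}

#' Phase-randomized surrogate of a window
#'
#' Per channel, the FFT magnitudes are kept and the phases of the positive
#' frequencies replaced by i.i.d. uniform draws, Hermitian symmetry
#' enforced, and the inverse transform returned.  The surrogate has the
#' same power spectrum (hence autocorrelation) as the original but its
#' nonlinear and envelope structure destroyed.  Channel phases are
#' randomized independently.
#'
#' @param window channels x samples numeric matrix (or a single vector).
#' @param seed integer seed; deterministic for equal seeds.
#' @return matrix (or vector) of the same shape.
#' @export
phase_randomize <- function(window, seed = 1) {
  vec <- is.null(dim(window))
  if (vec) window <- matrix(window, nrow = 1L)
  n <- ncol(window)
  out <- with_seed(seed, {
    t(apply(window, 1L, function(x) {
      X <- stats::fft(x)
      half <- floor((n - 1L) / 2L)         # strictly positive, non-Nyquist
      if (half >= 1L) {
        ph <- stats::runif(half, 0, 2 * pi)
        pos <- 2L:(half + 1L)
        X[pos] <- Mod(X[pos]) * exp(1i * ph)
        X[n - pos + 2L] <- Conj(X[pos])
      }
      Re(stats::fft(X, inverse = TRUE) / n)
    }))
  })
  if (vec) drop(out) else out
}

#' Surrogate-normalized Lempel-Ziv complexity
#'
#' Computes the three raw LZC variants per window, then divides each by the
#' mean raw value over `n_norm_surrogates` phase-randomized versions of the
#' same window (binarized the same way).  The normalization minimizes the
#' influence of spectral change on the complexity estimate: a linear
#' Gaussian signal is its own surrogate class and normalizes to about 1,
#' while strong amplitude structure (which surrogates destroy) pushes the
#' ratio below 1.
#'
#' @param ep preprocessed broadband [epoch()]s.
#' @param n_norm_surrogates surrogates per window (default 10).
#' @param seed integer seed.
#' @return `complexity_result` with `per_window` raw counts, `normalized`
#'   per-window data frame, and `means` over windows of both.
#' @export
normalized_lzc <- function(ep, n_norm_surrogates = 10, seed = 1) {
  stopifnot(inherits(ep, "eeg_epochs"))
  bw <- binarize(ep)
  raw <- lzc_variants(bw)
  vars <- c("univariate_median", "concatenated", "joint")
  norm_rows <- lapply(seq_along(ep$windows), function(w) {
    win <- ep$windows[[w]]
    sur_counts <- vapply(seq_len(n_norm_surrogates), function(k) {
      sw <- phase_randomize(win, seed = seed + 7919L * w + k)
      sep <- structure(list(windows = list(sw), window_s = ep$window_s,
                            fs_hz = ep$fs_hz, labels = ep$labels,
                            state = ep$state), class = "eeg_epochs")
      unlist(lzc_variants(suppressWarnings(binarize(sep)))$per_window[vars])
    }, numeric(3L))
    sur_mean <- rowMeans(matrix(sur_counts, nrow = 3L))
    obs <- unlist(raw$per_window[w, vars])
    val <- ifelse(sur_mean > 0, obs / sur_mean, NA_real_)
    if (anyNA(val))
      warning("degenerate window ", w, ": surrogate complexity 0")
    stats::setNames(as.list(c(window = w, val)), c("window", vars))
  })
  normalized <- do.call(rbind, lapply(norm_rows, as.data.frame))
  raw$normalized <- normalized
  raw$n_norm_surrogates <- as.integer(n_norm_surrogates)
  raw$means <- c(raw$means,
                 stats::setNames(colMeans(normalized[vars]),
                                 paste0(vars, "_norm")))
  raw
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("<complexity_result> %d windows, %d channels%s\n",
              nrow(x$per_window), length(x$labels),
              if (!is.null(x$normalized))
                sprintf(", %d normalization surrogates",
                        x$n_norm_surrogates) else " (raw only)"))
  print(round(x$means, 4))
  invisible(x)
}
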