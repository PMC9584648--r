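#' Weighted and directed phase lag indices per window
#'
#' For every 10-s window the analytic signal of each channel is computed by
#' Hilbert transform and the pairwise cross-spectrum estimated per sample as
#' \eqn{C_{ij}(t) = a_i(t)\,\overline{a_j(t)}}.  The weighted phase lag
#' index is
#' \deqn{wPLI_{ij} = \frac{|E\{\Im(C_{ij})\}|}{E\{|\Im(C_{ij})|\}}}
#' with the expectation taken over within-window samples, and the directed
#' phase lag index is
#' \deqn{dPLI_{ij} = \frac{1}{N}\sum_{t=1}^{N} H(\Delta\phi_{ij}(t))}
#' with \eqn{\Delta\phi_{ij} = \phi_i - \phi_j} wrapped to \eqn{(-\pi,\pi]},
#' Heaviside \eqn{H(x>0)=1}, \eqn{H(0)=0.5}, \eqn{H(x<0)=0}.  Since
#' \eqn{\mathrm{sign}(\sin\Delta\phi_{ij}) = \mathrm{sign}(\Im C_{ij})},
#' both indices derive from the imaginary cross-spectrum samples.
#' `dPLI > 0.5` means the row channel phase-leads the column channel.
#'
#' @param ep alpha-band-filtered [epoch()]s (windows of at least 2 s).
#' @return object of class `conn_matrices`: per-window `wpli` and `dpli`
#'   arrays (channels x channels x windows), their time averages
#'   `wpli_avg` / `dpli_avg`, `labels`, and `corrected = FALSE`.
#' @export
phase_lag_indices <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (ep$window_s < 2) stop("windows must be at least 2 s for stable phases")
  nch <- length(ep$labels)
  nwin <- length(ep$windows)
  wpli <- array(0, c(nch, nch, nwin))
  dpli <- array(0.5, c(nch, nch, nwin))
  flat <- logical(nch)
  for (w in seq_len(nwin)) {
    win <- ep$windows[[w]]
    zero_ch <- apply(win, 1L, function(r) all(r == 0))
    flat <- flat | zero_ch
    A <- analytic_matrix(win)
    for (i in seq_len(nch - 1L)) {
      for (j in (i + 1L):nch) {
        if (zero_ch[i] || zero_ch[j]) next    # leave at 0 / 0.5
        C <- A[i, ] * Conj(A[j, ])
        pl <- pli_from_imcross(Im(C), mean(Mod(C)))
        wpli[i, j, w] <- wpli[j, i, w] <- pl["wpli"]
        dpli[i, j, w] <- pl["dpli"]
        dpli[j, i, w] <- 1 - pl["dpli"]
      }
    }
    for (d in seq_len(nch)) dpli[d, d, w] <- 0.5
  }
  if (any(flat))
    warning("all-zero channel(s): ", paste(ep$labels[flat], collapse = ", "),
            "; their pairs set to wPLI 0 / dPLI 0.5")
  new_conn(wpli, dpli, ep$labels, corrected = FALSE,
           window_s = ep$window_s, fs_hz = ep$fs_hz)
}

# wPLI and dPLI of one pair from the imaginary cross-spectrum samples z,
# with `scale` = E{|C_ij|}.  When E{|Im C|} is negligible relative to the
# cross-spectrum magnitude (zero-lag coupling up to numerical jitter) the
# pair carries no phase-lag information: wPLI 0, dPLI 0.5 by convention.
pli_from_imcross <- function(z, scale = 1, rel_tol = 1e-4) {
  denom <- mean(abs(z))
  if (denom <= rel_tol * scale)
    return(c(wpli = 0, dpli = 0.5))
  c(wpli = abs(mean(z)) / denom,
    dpli = mean((z > 0) + 0.5 * (z == 0)))
}

new_conn <- function(wpli, dpli, labels, corrected, window_s, fs_hz,
                     surrogate = NULL) {
  dimnames(wpli) <- dimnames(dpli) <- list(labels, labels, NULL)
  structure(list(
    wpli = wpli, dpli = dpli,
    wpli_avg = avg_slices(wpli), dpli_avg = avg_slices(dpli),
    labels = labels, corrected = corrected,
    window_s = window_s, fs_hz = fs_hz, surrogate = surrogate),
    class = "conn_matrices")
}

avg_slices <- function(a) {
  out <- apply(a, c(1L, 2L), mean)
  dimnames(out) <- dimnames(a)[1:2]
  out
}

#' @export
print.conn_matrices <- function(x, ...) {
  cat(sprintf("<conn_matrices> %d channels, %d windows (%g s), %s\n",
              length(x$labels), dim(x$wpli)[3L], x$window_s,
              if (x$corrected) "surrogate-corrected" else "uncorrected"))
  cat(sprintf("  mean wPLI %.3f, mean off-diagonal dPLI deviation %.3f\n",
              mean(x$wpli_avg[upper.tri(x$wpli_avg)]),
              mean(abs(x$dpli_avg[upper.tri(x$dpli_avg)] - 0.5))))
  invisible(x)
}

#' @export
summary.conn_matrices <- function(object, ...) {
  ut <- upper.tri(object$wpli_avg)
  structure(list(
    n_channels = length(object$labels),
    n_windows = dim(object$wpli)[3L],
    corrected = object$corrected,
    wpli = summary(object$wpli_avg[ut]),
    dpli_dev = summary(abs(object$dpli_avg[ut] - 0.5)),
    prop_retained = if (object$corrected) mean(object$wpli_avg[ut] > 0)
                    else NA_real_),
    class = "summary.conn_matrices")
}

#' @export
print.summary.conn_matrices <- function(x, ...) {
  cat(sprintf("Connectivity over %d channels, %d windows (%s)\n",
              x$n_channels, x$n_windows,
              if (x$corrected) "surrogate-corrected" else "uncorrected"))
  cat("time-averaged wPLI (upper triangle):\n"); print(x$wpli)
  cat("time-averaged |dPLI - 0.5|:\n"); print(x$dpli_dev)
  if (!is.na(x$prop_retained))
    cat(sprintf("fraction of pairs retained: %.3f\n", x$prop_retained))
  invisible(x)
}

#' Surrogate-testing configuration
#'
#' @param n_surrogates surrogates per channel pair per window (default 20;
#'   at least 19 when `alpha = 0.05` so the empirical p-value resolution
#'   `1/(n+1)` can reach the level).
#' @param alpha significance level (default 0.05).
#' @param method `"circular_shift"` (default: channel j circularly shifted
#'   by a uniform random offset of at least `min_shift_s`, preserving its
#'   spectrum and autocorrelation while destroying the phase relation) or
#'   `"sample_shuffle"` (random permutation of channel j's samples).
#' @param min_shift_s minimum circular shift in seconds (default 1).
#' @param dpli_sided `"two"` (default; test on `|dPLI - 0.5|`) or `"one"`.
#' @param seed integer seed for the dedicated surrogate generator.
#' @return object of class `surrogate_config`.
#' @export
surrogate_config <- function(n_surrogates = 20, alpha = 0.05,
                             method = c("circular_shift", "sample_shuffle"),
                             min_shift_s = 1, dpli_sided = c("two", "one"),
                             seed = 1) {
  method <- match.arg(method)
  dpli_sided <- match.arg(dpli_sided)
  if (1 / (n_surrogates + 1) > alpha)
    stop("n_surrogates = ", n_surrogates, " cannot resolve alpha = ", alpha,
         " (need at least ", ceiling(1 / alpha) - 1, ")")
  structure(list(n_surrogates = as.integer(n_surrogates), alpha = alpha,
                 method = method, min_shift_s = min_shift_s,
                 dpli_sided = dpli_sided, seed = as.integer(seed)),
            class = "surrogate_config")
}

#' Surrogate-data significance correction of phase-lag matrices
#'
#' For each channel pair and window, `n_surrogates` recomputations are made
#' with channel i kept intact and channel j scrambled.  Each observed value
#' is first bias-corrected by the mean of its surrogate set —
#' `wPLI' = max(0, wPLI - mean_surr)` and
#' `dPLI' = 0.5 + (dPLI - mean_surr)` (recentering preserves the
#' antisymmetry `dPLI_ij + dPLI_ji = 1`) — and retained only if it falls
#' outside the surrogate distribution at level `alpha` by rank test
#' (one-sided upper for wPLI; on `|dPLI - 0.5|` for dPLI).  Non-significant
#' connections are set to 0 (wPLI) and 0.5 (dPLI).  Windows are averaged
#' after correction.
#'
#' @param ep the alpha-band [epoch()]s the raw matrices came from.
#' @param raw uncorrected [phase_lag_indices()] result.
#' @param cfg a [surrogate_config()].
#' @return corrected `conn_matrices`.
#' @export
surrogate_correct <- function(ep, raw, cfg = surrogate_config()) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(raw, "conn_matrices"),
            inherits(cfg, "surrogate_config"))
  if (raw$corrected) stop("matrices are already corrected")
  nch <- length(ep$labels)
  nwin <- length(ep$windows)
  ns <- cfg$n_surrogates
  wpli <- raw$wpli
  dpli <- raw$dpli
  with_seed(cfg$seed, {
    for (w in seq_len(nwin)) {
      win <- ep$windows[[w]]
      N <- ncol(win)
      A <- analytic_matrix(win)
      min_shift <- max(1L, round(cfg$min_shift_s * ep$fs_hz))
      if (cfg$method == "circular_shift" && 2L * min_shift >= N)
        stop("window too short for min_shift_s = ", cfg$min_shift_s)
      for (i in seq_len(nch - 1L)) {
        ai <- A[i, ]
        for (j in (i + 1L):nch) {
          obs_w <- raw$wpli[i, j, w]
          obs_d <- raw$dpli[i, j, w]
          # columns: surrogate versions of channel j (spectrum preserved)
          if (cfg$method == "circular_shift") {
            offs <- sample(seq.int(min_shift, N - min_shift), ns,
                           replace = TRUE)
            idx <- vapply(offs, function(o) c(seq.int(o + 1L, N),
                                              seq_len(o)), integer(N))
          } else {
            idx <- vapply(seq_len(ns), function(k) sample.int(N),
                          integer(N))
          }
          Cs <- ai * Conj(matrix(A[j, ][idx], nrow = N))
          sur <- vapply(seq_len(ns), function(k)
            pli_from_imcross(Im(Cs[, k]), mean(Mod(Cs[, k]))),
            c(wpli = 0, dpli = 0))
          w_sur <- sur["wpli", ]
          d_sur <- sur["dpli", ]
          p_w <- (1 + sum(w_sur >= obs_w)) / (ns + 1)
          w_corr <- if (p_w <= cfg$alpha) max(0, obs_w - mean(w_sur)) else 0
          dev_obs <- if (cfg$dpli_sided == "two") abs(obs_d - 0.5)
                     else obs_d - 0.5
          dev_sur <- if (cfg$dpli_sided == "two") abs(d_sur - 0.5)
                     else d_sur - 0.5
          p_d <- (1 + sum(dev_sur >= dev_obs)) / (ns + 1)
          d_corr <- if (p_d <= cfg$alpha)
            min(1, max(0, 0.5 + obs_d - mean(d_sur))) else 0.5
          wpli[i, j, w] <- wpli[j, i, w] <- w_corr
          dpli[i, j, w] <- d_corr
          dpli[j, i, w] <- 1 - d_corr
        }
      }
    }
  })
  new_conn(wpli, dpli, raw$labels, corrected = TRUE,
           window_s = raw$window_s, fs_hz = raw$fs_hz, surrogate = cfg)
}

#' Node degree of the time-averaged wPLI matrix
#'
#' The summed connection strength from one electrode to all others: row
#' sums of the (corrected, time-averaged) wPLI matrix.  High-degree nodes
#' are the network hubs.
#'
#' @param m a [surrogate_correct()]ed `conn_matrices`.
#' @return named nonnegative numeric vector (class `degree_vector`).
#' @export
node_degree <- function(m) {
  stopifnot(inherits(m, "conn_matrices"))
  structure(rowSums(m$wpli_avg), class = "degree_vector")
}

#' Frontoparietal feedback-dominance summary
#'
#' Collects the time-averaged dPLI of every frontal-to-parietal channel
#' pair within each lateral hemisphere.  A mean above 0.5 means frontal
#' channels phase-lead parietal ones: feedback-dominant (anterior-to-
#' posterior) connectivity.  A hemisphere lacking frontal or parietal
#' coverage is reported as missing (`NA`), not an error.
#'
#' @param m a `conn_matrices` (rows lead when dPLI > 0.5).
#' @param montage an `eeg_montage` resolving all labels of `m`.
#' @return object of class `fp_summary`: `per_hemisphere` (named mean dPLI,
#'   `L` and `R`) and `pairs` (data frame hemisphere/frontal/parietal/dpli).
#' @export
frontoparietal_summary <- function(m, montage) {
  stopifnot(inherits(m, "conn_matrices"), inherits(montage, "eeg_montage"))
  un <- setdiff(m$labels, montage$label)
  if (length(un)) stop("montage does not resolve: ",
                       paste(un, collapse = ", "))
  pairs <- list()
  means <- c(L = NA_real_, R = NA_real_)
  for (h in c("L", "R")) {
    f <- intersect(montage_labels(montage, "F", h), m$labels)
    p <- intersect(montage_labels(montage, "P", h), m$labels)
    if (!length(f) || !length(p)) next
    grid <- expand.grid(frontal = f, parietal = p,
                        stringsAsFactors = FALSE)
    grid$hemisphere <- h
    grid$dpli <- m$dpli_avg[cbind(grid$frontal, grid$parietal)]
    pairs[[h]] <- grid[, c("hemisphere", "frontal", "parietal", "dpli")]
    means[h] <- mean(grid$dpli)
  }
  structure(list(per_hemisphere = means,
                 pairs = if (length(pairs)) do.call(rbind, pairs)
                         else data.frame()),
            class = "fp_summary")
}

#' @export
print.fp_summary <- function(x, ...) {
  cat("<fp_summary> mean frontal->parietal dPLI per hemisphere\n")
  print(round(x$per_hemisphere, 4))
  for (h in names(x$per_hemisphere)) {
    v <- x$per_hemisphere[h]
    if (is.na(v)) cat(sprintf("  %s: missing frontal or parietal coverage\n", h))
    else cat(sprintf("  %s: %s (mean dPLI %s 0.5)\n", h,
                     if (v > 0.5) "feedback-dominant"
                     else if (v < 0.5) "feedforward-dominant" else "neutral",
                     if (v > 0.5) ">" else if (v < 0.5) "<" else "="))
  }
  invisible(x)
}

#' Anterior-posterior hub index and hub channel
#'
#' The degree-weighted mean of the montage's anterior-posterior coordinate:
#' `score = sum(deg * y) / sum(deg)` in \[-1, 1\], positive when connection
#' degree concentrates frontally ("anteriorized" hubs), negative when
#' posteriorly.  The hub channel is the degree argmax (ties broken by label
#' order).  With an all-zero degree vector the score is undefined (`NA`
#' with a warning).
#'
#' @param deg a [node_degree()] vector.
#' @param montage an `eeg_montage`.
#' @return list with `score`, `hub_channel`, `degree`.
#' @export
hub_index <- function(deg, montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  d <- unclass(deg)
  y <- montage$y[match(names(d), montage$label)]
  if (anyNA(y)) stop("montage does not resolve: ",
                     paste(names(d)[is.na(y)], collapse = ", "))
  s <- sum(d)
  if (s <= 0) {
    warning("all-zero degree vector: hub index undefined")
    return(list(score = NA_real_, hub_channel = NA_character_, degree = d))
  }
  list(score = sum(d * y) / s,
       hub_channel = names(d)[which.max(d)],
       degree = d)
}

#' Hub directionality: per-channel mean dPLI
#'
#' For each channel the mean time-averaged dPLI to all other channels.
#' Values above 0.5 label the node a source (it phase-leads the network),
#' below 0.5 a target.
#'
#' @param m a `conn_matrices`.
#' @return named numeric vector.
#' @export
hub_directionality <- function(m) {
  stopifnot(inherits(m, "conn_matrices"))
  n <- length(m$labels)
  (rowSums(m$dpli_avg) - 0.5) / (n - 1)
}

#' Heatmap of a time-averaged connectivity matrix
#'
#' Channels are ordered frontal, central, parietal, temporal, occipital
#' within hemisphere, matching the conventional figure layout.
#'
#' @param x a `conn_matrices`.
#' @param montage optional `eeg_montage` used for region ordering.
#' @param which `"wpli"` or `"dpli"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.conn_matrices <- function(x, montage = NULL,
                               which = c("wpli", "dpli"), ...) {
  which <- match.arg(which)
  m <- if (which == "wpli") x$wpli_avg else x$dpli_avg
  ord <- seq_along(x$labels)
  if (!is.null(montage)) {
    key <- match(x$labels, montage$label)
    ord <- order(match(montage$hemisphere[key], c("L", "Z", "R")),
                 match(montage$region[key], c("F", "C", "P", "T", "O")))
  }
  m <- m[ord, ord]
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, ]), axes = FALSE,
                  xlab = "", ylab = "",
                  main = if (which == "wpli") "time-averaged wPLI"
                         else "time-averaged dPLI", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}
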