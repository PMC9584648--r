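#' Multichannel EEG recording container
#'
#' A labeled channels-by-samples matrix with a sampling rate and a state tag.
#' All estimation in the package starts from this container.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param labels character vector of unique channel names; defaults to the
#'   rownames of `data`.
#' @param state one of `"baseline"`, `"anesthesia"`, `"post"`, `"synthetic"`.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, labels = rownames(data),
                          state = "synthetic") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric matrix (channels x samples)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("label count (", length(labels), ") != channel count (",
         nrow(data), ")")
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  if (length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0)
    stop("fs_hz must be a single positive number")
  if (!all(is.finite(data))) stop("all samples must be finite")
  state <- match.arg(state, c("baseline", "anesthesia", "post", "synthetic"))
  rownames(data) <- labels
  structure(list(data = data, labels = labels, fs_hz = fs_hz, state = state),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), state: %s\n",
              nrow(x$data), ncol(x$data), x$fs_hz,
              ncol(x$data) / x$fs_hz, x$state))
  invisible(x)
}

#' Read a recording from disk
#'
#' Two formats are supported.  `"matrix"` is a delimited text file whose
#' header row holds the channel labels and whose rows are time samples; the
#' sampling rate comes from a JSON sidecar (`<path>.json` with fields `fs_hz`
#' and optionally `state`) or from `fs_hint`.  `"edf"` is the 16-bit European
#' Data Format.
#'
#' @param path input file.
#' @param format `"edf"` or `"matrix"`.
#' @param fs_hint sampling rate in Hz, used for matrix files without a
#'   sidecar.
#' @param state optional state tag overriding what the file carries.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("matrix", "edf"),
                           fs_hint = NULL, state = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") {
    rec <- read_edf(path)
    if (!is.null(state)) rec$state <- match.arg(state, c("baseline",
      "anesthesia", "post", "synthetic"))
    return(rec)
  }
  m <- utils::read.delim(path, check.names = FALSE)
  labels <- colnames(m)
  if (anyDuplicated(labels)) stop("duplicate channel labels in header")
  side <- paste0(path, ".json")
  fs <- fs_hint
  st <- state
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- fs %||% meta$fs_hz
    st <- st %||% meta$state
  }
  if (is.null(fs))
    stop("sampling rate missing: no sidecar ", basename(side),
         " and no fs_hint given")
  eeg_recording(t(as.matrix(m)), fs_hz = as.numeric(fs), labels = labels,
                state = as.character(st %||% "synthetic"))
}

#' Write a recording to disk
#'
#' @param rec an [eeg_recording()].
#' @param path output file.
#' @param format `"matrix"` (tab-delimited, header of labels, JSON sidecar
#'   with `fs_hz`/`state`) or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("matrix", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "edf") return(write_edf(rec, path))
  m <- t(rec$data)
  colnames(m) <- rec$labels
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs_hz = rec$fs_hz, state = rec$state),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# ---- minimal EDF (European Data Format) support -----------------------------
# 256-byte fixed header + 256 bytes per signal, then 1-second data records of
# 16-bit little-endian integers.  Requires an integer sampling rate; the
# trailing partial second is dropped on write.

pad <- function(s, n) formatC(substr(s, 1, n), width = n, flag = "-")

#' @rdname read_recording
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1L))
  state <- sub("^state=", "", fld(89, 80))
  if (!state %in% c("baseline", "anesthesia", "post", "synthetic"))
    state <- "synthetic"
  n_rec <- as.integer(fld(237, 8))
  dur <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  sfld <- function(off, len) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, off * ns + (i - 1L) * len + 1L,
                    off * ns + i * len)), "")
  }
  labels <- sfld(0, 16)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i)
    substr(sig_hdr, (16 + 80 + 8) * ns + (i - 1L) * 8 + 1L,
           (16 + 80 + 8) * ns + i * 8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i)
    substr(sig_hdr, (16 + 80 + 8 + 8) * ns + (i - 1L) * 8 + 1L,
           (16 + 80 + 8 + 8) * ns + i * 8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i)
    substr(sig_hdr, (16 + 80 + 8 + 16) * ns + (i - 1L) * 8 + 1L,
           (16 + 80 + 8 + 16) * ns + i * 8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i)
    substr(sig_hdr, (16 + 80 + 8 + 24) * ns + (i - 1L) * 8 + 1L,
           (16 + 80 + 8 + 24) * ns + i * 8), ""))
  nsamp <- as.integer(vapply(seq_len(ns), function(i)
    substr(sig_hdr, (16 + 80 + 8 + 32 + 80) * ns + (i - 1L) * 8 + 1L,
           (16 + 80 + 8 + 32 + 80) * ns + i * 8), ""))
  if (length(unique(nsamp)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- nsamp[1L] / dur
  data <- matrix(0, nrow = ns, ncol = n_rec * nsamp[1L])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", nsamp[s], size = 2L, signed = TRUE,
                   endian = "little")
      phys <- pmin_[s] + (v - dmin_[s]) * (pmax_[s] - pmin_[s]) /
        (dmax_[s] - dmin_[s])
      data[s, ((r - 1L) * nsamp[s] + 1L):(r * nsamp[s])] <- phys
    }
  }
  eeg_recording(data, fs_hz = fs, labels = labels, state = state)
}

#' @rdname write_recording
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  # physical range rounded UP to 2 significant digits so "+/-%.1e" always
  # fits the 8-char EDF field and never clips a sample
  up2 <- function(v) {
    e <- 10^(floor(log10(v)) - 1)
    ceiling(v / e) * e
  }
  pmax_ <- up2(pmax(apply(abs(x), 1L, max), 1e-9))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad(paste0("state=", rec$state), 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(as.character(256L * (ns + 1L)), 8), pad("", 44),
    pad(as.character(n_rec), 8), pad("1", 8), pad(as.character(ns), 4))
  writeBin(charToRaw(hdr), con)
  w <- function(vals, len) writeBin(charToRaw(paste0(
    vapply(vals, pad, "", n = len), collapse = "")), con)
  w(rec$labels, 16)                           # labels
  w(rep("", ns), 80)                          # transducer
  w(rep("uV", ns), 8)                         # physical dimension
  w(sprintf("%.1e", -pmax_), 8)               # physical min
  w(sprintf("%.1e", pmax_), 8)                # physical max
  w(rep("-32767", ns), 8)                     # digital min
  w(rep("32767", ns), 8)                      # digital max
  w(rep("", ns), 80)                          # prefiltering
  w(rep(as.character(as.integer(fs)), ns), 8) # samples per record
  w(rep("", ns), 32)                          # reserved
  for (r in seq_len(n_rec)) for (s in seq_len(ns)) {
    seg <- x[s, ((r - 1L) * fs + 1L):(r * fs)]
    dig <- pmin(pmax(as.integer(round(seg / pmax_[s] * 32767)),
                     -32767L), 32767L)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}
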