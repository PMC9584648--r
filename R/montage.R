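#' Construct a symmetric scalp montage
#'
#' Builds a reduced electrode montage covering the five scalp regions used to
#' order connectivity figures — frontal (F), central (C), parietal (P),
#' temporal (T) and occipital (O) — on both lateral hemispheres (L/R).
#' Channels are placed on a schematic head with `x` in \[-1, 1\] (left
#' negative) and `y` in \[-1, 1\] increasing from posterior to anterior, so
#' frontal channels have `y > 0` and occipital channels `y < 0`.
#'
#' @param n_channels even integer, at least 10 (one channel per region per
#'   hemisphere is the minimal cover).
#' @return an object of class `eeg_montage`: a data frame with columns
#'   `label`, `region`, `hemisphere`, `x`, `y`.
#' @examples
#' make_montage(10)
#' @export
make_montage <- function(n_channels) {
  if (length(n_channels) != 1L || !is.finite(n_channels) ||
      n_channels != round(n_channels))
    stop("n_channels must be a single integer")
  if (n_channels %% 2L != 0L)
    stop("n_channels must be even (equal left/right coverage); got ",
         n_channels)
  if (n_channels < 10L)
    stop("n_channels = ", n_channels,
         " cannot cover all five regions (F, C, P, T, O) per hemisphere; ",
         "need at least 10 channels")
  regions <- c("F", "C", "P", "T", "O")
  # y sums to zero over the five regions so a symmetric montage with uniform
  # degree has a zero anterior-posterior hub score
  region_y <- c(F = 0.8, C = 0.3, P = -0.4, T = 0.1, O = -0.8)
  region_x <- c(F = 0.35, C = 0.45, P = 0.4, T = 0.85, O = 0.3)
  per_hemi <- n_channels / 2L
  # cycle F,C,P,T,O so extra channels densify regions evenly
  reg_seq <- rep_len(regions, per_hemi)
  rows <- list()
  for (hemi in c("L", "R")) {
    sgn <- if (hemi == "L") -1 else 1
    idx_in_region <- integer(0)
    cnt <- stats::setNames(integer(5), regions)
    for (r in reg_seq) {
      cnt[r] <- cnt[r] + 1L
      k <- cnt[r]
      # deterministic within-region spread along the anterior-posterior axis
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("%s%s%d", r, hemi, k),
        region = r,
        hemisphere = hemi,
        x = sgn * region_x[[r]],
        y = region_y[[r]] + 0.08 * ((k - 1L) %% 3L) * (-1)^k,
        stringsAsFactors = FALSE
      )
    }
  }
  mont <- do.call(rbind, rows)
  rownames(mont) <- NULL
  class(mont) <- c("eeg_montage", "data.frame")
  mont
}

#' Read / write a montage CSV (label,region,hemisphere,x,y)
#'
#' @param path file path.
#' @return `read_montage` returns an `eeg_montage`.
#' @export
read_montage <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "region", "hemisphere", "x", "y")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("montage file lacks columns: ",
                         paste(miss, collapse = ", "))
  as_montage(m[need])
}

#' @rdname read_montage
#' @param montage an `eeg_montage`.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "eeg_montage"))
  utils::write.csv(as.data.frame(montage), path, row.names = FALSE)
  invisible(path)
}

#' Coerce a data frame to a validated montage
#'
#' @param m data frame with columns label, region, hemisphere, x, y.
#' @export
as_montage <- function(m) {
  if (anyDuplicated(m$label)) stop("duplicate montage labels")
  if (!all(m$region %in% c("F", "C", "P", "T", "O")))
    stop("montage regions must be in {F, C, P, T, O}")
  if (!all(m$hemisphere %in% c("L", "R", "Z")))
    stop("montage hemispheres must be in {L, R, Z}")
  if (!all(is.finite(m$x)) || !all(is.finite(m$y)) ||
      any(abs(m$y) > 1) || any(abs(m$x) > 1))
    stop("montage coordinates must be finite and within [-1, 1]")
  class(m) <- c("eeg_montage", "data.frame")
  m
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels\n", nrow(x)))
  tab <- table(x$region, x$hemisphere)
  print(tab)
  invisible(x)
}

# labels of a montage belonging to region/hemisphere (either may be NULL)
montage_labels <- function(montage, region = NULL, hemisphere = NULL) {
  keep <- rep(TRUE, nrow(montage))
  if (!is.null(region)) keep <- keep & montage$region %in% region
  if (!is.null(hemisphere)) keep <- keep & montage$hemisphere %in% hemisphere
  montage$label[keep]
}
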