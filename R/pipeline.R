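#' Configuration for a case analysis
#'
#' One object governs the whole run; the effective configuration is embedded
#' in every report together with its MD5 hash.
#'
#' @param window_s epoch length in seconds (default 10).
#' @param alpha_band connectivity band in Hz (default `c(8, 13)`).
#' @param fs_target downsampling target (default 250 Hz).
#' @param hp_hz,lp_hz,notch_hz broadband filter cutoffs (0.1, 45, 60 Hz).
#' @param reject_threshold amplitude bound for window rejection (150).
#' @param surrogate a [surrogate_config()].
#' @param n_norm_surrogates phase-randomized surrogates per window for LZC
#'   normalization (default 10).
#' @param tol_fp_dpli,tol_hub,tol_lzc null-classification tolerances for the
#'   frontoparietal dPLI delta (0.01), hub-index delta (0.05) and normalized
#'   LZC delta (0.01).
#' @param alpha_power_band band for the per-channel power block (8-13 Hz).
#' @param seed base seed for LZC normalization surrogates.
#' @return object of class `case_config`.
#' @export
case_config <- function(window_s = 10, alpha_band = c(8, 13),
                        fs_target = 250, hp_hz = 0.1, lp_hz = 45,
                        notch_hz = 60, reject_threshold = 150,
                        surrogate = surrogate_config(),
                        n_norm_surrogates = 10,
                        tol_fp_dpli = 0.01, tol_hub = 0.05, tol_lzc = 0.01,
                        alpha_power_band = c(8, 13), seed = 1) {
  structure(list(window_s = window_s, alpha_band = alpha_band,
                 fs_target = fs_target, hp_hz = hp_hz, lp_hz = lp_hz,
                 notch_hz = notch_hz, reject_threshold = reject_threshold,
                 surrogate = surrogate,
                 n_norm_surrogates = n_norm_surrogates,
                 tol_fp_dpli = tol_fp_dpli, tol_hub = tol_hub,
                 tol_lzc = tol_lzc, alpha_power_band = alpha_power_band,
                 seed = as.integer(seed)),
            class = "case_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f)
  unname(tools::md5sum(f))
}

# full single-state analysis: conditioning -> connectivity + complexity
analyze_state <- function(rec, montage, config, drop_labels = character()) {
  pp <- preprocess(rec, drop_labels = drop_labels,
                   fs_target = config$fs_target, hp_hz = config$hp_hz,
                   lp_hz = config$lp_hz, notch_hz = config$notch_hz)
  un <- setdiff(pp$labels, montage$label)
  if (length(un)) stop("montage does not resolve: ",
                       paste(un, collapse = ", "))
  ep <- epoch(pp, config$window_s)
  bad <- vapply(ep$windows, function(w)
    any(abs(w) > config$reject_threshold), logical(1))
  if (any(bad))
    message("state '", rec$state, "': rejected ", sum(bad),
            " window(s) exceeding ", config$reject_threshold)
  ep$windows <- ep$windows[!bad]
  if (length(ep$windows) < 3L)
    stop("state '", rec$state, "' has only ", length(ep$windows),
         " usable window(s); need at least 3")
  # alpha filtering on the continuous signal, then the same window cut,
  # so connectivity windows carry no filter edge transients
  alpha_ep <- epoch(bandpass_alpha(pp, config$alpha_band), config$window_s)
  alpha_ep$windows <- alpha_ep$windows[!bad]
  conn <- surrogate_correct(alpha_ep, phase_lag_indices(alpha_ep),
                            config$surrogate)
  deg <- node_degree(conn)
  hub <- hub_index(deg, montage)
  lzc <- normalized_lzc(ep, config$n_norm_surrogates, seed = config$seed)
  list(state = rec$state,
       n_windows = length(ep$windows),
       connectivity = conn,
       degree = deg,
       fp = frontoparietal_summary(conn, montage),
       hub = hub,
       hub_directionality = hub_directionality(conn),
       alpha_power = band_power(ep, config$alpha_power_band[1L],
                                config$alpha_power_band[2L]),
       lzc = lzc)
}

classify_delta <- function(delta, tol, paradoxical_when = c("positive",
                                                            "negative")) {
  paradoxical_when <- match.arg(paradoxical_when)
  if (is.na(delta)) return(NA_character_)
  if (abs(delta) < tol) return("null")
  up <- delta > 0
  if ((up && paradoxical_when == "positive") ||
      (!up && paradoxical_when == "negative")) "paradoxical" else "canonical"
}

#' Run a baseline/anesthesia(/post) case analysis
#'
#' Each state runs conditioning, epoching and window rejection, then
#' alpha-band surrogate-corrected wPLI/dPLI connectivity (hubs, fronto-
#' parietal feedback, hub directionality) and broadband normalized LZC.
#' Anesthesia-minus-baseline deltas are classified per metric: under
#' anesthesia, *canonical* responses are a drop in frontoparietal feedback
#' dominance, hub anteriorization, and reduced complexity; the reverse
#' directions are *paradoxical*; deltas inside the configured tolerances
#' are *null*.  When a post-anesthetic recording is given, each metric is
#' additionally marked reversed if its post value returns to within
#' tolerance of baseline.
#'
#' @param baseline,anesthesia [eeg_recording()]s sharing labels (after
#'   drop lists).
#' @param post optional post-anesthetic recording.
#' @param montage an `eeg_montage` resolving all retained labels.
#' @param config a [case_config()].
#' @param drop_labels channels to drop from every state.
#' @param metadata optional one-row data frame of clinical metadata (as
#'   from [read_clinical()]), carried into the report.
#' @return object of class `case_report`.
#' @export
run_case <- function(baseline, anesthesia, post = NULL, montage,
                     config = case_config(), drop_labels = character(),
                     metadata = NULL) {
  stopifnot(inherits(baseline, "eeg_recording"),
            inherits(anesthesia, "eeg_recording"))
  keep <- function(r) sort(setdiff(r$labels, drop_labels))
  if (!identical(keep(baseline), keep(anesthesia)))
    stop("baseline and anesthesia recordings do not share channel labels")
  states <- list(baseline = analyze_state(baseline, montage, config,
                                          drop_labels),
                 anesthesia = analyze_state(anesthesia, montage, config,
                                            drop_labels))
  if (!is.null(post))
    states$post <- analyze_state(post, montage, config, drop_labels)
  fp_mean <- function(s) mean(s$fp$per_hemisphere, na.rm = TRUE)
  lzc_norm <- function(s, var) unname(s$lzc$means[[paste0(var, "_norm")]])
  vars <- c("univariate_median", "concatenated", "joint")
  deltas <- list(
    fp_dpli = fp_mean(states$anesthesia) - fp_mean(states$baseline),
    hub_index = states$anesthesia$hub$score - states$baseline$hub$score,
    lzc = stats::setNames(
      vapply(vars, function(v) lzc_norm(states$anesthesia, v) -
               lzc_norm(states$baseline, v), numeric(1)), vars))
  classification <- list(
    fp_dpli = classify_delta(deltas$fp_dpli, config$tol_fp_dpli,
                             paradoxical_when = "positive"),
    hub_index = classify_delta(deltas$hub_index, config$tol_hub,
                               paradoxical_when = "negative"),
    lzc = stats::setNames(vapply(vars, function(v)
      classify_delta(deltas$lzc[[v]], config$tol_lzc,
                     paradoxical_when = "positive"), character(1)), vars))
  reversibility <- NULL
  if (!is.null(post)) {
    within <- function(a, b, tol) !is.na(a) && !is.na(b) && abs(a - b) <= tol
    reversibility <- list(
      fp_dpli = within(fp_mean(states$post), fp_mean(states$baseline),
                       config$tol_fp_dpli),
      hub_index = within(states$post$hub$score, states$baseline$hub$score,
                         config$tol_hub),
      lzc = stats::setNames(vapply(vars, function(v)
        within(lzc_norm(states$post, v), lzc_norm(states$baseline, v),
               config$tol_lzc), logical(1)), vars))
  }
  structure(list(metadata = metadata, states = states, deltas = deltas,
                 classification = classification,
                 reversibility = reversibility, config = config,
                 config_hash = config_hash(config)),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("<case_report>", paste(names(x$states), collapse = " / "), "\n")
  cat(sprintf("  frontoparietal dPLI delta: %+.4f  [%s]\n",
              x$deltas$fp_dpli, x$classification$fp_dpli))
  cat(sprintf("  hub index delta:           %+.4f  [%s]\n",
              x$deltas$hub_index, x$classification$hub_index))
  for (v in names(x$deltas$lzc))
    cat(sprintf("  normalized LZC (%s) delta: %+.4f  [%s]\n",
                v, x$deltas$lzc[[v]], x$classification$lzc[[v]]))
  if (!is.null(x$reversibility))
    cat("  reversed at post:",
        paste(names(unlist(x$reversibility))[unlist(x$reversibility)],
              collapse = ", "), "\n")
  cat("  config hash:", x$config_hash, "\n")
  invisible(x)
}

#' @export
summary.case_report <- function(object, ...) {
  s <- lapply(object$states, function(st) c(
    n_windows = st$n_windows,
    fp_dpli_mean = mean(st$fp$per_hemisphere, na.rm = TRUE),
    hub_index = st$hub$score,
    st$lzc$means))
  out <- list(per_state = s, deltas = object$deltas,
              classification = object$classification)
  class(out) <- "summary.case_report"
  out
}

#' @export
print.summary.case_report <- function(x, ...) {
  for (st in names(x$per_state)) {
    cat("--", st, "--\n")
    print(round(x$per_state[[st]], 4))
  }
  cat("-- deltas (anesthesia - baseline) --\n")
  print(lapply(x$deltas, round, 4))
  cat("-- classification --\n")
  print(x$classification)
  invisible(x)
}

#' Serialize a case report to JSON
#'
#' Writes the per-state metric blocks (frontoparietal means and pairs,
#' hub index and channel, degree and hub-directionality vectors, alpha
#' power, LZC means), the deltas, the classification, the reversibility
#' block and the effective configuration with its hash.  Deterministic for
#' identical inputs, configuration and seed.
#'
#' @param report a [run_case()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  stopifnot(inherits(report, "case_report"))
  st <- lapply(report$states, function(s) list(
    state = s$state, n_windows = s$n_windows,
    fp_per_hemisphere = as.list(s$fp$per_hemisphere),
    fp_pairs = s$fp$pairs,
    hub_index = s$hub$score, hub_channel = s$hub$hub_channel,
    degree = as.list(unclass(s$degree)),
    hub_directionality = as.list(s$hub_directionality),
    alpha_power = as.list(s$alpha_power),
    lzc_means = as.list(s$lzc$means),
    lzc_per_window = s$lzc$per_window,
    lzc_normalized = s$lzc$normalized))
  out <- list(states = st, deltas = report$deltas,
              classification = report$classification,
              reversibility = report$reversibility,
              metadata = report$metadata,
              config = unclass_deep(report$config),
              config_hash = report$config_hash)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Correlation of alpha-power change with node-degree change
#'
#' Checks whether the anesthetic-induced change in per-channel alpha power
#' explains the change in node degree: Spearman rank correlation across
#' channels with a seeded permutation p-value.
#'
#' @param report a [run_case()] result (needs baseline and anesthesia).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @return list with `rho`, `p_value`, `n_channels`; `rho` is `NA` with a
#'   warning when either delta vector is constant.
#' @export
alpha_power_degree_check <- function(report, n_perm = 10000, seed = 1) {
  stopifnot(inherits(report, "case_report"))
  b <- report$states$baseline
  a <- report$states$anesthesia
  d_pow <- a$alpha_power[names(b$alpha_power)] - b$alpha_power
  d_deg <- unclass(a$degree)[names(b$degree)] - unclass(b$degree)
  n <- length(d_pow)
  if (n < 5L) stop("need at least 5 channels; got ", n)
  if (stats::sd(d_pow) == 0 || stats::sd(d_deg) == 0) {
    warning("constant delta vector: correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n_channels = n))
  }
  rho <- stats::cor(d_pow, d_deg, method = "spearman")
  null_rho <- with_seed(seed, vapply(seq_len(n_perm), function(k)
    stats::cor(d_pow, sample(d_deg), method = "spearman"), numeric(1)))
  p <- (1 + sum(abs(null_rho) >= abs(rho))) / (n_perm + 1)
  list(rho = unname(rho), p_value = p, n_channels = n)
}

#' Read and validate a clinical metadata table
#'
#' Expects CSV columns Case, Age, Sex, Etiology, State, Diagnose, the six
#' CRS-R subscales (Auditory, Visual, Motor, Oromotor, Communication,
#' Arousal) and Total.  Every row's Total must equal the sum of its six
#' subscales; offending rows are rejected with an error naming them.
#'
#' @param path CSV file.
#' @param validate check subscale sums (default TRUE).
#' @return data frame of validated rows.
#' @export
read_clinical <- function(path, validate = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  sub_cols <- c("Auditory", "Visual", "Motor", "Oromotor",
                "Communication", "Arousal")
  need <- c("Case", sub_cols, "Total")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (validate) {
    sums <- rowSums(d[sub_cols])
    bad <- which(sums != d$Total)
    if (length(bad))
      stop("CRS-R total does not match subscale sum for case(s): ",
           paste(d$Case[bad], collapse = ", "),
           " (stated ", paste(d$Total[bad], collapse = ", "),
           ", computed ", paste(sums[bad], collapse = ", "), ")")
  }
  d
}
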