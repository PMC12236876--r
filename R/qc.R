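#' Quality-control rule thresholds
#'
#' Defaults for the erroneous-recording screen and drift correction. The
#' study's screening intent is that sensor force stays zero whenever the
#' insole is unloaded; these numeric rule values are package defaults
#' justified as "physically implausible under normal wear", not published
#' constants.
#'
#' @param window_s rolling lower-envelope window for drift estimation (s).
#' @param tolerance_bw per-channel baseline (xBW of channel force) below
#'   which no correction is applied.
#' @param fatal_offset_bw persistent per-channel baseline (xBW) beyond
#'   which a session is unrecoverable (`drift_excessive`).
#' @param max_loaded_frac rule (a): fraction of samples at or above the
#'   overall load threshold beyond which a session with no unloaded
#'   interval is implausible.
#' @param min_unload_gap_s rule (a): minimum credible unloaded interval
#'   (swing/rest) in seconds.
#' @param neg_thresh_bw,max_neg_frac rule (b): a channel more negative
#'   than `-neg_thresh_bw` xBW for more than `max_neg_frac` of samples is
#'   flagged.
#' @param min_duration_s rule (c): minimum usable session duration.
#' @return named list of rule values.
#' @export
qc_rules <- function(window_s = 30, tolerance_bw = 0.02,
                     fatal_offset_bw = 0.5, max_loaded_frac = 0.95,
                     min_unload_gap_s = 2, neg_thresh_bw = 0.05,
                     max_neg_frac = 0.01, min_duration_s = 60) {
  list(window_s = window_s, tolerance_bw = tolerance_bw,
       fatal_offset_bw = fatal_offset_bw,
       max_loaded_frac = max_loaded_frac,
       min_unload_gap_s = min_unload_gap_s,
       neg_thresh_bw = neg_thresh_bw, max_neg_frac = max_neg_frac,
       min_duration_s = min_duration_s)
}

# Chunked rolling lower envelope: minimum over non-overlapping windows of
# window_s, then the minimum of each window and its two neighbours,
# expanded back to sample resolution. O(n); adequate because unloaded
# swing/rest phases recur within any 30 s of normal wear.
lower_envelope <- function(x, window_n) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  n_chunks <- ceiling(n / window_n)
  grp <- rep(seq_len(n_chunks), each = window_n, length.out = n)
  mins <- vapply(split(x, grp), min, numeric(1))
  if (n_chunks > 1) {
    sm <- pmin(mins, c(mins[-1], mins[n_chunks]),
               c(mins[1], mins[-n_chunks]))
  } else sm <- mins
  rep(sm, times = tabulate(grp))
}

new_qc_report <- function(recording, flags = character(0),
                          offsets = c(heel = 0, mid = 0, fore = 0),
                          corrected = FALSE) {
  fatal <- c("drift_excessive", "constant_offset", "too_short",
             "negative_rail")
  structure(list(participant_id = recording$participant_id,
                 day = recording$day, session = recording$session,
                 offsets_n = offsets, corrected = corrected,
                 flags = flags,
                 disposition = if (any(flags %in% fatal)) "drop" else
                   "keep"),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s day %d session %d: %s\n", x$participant_id,
              x$day, x$session, x$disposition))
  if (length(x$flags) > 0)
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  if (x$corrected)
    cat(sprintf("  baseline removed (N): heel %.2f, mid %.2f, fore %.2f\n",
                x$offsets_n[["heel"]], x$offsets_n[["mid"]],
                x$offsets_n[["fore"]]))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(participant_id = x$participant_id, day = x$day,
             session = x$session, corrected = x$corrected,
             offset_heel_n = x$offsets_n[["heel"]],
             offset_mid_n = x$offsets_n[["mid"]],
             offset_fore_n = x$offsets_n[["fore"]],
             flags = paste(x$flags, collapse = ";"),
             disposition = x$disposition, stringsAsFactors = FALSE)
}

#' Detect and remove nonphysical baseline drift
#'
#' Estimates each channel's baseline as its rolling lower envelope
#' (chunked minimum over `window_s`, smoothed across neighbouring
#' windows): under normal wear, unloaded swing and rest phases recur
#' within any window, so the lower envelope tracks a nonphysical offset
#' while staying at zero on clean signal. Where the envelope exceeds
#' `tolerance_bw` xBW it is subtracted and the output is clipped at zero;
#' channels within tolerance are left untouched, so clean recordings pass
#' through unchanged and the operation is idempotent.
#'
#' A session whose baseline never returns near zero -- the estimated-load
#' offset implied by the channel envelopes stays above `fatal_offset_bw`
#' xBW throughout (e.g. a whole-session initialization offset) -- cannot
#' be trusted at all: it is flagged `drift_excessive` and dropped without
#' correction. A session shorter than the window is flagged `too_short`
#' and dropped.
#'
#' @param recording an [insole_recording()].
#' @param bw_n body weight in newtons (converts xBW rule values to N).
#' @param rules a [qc_rules()] list.
#' @param geometry a [sensor_geometry()]; the fatal-offset check operates
#'   on the estimated-load scale.
#' @return list with `recording` (corrected copy) and `report`
#'   (a `qc_report`).
#' @export
correct_drift <- function(recording, bw_n, rules = qc_rules(),
                          geometry = sensor_geometry()) {
  stopifnot(inherits(recording, "insole_recording"))
  if (duration_s(recording) < rules$window_s)
    return(list(recording = recording,
                report = new_qc_report(recording, flags = "too_short")))
  window_n <- max(1L, round(rules$window_s * recording$sample_rate_hz))
  tol_n <- rules$tolerance_bw * bw_n
  chans <- c(heel = "f_heel", mid = "f_mid", fore = "f_fore")
  envs <- lapply(chans, function(ch)
    lower_envelope(recording[[ch]], window_n))

  # baseline expressed as the load offset it would induce; a session that
  # never comes near zero is unrecoverable
  env_load <- pmax(envs$heel * geometry$r_heel + envs$mid * geometry$r_mid +
                     envs$fore * geometry$r_fore, 0) /
    geometry$r_at / bw_n
  if (min(env_load) > rules$fatal_offset_bw)
    return(list(recording = recording,
                report = new_qc_report(recording,
                                       flags = "drift_excessive")))

  out <- recording
  offsets <- c(heel = 0, mid = 0, fore = 0)
  corrected <- FALSE
  flags <- character(0)
  for (nm in names(chans)) {
    x <- recording[[chans[[nm]]]]
    env <- envs[[nm]]
    sub <- env > tol_n
    if (any(sub)) {
      x[sub] <- x[sub] - env[sub]
      out[[chans[[nm]]]] <- pmax(x, 0)
      offsets[[nm]] <- mean(env[sub])
      corrected <- TRUE
    } else if (any(x < 0)) {
      # no baseline to remove, but negatives are nonphysical post-QC
      out[[chans[[nm]]]] <- pmax(x, 0)
    }
  }
  list(recording = out,
       report = new_qc_report(recording, flags = unique(flags),
                              offsets = offsets, corrected = corrected))
}

#' Flag erroneous recordings
#'
#' Report-only screen for sessions corrupted by incorrect sensor
#' initialization or insole misfit. Rules (all fatal):
#' (a) `constant_offset`: the estimated load is at or above the overall
#' threshold for more than `max_loaded_frac` of samples and no unloaded
#' interval of at least `min_unload_gap_s` exists -- no swing or rest
#' ever, which is physically implausible;
#' (b) `negative_rail`: some channel reads below `-neg_thresh_bw` xBW for
#' more than `max_neg_frac` of samples;
#' (c) `too_short`: duration under `min_duration_s`.
#'
#' @param recording an [insole_recording()] (nonempty).
#' @param bw_n body weight in newtons.
#' @param geometry a [sensor_geometry()] (rule (a) operates on the
#'   estimated load).
#' @param rules a [qc_rules()] list.
#' @param overall_threshold_bw loading threshold defining "loaded"
#'   samples for rule (a) (default 0.3 xBW).
#' @return a `qc_report`.
#' @export
flag_erroneous <- function(recording, bw_n, geometry = sensor_geometry(),
                           rules = qc_rules(),
                           overall_threshold_bw = 0.3) {
  stopifnot(inherits(recording, "insole_recording"))
  if (n_samples(recording) == 0)
    stop("recording is empty", call. = FALSE)
  flags <- character(0)
  if (duration_s(recording) < rules$min_duration_s)
    flags <- c(flags, "too_short")
  n <- n_samples(recording)
  neg_n <- -rules$neg_thresh_bw * bw_n
  neg_frac <- vapply(list(recording$f_heel, recording$f_mid,
                          recording$f_fore),
                     function(x) mean(x < neg_n), numeric(1))
  if (any(neg_frac > rules$max_neg_frac))
    flags <- c(flags, "negative_rail")
  load <- estimate_tendon_load(recording, geometry, bw_n)$load_bw
  loaded <- load >= overall_threshold_bw
  if (mean(loaded) > rules$max_loaded_frac) {
    gap_n <- rules$min_unload_gap_s * recording$sample_rate_hz
    r <- rle(loaded)
    has_gap <- any(!r$values & r$lengths >= gap_n)
    if (!has_gap) flags <- c(flags, "constant_offset")
  }
  new_qc_report(recording, flags = flags)
}

#' Run full per-recording quality control
#'
#' Applies [correct_drift()] then [flag_erroneous()]; the returned report
#' merges flags from both stages.
#'
#' @inheritParams flag_erroneous
#' @param rules a [qc_rules()] list.
#' @return list with `recording` (corrected copy) and `report`.
#' @export
qc_recording <- function(recording, bw_n, geometry = sensor_geometry(),
                         rules = qc_rules(), overall_threshold_bw = 0.3) {
  dr <- correct_drift(recording, bw_n, rules, geometry)
  if (dr$report$disposition == "drop")
    return(dr)
  er <- flag_erroneous(dr$recording, bw_n, geometry, rules,
                       overall_threshold_bw)
  report <- new_qc_report(recording,
                          flags = unique(c(dr$report$flags, er$flags)),
                          offsets = dr$report$offsets_n,
                          corrected = dr$report$corrected)
  list(recording = dr$recording, report = report)
}

#' Protocol adherence check
#'
#' A participant who wore the insole for only a small part of each day
#' (e.g. only while exercising) does not represent habitual loading;
#' such participants are excluded. The criterion is the median daily
#' total loading time (hours at or above the overall threshold) falling
#' below a configurable minimum.
#'
#' @param day_df day-level summaries of one participant (data frame with
#'   a `t_load_h` column; see [day_summaries()]).
#' @param min_median_daily_loading_h exclusion threshold in hours.
#' @return `"keep"` or `"exclude"`.
#' @export
check_adherence <- function(day_df, min_median_daily_loading_h = 4) {
  stopifnot(is.data.frame(day_df), nrow(day_df) >= 1)
  if (stats::median(day_df$t_load_h) < min_median_daily_loading_h)
    "exclude" else "keep"
}
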