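#' Loading thresholds
#'
#' The two loading magnitude thresholds delimiting cumulative load
#' accumulation: the overall threshold (default 0.3 xBW, the load of the
#' lowest-loading tendon exercise, seated heel raises) and the high-level
#' threshold (default 3.0 xBW, approximately the peak Achilles load of
#' walking, so loading above it is attributed to dynamic activity).
#'
#' @param overall overall threshold in xBW (> 0).
#' @param high high-level threshold in xBW (> overall).
#' @return An object of class `load_thresholds`.
#' @export
load_thresholds <- function(overall = 0.3, high = 3.0) {
  if (!is.finite(overall) || !is.finite(high) || overall <= 0 ||
      high <= overall)
    stop("thresholds must satisfy 0 < overall < high", call. = FALSE)
  structure(list(overall = overall, high = high), class = "load_thresholds")
}

#' Cumulative loading time and impulse of one load series
#'
#' Accumulates, by rectangle-rule integration at the native sample rate,
#' the time the load is at or above each threshold and the loading impulse
#' over those samples. Threshold comparisons are closed (`>=`), and the
#' impulse accumulates the full sample load F over supra-threshold samples,
#' not the excess F - theta (this full-F convention is what makes the
#' per-hour normalized overall load comparable to a mean stance-phase
#' load).
#'
#' Units: times in hours, impulses in xBW x hour.
#'
#' @param series a [tendon_load_series()].
#' @param thresholds a [load_thresholds()].
#' @return A `cumulative_load_summary`: list with `t_load_h` (time at or
#'   above the overall threshold), `i_overall_bwh`, `t_high_h`,
#'   `i_high_bwh`, provenance identifiers and `scope = "recording"`.
#'   An empty series yields an all-zero summary.
#' @examples
#' s <- tendon_load_series(rep(4, 720), sample_rate_hz = 20)  # 36 s at 4 xBW
#' summarize_series(s)  # 0.01 h and 0.04 xBW.h above both thresholds
#' @export
summarize_series <- function(series, thresholds = load_thresholds()) {
  stopifnot(inherits(series, "tendon_load_series"),
            inherits(thresholds, "load_thresholds"))
  dt_h <- 1 / series$sample_rate_hz / 3600
  f <- series$load_bw
  over <- f >= thresholds$overall
  high <- f >= thresholds$high
  out <- list(participant_id = series$participant_id,
              day = series$day, session = series$session,
              scope = "recording",
              t_load_h = sum(over) * dt_h,
              i_overall_bwh = sum(f[over]) * dt_h,
              t_high_h = sum(high) * dt_h,
              i_high_bwh = sum(f[high]) * dt_h)
  class(out) <- "cumulative_load_summary"
  out
}

#' @export
print.cumulative_load_summary <- function(x, ...) {
  cat(sprintf("<cumulative_load_summary> scope: %s (%s)\n", x$scope,
              x$participant_id))
  cat(sprintf("  loading time %.4f h, overall impulse %.4f xBW.h\n",
              x$t_load_h, x$i_overall_bwh))
  cat(sprintf("  high-level time %.4f h, high-level impulse %.4f xBW.h\n",
              x$t_high_h, x$i_high_bwh))
  invisible(x)
}

#' @export
as.data.frame.cumulative_load_summary <- function(x, ...) {
  data.frame(participant_id = x$participant_id, day = x$day,
             session = x$session, t_load_h = x$t_load_h,
             i_overall_bwh = x$i_overall_bwh, t_high_h = x$t_high_h,
             i_high_bwh = x$i_high_bwh, stringsAsFactors = FALSE)
}

#' Bind cumulative load summaries into a data frame
#'
#' @param summaries list of `cumulative_load_summary` objects (or a data
#'   frame already holding the summary columns, returned unchanged).
#' @return data frame with one row per summary.
#' @export
bind_summaries <- function(summaries) {
  if (is.data.frame(summaries)) return(summaries)
  if (inherits(summaries, "cumulative_load_summary"))
    summaries <- list(summaries)
  do.call(rbind, lapply(summaries, as.data.frame))
}

#' Collapse recording summaries to one row per day
#'
#' @param summaries per-recording summaries (list or data frame as in
#'   [bind_summaries()]).
#' @return data frame keyed by (participant_id, day) with summed times and
#'   impulses.
#' @export
day_summaries <- function(summaries) {
  df <- bind_summaries(summaries)
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(participant_id = character(), day = integer(),
                      t_load_h = numeric(), i_overall_bwh = numeric(),
                      t_high_h = numeric(), i_high_bwh = numeric(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(
    df[c("t_load_h", "i_overall_bwh", "t_high_h", "i_high_bwh")],
    by = list(participant_id = df$participant_id, day = df$day), FUN = sum)
  agg[order(agg$participant_id, agg$day), , drop = FALSE]
}

#' Aggregate summaries into per-participant normalized loads
#'
#' Sums loading times and impulses over all kept recordings (or days) of
#' one participant, then divides each cumulative impulse by the total
#' loading time -- the total time at or above the overall threshold, not
#' the high-level time -- to obtain the per-hour normalized overall and
#' high-level loads (units xBW per loading hour).
#'
#' @param summaries summaries of a single participant: list of
#'   `cumulative_load_summary` or a data frame with columns
#'   `participant_id`, `t_load_h`, `i_overall_bwh`, `t_high_h`,
#'   `i_high_bwh`.
#' @return A `participant_load_summary`: list with `participant_id`,
#'   `l_overall` and `l_high` (xBW per loading hour; `NA` and
#'   `defined = FALSE` when the total loading time is zero), the summed
#'   times/impulses and `n_units` (rows aggregated).
#' @examples
#' df <- data.frame(participant_id = "P01", t_load_h = c(0.5, 1.5),
#'                  i_overall_bwh = c(0.45, 1.55),
#'                  t_high_h = c(0, 0), i_high_bwh = c(0, 0))
#' aggregate_participant(df)$l_overall  # 2.0 / 2.0 = 1.0
#' @export
aggregate_participant <- function(summaries) {
  df <- bind_summaries(summaries)
  if (is.null(df) || nrow(df) == 0)
    stop("at least one summary is required", call. = FALSE)
  ids <- unique(df$participant_id)
  if (length(ids) != 1)
    stop("summaries mix multiple participants: ",
         paste(ids, collapse = ", "), call. = FALSE)
  t_load <- sum(df$t_load_h)
  i_overall <- sum(df$i_overall_bwh)
  t_high <- sum(df$t_high_h)
  i_high <- sum(df$i_high_bwh)
  defined <- t_load > 0
  out <- list(participant_id = ids,
              l_overall = if (defined) i_overall / t_load else NA_real_,
              l_high = if (defined) i_high / t_load else NA_real_,
              t_load_h = t_load, i_overall_bwh = i_overall,
              t_high_h = t_high, i_high_bwh = i_high,
              n_units = nrow(df), defined = defined)
  class(out) <- "participant_load_summary"
  out
}

#' @export
print.participant_load_summary <- function(x, ...) {
  cat(sprintf("<participant_load_summary> %s (%d units)\n",
              x$participant_id, x$n_units))
  if (x$defined) {
    cat(sprintf("  L_overall %.3f xBW/h, L_high %.3f xBW/h over %.2f loading h\n",
                x$l_overall, x$l_high, x$t_load_h))
  } else {
    cat("  undefined: total loading time is zero\n")
  }
  invisible(x)
}

#' @export
as.data.frame.participant_load_summary <- function(x, ...) {
  data.frame(participant_id = x$participant_id, l_overall = x$l_overall,
             l_high = x$l_high, t_load_h = x$t_load_h,
             i_overall_bwh = x$i_overall_bwh, t_high_h = x$t_high_h,
             i_high_bwh = x$i_high_bwh, n_units = x$n_units,
             defined = x$defined, stringsAsFactors = FALSE)
}

#' Per-participant normalized loads for a whole cohort
#'
#' @param day_df day-level summaries (see [day_summaries()]) for all
#'   participants.
#' @return data frame with one row per participant (see
#'   [aggregate_participant()]), plus `days_used`.
#' @export
participant_summaries <- function(day_df) {
  stopifnot(is.data.frame(day_df))
  ids <- unique(day_df$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- day_df[day_df$participant_id == id, , drop = FALSE]
    out <- as.data.frame(aggregate_participant(sub))
    out$days_used <- length(unique(sub$day))
    out
  })
  do.call(rbind, rows)
}
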