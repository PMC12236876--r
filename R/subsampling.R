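#' Per-participant estimates from day subsets
#'
#' Re-runs the per-participant aggregation on every subset of size `k`
#' drawn from the participant's first six recorded days (all `C(6, k)`
#' combinations; this generalizes the leave-one-out scheme for k = 5 and
#' the singleton scheme for k = 1 symmetrically). Participants with fewer
#' than six recorded days contribute subsets drawn from the days they
#' have, and are flagged via the `limited` column.
#'
#' @param day_df day-level summaries of one participant (see
#'   [day_summaries()]).
#' @param k subset size, 1 to 6.
#' @return data frame with one row per subset: `participant_id`, `k`,
#'   `subset` (hyphen-joined day ranks), `l_overall`, `l_high`,
#'   `t_load_h`, `limited`. Zero rows if the participant has fewer than
#'   `k` days.
#' @export
subsample_estimates <- function(day_df, k) {
  stopifnot(is.data.frame(day_df))
  if (!is.finite(k) || k < 1 || k > 6)
    stop("k must be between 1 and 6", call. = FALSE)
  k <- as.integer(k)
  id <- unique(day_df$participant_id)
  if (length(id) != 1)
    stop("day_df must cover a single participant", call. = FALSE)
  day_df <- day_df[order(day_df$day), , drop = FALSE]
  n_avail <- min(nrow(day_df), 6L)
  limited <- nrow(day_df) < 6L
  if (n_avail < k)
    return(data.frame(participant_id = character(0), k = integer(0),
                      subset = character(0), l_overall = numeric(0),
                      l_high = numeric(0), t_load_h = numeric(0),
                      limited = logical(0), stringsAsFactors = FALSE))
  first <- day_df[seq_len(n_avail), , drop = FALSE]
  combos <- utils::combn(n_avail, k)
  rows <- apply(combos, 2, function(ix) {
    agg <- aggregate_participant(first[ix, , drop = FALSE])
    data.frame(participant_id = id, k = k,
               subset = paste(ix, collapse = "-"),
               l_overall = agg$l_overall, l_high = agg$l_high,
               t_load_h = agg$t_load_h, limited = limited,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean absolute percent error
#'
#' Mean over pairs of `|estimate - reference| / reference * 100`.
#' Reference-zero pairs (participants whose full-data high-level load is
#' exactly zero) are defined as 0% error when the estimate is also zero,
#' and are otherwise excluded from the mean; the excluded count is
#' reported in the `n_excluded` attribute.
#'
#' @param estimates numeric vector of subset-based estimates.
#' @param references paired full-dataset references.
#' @return MAPE in percent, with attributes `n` (pairs used) and
#'   `n_excluded` (zero-reference, nonzero-estimate pairs dropped).
#' @export
mape <- function(estimates, references) {
  if (length(estimates) == 0 || length(estimates) != length(references))
    stop("estimates and references must be nonempty and paired",
         call. = FALSE)
  pct <- numeric(length(estimates))
  zero_ref <- references == 0
  pct[!zero_ref] <- abs(estimates[!zero_ref] - references[!zero_ref]) /
    references[!zero_ref] * 100
  pct[zero_ref & estimates == 0] <- 0
  drop <- zero_ref & estimates != 0
  pct <- pct[!drop]
  if (length(pct) == 0)
    stop("no usable pairs (all references zero with nonzero estimates)",
         call. = FALSE)
  structure(mean(pct), n = length(pct), n_excluded = sum(drop))
}

# absolute percent errors of one k-level estimate table vs references
.abs_pct_errors <- function(est, ref) {
  out <- rep(NA_real_, length(est))
  nz <- ref != 0
  out[nz] <- abs(est[nz] - ref[nz]) / ref[nz] * 100
  out[!nz & est == 0] <- 0
  out  # NA where ref == 0 and est != 0 (excluded)
}

#' Day-subsampling reliability curve
#'
#' For k = 1..6 monitoring days, computes how per-participant normalized
#' loads estimated from only k of the first six recorded days deviate
#' from the full-dataset estimates: mean absolute percent error (MAPE)
#' pooled across participants and subsets, the SD of those absolute
#' percent errors (the dispersion across subset estimates), and the
#' Pearson correlation between subset and full estimates pooled over all
#' subsets.
#'
#' @param day_df day-level summaries for the whole cohort (see
#'   [day_summaries()]).
#' @param ks subset sizes to evaluate (default 1:6).
#' @return object of class `subsampling_result`: a data frame with one
#'   row per (measure, k): `mape_pct`, `sd_pct`, `r`, `n_subsets`,
#'   `n_pairs`, `n_excluded`.
#' @export
subsampling_curve <- function(day_df, ks = 1:6) {
  stopifnot(is.data.frame(day_df))
  ids <- unique(day_df$participant_id)
  n_days_per <- vapply(ids, function(id)
    nrow(day_df[day_df$participant_id == id, ]), integer(1))
  if (!any(n_days_per >= 2))
    stop("subsampling requires at least one participant with >= 2 days",
         call. = FALSE)
  full <- participant_summaries(day_df)
  rows <- list()
  for (k in ks) {
    est <- do.call(rbind, lapply(ids, function(id)
      subsample_estimates(day_df[day_df$participant_id == id, ,
                                 drop = FALSE], k)))
    if (is.null(est) || nrow(est) == 0) next
    ref <- full[match(est$participant_id, full$participant_id), ]
    for (measure in c("l_overall", "l_high")) {
      e <- est[[measure]]
      r_ <- ref[[measure]]
      pct <- .abs_pct_errors(e, r_)
      used <- !is.na(pct)
      r_sub <- if (stats::sd(e[used]) > 0 && stats::sd(r_[used]) > 0)
        stats::cor(e[used], r_[used]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        measure = measure, k = k, mape_pct = mean(pct[used]),
        sd_pct = stats::sd(pct[used]), r = r_sub,
        n_subsets = length(unique(est$subset)), n_pairs = sum(used),
        n_excluded = sum(!used), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("subsampling_result", class(out))
  out
}

#' @export
print.subsampling_result <- function(x, ...) {
  cat("<subsampling_result> MAPE vs full dataset by monitoring days\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.subsampling_result <- function(x, ...) {
  ov <- x[x$measure == "l_overall", ]
  hi <- x[x$measure == "l_high", ]
  ylim <- c(0, max(x$mape_pct + x$sd_pct, na.rm = TRUE))
  graphics::plot(ov$k, ov$mape_pct, type = "b", pch = 16, col = "blue",
                 ylim = ylim, xlab = "days of insole data used",
                 ylab = "MAPE vs full dataset (%)", ...)
  graphics::lines(hi$k, hi$mape_pct, type = "b", pch = 17,
                  col = "orange")
  graphics::arrows(x$k, pmax(x$mape_pct - x$sd_pct, 0),
                   x$k, x$mape_pct + x$sd_pct,
                   angle = 90, code = 3, length = 0.03,
                   col = ifelse(x$measure == "l_overall", "blue",
                                "orange"))
  graphics::legend("topright", c("overall load", "high-level load"),
                   col = c("blue", "orange"), pch = c(16, 17), lty = 1)
  invisible(x)
}
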