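#' Classify Pearson correlation strength
#'
#' Fixed literature cutpoints on the absolute correlation: `|r| >= 0.6`
#' strong, `0.4 <= |r| < 0.6` moderate, `|r| < 0.4` weak.
#'
#' @param r correlation coefficient(s).
#' @return character vector of `"weak"`, `"moderate"`, `"strong"`.
#' @export
classify_strength <- function(r) {
  a <- abs(r)
  out <- ifelse(a >= 0.6, "strong", ifelse(a >= 0.4, "moderate", "weak"))
  out[is.na(r)] <- NA_character_
  out
}

#' Pearson correlation with strength label
#'
#' Sample Pearson correlation over pairwise-complete observations, with a
#' two-sided p-value from the t transform on n - 2 degrees of freedom and
#' the strength classification of [classify_strength()]. Significance is
#' ancillary (the strength label is the primary readout).
#'
#' @param x,y paired numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return object of class `correlation_result`: list with `n`, `r`, `p`,
#'   `strength`, `significant`.
#' @export
pearson_with_strength <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y))
    stop("x and y must be paired", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop("at least 3 complete pairs are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(n = n, r = r, p = ct$p.value,
                 strength = classify_strength(r),
                 significant = ct$p.value < alpha, alpha = alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (%s%s), p = %.4g, n = %d\n", x$r, x$strength,
              if (x$significant) ", significant" else "", x$p, x$n))
  invisible(x)
}

#' Correlation grid of load measures against clinical measures
#'
#' Computes the full 2 x 13 grid of Pearson correlations between the two
#' normalized cumulative load measures (`l_overall`, `l_high`, xBW per
#' loading hour) and the 13 clinical measures, over pairwise-complete
#' participants. Participants whose loads are undefined (zero loading
#' time) are excluded; per-cell n is reported.
#'
#' @param load_df per-participant load summaries (see
#'   [participant_summaries()]).
#' @param clinical clinical table (one row per participant, columns as in
#'   [clinical_measure_names()]).
#' @param alpha significance level.
#' @return object of class `correlation_table`: data frame with columns
#'   `load_measure`, `clinical_measure`, `n`, `r`, `p`, `strength`,
#'   `significant`.
#' @export
correlation_table <- function(load_df, clinical, alpha = 0.05) {
  stopifnot(is.data.frame(load_df))
  if (!is.data.frame(clinical) || nrow(clinical) == 0)
    stop("clinical table is empty", call. = FALSE)
  measures <- intersect(clinical_measure_names(), names(clinical))
  if (length(measures) == 0)
    stop("clinical table holds none of the canonical measures",
         call. = FALSE)
  if ("defined" %in% names(load_df))
    load_df <- load_df[load_df$defined, , drop = FALSE]
  merged <- merge(load_df, clinical, by = "participant_id")
  if (nrow(merged) < 3)
    stop("fewer than 3 participants with defined loads and clinical data",
         call. = FALSE)
  rows <- list()
  for (lm in c("l_overall", "l_high")) {
    for (cm in measures) {
      res <- tryCatch(pearson_with_strength(merged[[lm]], merged[[cm]],
                                            alpha),
                      error = function(e) NULL)
      rows[[length(rows) + 1]] <- if (is.null(res))
        data.frame(load_measure = lm, clinical_measure = cm,
                   n = sum(is.finite(merged[[lm]]) &
                             is.finite(merged[[cm]])),
                   r = NA_real_, p = NA_real_,
                   strength = NA_character_, significant = NA,
                   stringsAsFactors = FALSE)
      else
        data.frame(load_measure = lm, clinical_measure = cm, n = res$n,
                   r = res$r, p = res$p, strength = res$strength,
                   significant = res$significant,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_table", class(out))
  out
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("<correlation_table> load vs clinical measures",
      "(* = significant)\n")
  df <- as.data.frame(x)
  df$r <- sprintf("%6.3f%s", df$r, ifelse(!is.na(df$significant) &
                                            df$significant, "*", " "))
  df$p <- signif(df$p, 3)
  print.data.frame(df[c("load_measure", "clinical_measure", "n", "r",
                        "p", "strength")], row.names = FALSE)
  invisible(x)
}
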