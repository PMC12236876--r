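#' Estimate Achilles tendon load from plantar forces
#'
#' Implements the ankle moment-balance estimator: per sample, the
#' plantarflexion moment is the sum of the three force-by-moment-arm
#' products,
#' \deqn{M_{PF} = f_{heel} r_{heel} + f_{mid} r_{mid} + f_{fore} r_{fore},}
#' and the Achilles tendon force is the moment divided by the tendon
#' moment arm, \eqn{F_{AT} = M_{PF} / r_{AT}}, normalized by body weight
#' to give load in units of xBW. Negative moments (dorsiflexion, e.g.
#' heel-only loading) are clamped to zero: the tendon cannot transmit a
#' compressive push.
#'
#' @param recording an [insole_recording()], post quality control.
#' @param geometry a [sensor_geometry()].
#' @param bw_n body weight in newtons (> 0), see [body_weight_n()].
#' @return A `tendon_load_series`: per-sample load in xBW at the
#'   recording's sample rate, carrying the recording's identifiers.
#' @examples
#' rec <- insole_recording(f_heel = 0, f_mid = 0, f_fore = 600)
#' s <- estimate_tendon_load(rec, sensor_geometry(), bw_n = 660)
#' s$load_bw  # 600 * 0.11 / 0.05 / 660 = 2 xBW
#' @export
estimate_tendon_load <- function(recording, geometry = sensor_geometry(),
                                 bw_n) {
  stopifnot(inherits(recording, "insole_recording"),
            inherits(geometry, "sensor_geometry"))
  if (!is.numeric(bw_n) || length(bw_n) != 1 || !is.finite(bw_n) || bw_n <= 0)
    stop("bw_n must be a single positive body weight in newtons",
         call. = FALSE)
  bad <- which(!is.finite(recording$f_heel) | !is.finite(recording$f_mid) |
                 !is.finite(recording$f_fore))
  if (length(bad) > 0)
    stop(sprintf("non-finite force at sample %d", bad[1]), call. = FALSE)
  m_pf <- recording$f_heel * geometry$r_heel +
    recording$f_mid * geometry$r_mid +
    recording$f_fore * geometry$r_fore
  load_bw <- pmax(m_pf / geometry$r_at, 0) / bw_n
  tendon_load_series(load_bw, recording$sample_rate_hz,
                     participant_id = recording$participant_id,
                     day = recording$day, session = recording$session)
}

#' Tendon load series container
#'
#' @param load_bw numeric vector, Achilles load per sample in xBW
#'   (non-negative, finite).
#' @param sample_rate_hz sampling rate in Hz.
#' @param participant_id,day,session provenance identifiers.
#' @return An object of class `tendon_load_series`.
#' @export
tendon_load_series <- function(load_bw, sample_rate_hz = 20,
                               participant_id = "P01", day = 1L,
                               session = 1L) {
  load_bw <- as.numeric(load_bw)
  if (any(!is.finite(load_bw)))
    stop("load values must be finite", call. = FALSE)
  if (any(load_bw < 0))
    stop("load values must be non-negative", call. = FALSE)
  if (sample_rate_hz <= 0)
    stop("sample_rate_hz must be > 0", call. = FALSE)
  structure(list(load_bw = load_bw,
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 participant_id = as.character(participant_id)[1],
                 day = as.integer(day), session = as.integer(session)),
            class = "tendon_load_series")
}

#' @export
print.tendon_load_series <- function(x, ...) {
  cat(sprintf("<tendon_load_series> %s day %d session %d\n",
              x$participant_id, x$day, x$session))
  n <- length(x$load_bw)
  cat(sprintf("  %d samples at %g Hz (%.1f s)\n", n, x$sample_rate_hz,
              n / x$sample_rate_hz))
  if (n > 0)
    cat(sprintf("  load: peak %.2f xBW, mean %.3f xBW\n",
                max(x$load_bw), mean(x$load_bw)))
  invisible(x)
}

#' @export
plot.tendon_load_series <- function(x, ...) {
  t <- (seq_along(x$load_bw) - 1) / x$sample_rate_hz
  graphics::plot(t, x$load_bw, type = "l", xlab = "time (s)",
                 ylab = "Achilles load (xBW)",
                 main = sprintf("%s day %d session %d", x$participant_id,
                                x$day, x$session), ...)
  graphics::abline(h = c(0.3, 3.0), lty = 2, col = c("blue", "orange"))
  invisible(x)
}
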