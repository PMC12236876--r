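#' Insole session recording
#'
#' Container for one continuous insole logging session: three plantar force
#' channels (heel, midfoot, forefoot) in newtons sampled at a fixed rate
#' (20 Hz on the study logger). Forces may be negative before quality
#' control (sensor drift, initialization error); after [correct_drift()]
#' they are clipped at zero.
#'
#' @param f_heel,f_mid,f_fore numeric vectors of equal length, channel
#'   forces in newtons.
#' @param sample_rate_hz sampling rate in Hz (> 0); the study logger runs
#'   at 20 Hz.
#' @param participant_id character scalar identifying the wearer.
#' @param day integer day index within the monitoring period (1-based).
#' @param session integer session index within the day (1-based; a new
#'   session starts at every re-initialization, e.g. a shoe change).
#' @return An object of class `insole_recording`.
#' @examples
#' rec <- insole_recording(f_heel = c(0, 100, 0), f_mid = c(0, 80, 0),
#'                         f_fore = c(0, 400, 0), participant_id = "P01")
#' n_samples(rec)
#' @export
insole_recording <- function(f_heel, f_mid, f_fore, sample_rate_hz = 20,
                             participant_id = "P01", day = 1L, session = 1L) {
  f_heel <- as.numeric(f_heel)
  f_mid <- as.numeric(f_mid)
  f_fore <- as.numeric(f_fore)
  n <- length(f_heel)
  if (length(f_mid) != n || length(f_fore) != n)
    stop("force channels must have equal length", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be a single positive number", call. = FALSE)
  day <- as.integer(day)
  session <- as.integer(session)
  if (is.na(day) || is.na(session) || day < 1L || session < 1L)
    stop("day and session must be positive integers", call. = FALSE)
  structure(
    list(participant_id = as.character(participant_id)[1],
         day = day, session = session,
         sample_rate_hz = as.numeric(sample_rate_hz),
         f_heel = f_heel, f_mid = f_mid, f_fore = f_fore),
    class = "insole_recording")
}

#' Number of samples in a recording
#' @param recording an [insole_recording()].
#' @return integer sample count.
#' @export
n_samples <- function(recording) {
  stopifnot(inherits(recording, "insole_recording"))
  length(recording$f_heel)
}

#' Recording duration in seconds
#' @param recording an [insole_recording()].
#' @return duration in seconds (samples / rate).
#' @export
duration_s <- function(recording) {
  n_samples(recording) / recording$sample_rate_hz
}

#' Sample time stamps of a recording
#'
#' Times of each sample relative to session start; the first sample is at
#' t = 0.
#' @param recording an [insole_recording()].
#' @return numeric vector of times in seconds.
#' @export
sample_times <- function(recording) {
  n <- n_samples(recording)
  if (n == 0) return(numeric(0))
  (seq_len(n) - 1) / recording$sample_rate_hz
}

#' @export
print.insole_recording <- function(x, ...) {
  cat(sprintf("<insole_recording> %s day %d session %d\n",
              x$participant_id, x$day, x$session))
  cat(sprintf("  %d samples at %g Hz (%.1f s)\n",
              n_samples(x), x$sample_rate_hz, duration_s(x)))
  if (n_samples(x) > 0)
    cat(sprintf("  peak channel forces (N): heel %.1f, mid %.1f, fore %.1f\n",
                max(x$f_heel), max(x$f_mid), max(x$f_fore)))
  invisible(x)
}

#' @export
as.data.frame.insole_recording <- function(x, ...) {
  data.frame(time_s = sample_times(x),
             f_heel_n = x$f_heel, f_mid_n = x$f_mid, f_fore_n = x$f_fore)
}
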