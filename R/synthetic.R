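#' Activity bout
#'
#' One element of a day's activity schedule: a contiguous interval of a
#' single activity kind. `walk` bouts use a two-hump (heel-strike /
#' push-off) stance load waveform, `run` and `jump` a single asymmetric
#' hump; `rest` is worn but unloaded, `nonwear` is not recorded at all.
#' A locomotor bout with `cadence_per_min <= 0` produces a constant load
#' equal to `peak_load_bw` for the whole bout (useful for analytic test
#' cases).
#'
#' @param kind one of `"walk"`, `"run"`, `"jump"`, `"rest"`, `"nonwear"`.
#' @param duration_s bout duration in seconds (> 0).
#' @param peak_load_bw target peak Achilles load per stance, in xBW
#'   (>= 0; ignored for rest/nonwear).
#' @param cadence_per_min stances (steps or landings of the instrumented
#'   foot) per minute.
#' @return An object of class `activity_bout`.
#' @export
activity_bout <- function(kind, duration_s, peak_load_bw = 0,
                          cadence_per_min = 0) {
  kinds <- c("walk", "run", "jump", "rest", "nonwear")
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% kinds))
    stop("kind must be one of ", paste(kinds, collapse = ", "),
         call. = FALSE)
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  if (!is.finite(peak_load_bw) || peak_load_bw < 0)
    stop("peak_load_bw must be >= 0", call. = FALSE)
  structure(list(kind = kind, duration_s = duration_s,
                 peak_load_bw = peak_load_bw,
                 cadence_per_min = cadence_per_min),
            class = "activity_bout")
}

#' Validate a day schedule
#'
#' A day schedule is an ordered list of [activity_bout()]s; bouts are
#' consecutive in time, so intervals cannot overlap by construction.
#'
#' @param schedule list of [activity_bout()]s (may be empty).
#' @return the schedule, invisibly; errors on invalid input.
#' @export
validate_schedule <- function(schedule) {
  if (!is.list(schedule))
    stop("schedule must be a list of activity_bout objects", call. = FALSE)
  ok <- vapply(schedule, inherits, logical(1), what = "activity_bout")
  if (length(schedule) > 0 && !all(ok))
    stop("schedule element ", which(!ok)[1], " is not an activity_bout",
         call. = FALSE)
  invisible(schedule)
}

# Fraction of the step period spent in stance, by activity kind.
.stance_frac <- c(walk = 0.62, run = 0.40, jump = 0.20)

# Normalized stance load waveform, phase p in [0, 1).
# walk: two raised-cosine humps (loading response and push-off), peaks at
# p = 0.25 and 0.75; run/jump: a single asymmetric raised cosine peaking
# at p = 0.4. Both integrate to the same closed-form supra-threshold time
# and impulse (see stance_supra_time / stance_supra_impulse).
stance_waveform <- function(kind, p) {
  if (kind == "walk") {
    0.5 * (1 - cos(4 * pi * p))
  } else {
    alpha <- 0.4
    ifelse(p < alpha,
           0.5 * (1 - cos(pi * p / alpha)),
           0.5 * (1 + cos(pi * (p - alpha) / (1 - alpha))))
  }
}

stance_peak_phase <- function(kind) if (kind == "walk") 0.25 else 0.4

#' Closed-form supra-threshold time and impulse of one stance
#'
#' For the raised-cosine stance families used by the generator, the time a
#' stance of peak `peak_bw` and duration `duration_s` spends at or above a
#' threshold, and the loading impulse (integral of the full load, not the
#' excess) over that region, have closed forms: with
#' \eqn{\phi = \arccos(1 - 2\theta/P)},
#' time \eqn{= d (1 - \phi/\pi)} and impulse
#' \eqn{= (P d / 2)\,(1 - \phi/\pi + \sin\phi/\pi)}.
#' Both the two-hump walking shape and the asymmetric running shape reduce
#' to these same totals, which is what makes them usable as an analytic
#' ground-truth oracle independent of the sampled signal path.
#'
#' @param peak_bw stance peak load (xBW); vectorized.
#' @param duration_s stance duration (s); vectorized.
#' @param threshold_bw threshold (xBW, > 0).
#' @return time in seconds (`stance_supra_time`) or impulse in xBW x s
#'   (`stance_supra_impulse`); zero where `peak_bw < threshold_bw`.
#' @export
stance_supra_time <- function(peak_bw, duration_s, threshold_bw) {
  phi <- acos(pmin(pmax(1 - 2 * threshold_bw / peak_bw, -1), 1))
  out <- duration_s * (1 - phi / pi)
  out[peak_bw < threshold_bw] <- 0
  out
}

#' @rdname stance_supra_time
#' @export
stance_supra_impulse <- function(peak_bw, duration_s, threshold_bw) {
  phi <- acos(pmin(pmax(1 - 2 * threshold_bw / peak_bw, -1), 1))
  out <- peak_bw * duration_s / 2 * ((1 - phi / pi) + sin(phi) / pi)
  out[peak_bw < threshold_bw] <- 0
  out
}

# Time-varying allocation of total plantar force across the three sensors
# as a function of stance phase: heel-carrying at contact, forefoot-
# dominant at push-off. Rows: samples; columns heel, mid, fore.
channel_fractions <- function(p) {
  a_fore <- 0.15 + 0.75 * p
  a_heel <- 0.30 * (1 - p)
  a_mid <- 1 - a_fore - a_heel
  cbind(heel = a_heel, mid = a_mid, fore = a_fore)
}

# Convert a target load series (xBW) plus stance phases into channel
# forces (N) that reproduce it exactly through the moment-balance
# estimator.
forces_from_load <- function(load_bw, p, geometry, bw_n) {
  fr <- channel_fractions(p)
  r_eff <- fr[, "heel"] * geometry$r_heel + fr[, "mid"] * geometry$r_mid +
    fr[, "fore"] * geometry$r_fore
  if (length(r_eff) > 0 && min(r_eff) <= 1e-4)
    stop("geometry incompatible with the stance force allocation ",
         "(effective moment arm not positive)", call. = FALSE)
  f_tot <- load_bw * bw_n * geometry$r_at / r_eff
  list(f_heel = f_tot * fr[, "heel"], f_mid = f_tot * fr[, "mid"],
       f_fore = f_tot * fr[, "fore"])
}

#' Simulate a single stance force segment
#'
#' Generates one stance's three-channel force segment such that applying
#' [estimate_tendon_load()] to it reproduces the stance load waveform with
#' maximum exactly `peak_load_bw`. The sampling grid is phase-aligned so
#' that one sample lands on the waveform argmax (`phase_offset = NULL`);
#' pass an explicit `phase_offset` in `[0, 1/rate)` to place the grid
#' elsewhere, as happens naturally inside a continuous session.
#'
#' @param kind `"walk"`, `"run"` or `"jump"`.
#' @param peak_load_bw target peak load (xBW, >= 0).
#' @param stance_duration_s stance duration in seconds (> 0).
#' @param geometry a [sensor_geometry()].
#' @param bw_n body weight in newtons.
#' @param sample_rate_hz sampling rate (default 20 Hz).
#' @param phase_offset time of the first sample relative to stance start,
#'   or `NULL` for peak-aligned sampling.
#' @return an [insole_recording()] covering one stance.
#' @export
simulate_stance_profile <- function(kind, peak_load_bw, stance_duration_s,
                                    geometry = sensor_geometry(), bw_n,
                                    sample_rate_hz = 20,
                                    phase_offset = NULL) {
  if (!kind %in% c("walk", "run", "jump"))
    stop("kind must be walk, run or jump", call. = FALSE)
  if (!is.finite(stance_duration_s) || stance_duration_s <= 0)
    stop("stance_duration_s must be > 0", call. = FALSE)
  if (!is.finite(peak_load_bw) || peak_load_bw < 0)
    stop("peak_load_bw must be >= 0", call. = FALSE)
  dt <- 1 / sample_rate_hz
  if (is.null(phase_offset)) {
    t_peak <- stance_peak_phase(kind) * stance_duration_s
    phase_offset <- t_peak - floor(t_peak / dt) * dt
  }
  t <- seq(phase_offset, stance_duration_s - 1e-12, by = dt)
  p <- t / stance_duration_s
  load <- peak_load_bw * stance_waveform(kind, p)
  f <- forces_from_load(load, p, geometry, bw_n)
  insole_recording(f$f_heel, f$f_mid, f$f_fore,
                   sample_rate_hz = sample_rate_hz,
                   participant_id = "stance")
}

# --- day simulation -------------------------------------------------------

# Build load samples and realized stance list for one bout.
# t_rel: sample times relative to bout start. Returns load (xBW), phase p,
# and a data frame of realized stances (peak_bw, duration_s) plus any
# constant-load segment for the analytic ground truth.
bout_load <- function(bout, t_rel, peak_jitter_sd) {
  n <- length(t_rel)
  if (bout$kind %in% c("rest", "nonwear") || bout$peak_load_bw == 0) {
    return(list(load = numeric(n), p = rep(0.7, n),
                stances = NULL, const = NULL))
  }
  if (bout$cadence_per_min <= 0) {
    return(list(load = rep(bout$peak_load_bw, n), p = rep(0.7, n),
                stances = NULL,
                const = data.frame(load_bw = bout$peak_load_bw,
                                   duration_s = bout$duration_s)))
  }
  period <- 60 / bout$cadence_per_min
  stance_d <- .stance_frac[[bout$kind]] * period
  n_steps <- floor(bout$duration_s / period)
  if (n_steps == 0)
    return(list(load = numeric(n), p = rep(0.7, n), stances = NULL,
                const = NULL))
  peaks <- bout$peak_load_bw *
    pmax(1 + stats::rnorm(n_steps, 0, peak_jitter_sd), 0.2)
  step <- floor(t_rel / period)
  tau <- t_rel - step * period
  in_stance <- step < n_steps & tau < stance_d
  p <- ifelse(in_stance, tau / stance_d, 0.7)
  load <- numeric(n)
  idx <- which(in_stance)
  if (length(idx) > 0)
    load[idx] <- peaks[step[idx] + 1] *
      stance_waveform(bout$kind, p[idx])
  list(load = load, p = p,
       stances = data.frame(peak_bw = peaks, duration_s = stance_d),
       const = NULL)
}

# Analytic cumulative summary of realized stances + constant segments.
analytic_summary <- function(stances, consts, thresholds) {
  t_o <- i_o <- t_h <- i_h <- 0
  if (!is.null(stances) && nrow(stances) > 0) {
    t_o <- t_o + sum(stance_supra_time(stances$peak_bw, stances$duration_s,
                                       thresholds$overall))
    i_o <- i_o + sum(stance_supra_impulse(stances$peak_bw,
                                          stances$duration_s,
                                          thresholds$overall))
    t_h <- t_h + sum(stance_supra_time(stances$peak_bw, stances$duration_s,
                                       thresholds$high))
    i_h <- i_h + sum(stance_supra_impulse(stances$peak_bw,
                                          stances$duration_s,
                                          thresholds$high))
  }
  if (!is.null(consts) && nrow(consts) > 0) {
    over <- consts$load_bw >= thresholds$overall
    high <- consts$load_bw >= thresholds$high
    t_o <- t_o + sum(consts$duration_s[over])
    i_o <- i_o + sum(consts$load_bw[over] * consts$duration_s[over])
    t_h <- t_h + sum(consts$duration_s[high])
    i_h <- i_h + sum(consts$load_bw[high] * consts$duration_s[high])
  }
  c(t_load_h = t_o / 3600, i_overall_bwh = i_o / 3600,
    t_high_h = t_h / 3600, i_high_bwh = i_h / 3600)
}

#' Simulate one monitoring day
#'
#' Renders a day's activity schedule into 20 Hz insole recordings (one per
#' contiguous worn block: `nonwear` bouts split sessions and are not
#' recorded) and computes the day's analytic ground-truth cumulative load
#' summary in closed form from the realized continuous stance schedule,
#' independently of the sampled signal path.
#'
#' @param profile a [participant_profile()] (supplies body weight).
#' @param schedule a day schedule: list of [activity_bout()]s.
#' @param artifacts optional artifact spec applied to every recording of
#'   the day (see [inject_artifacts()]).
#' @param seed integer seed; identical seeds and inputs give identical
#'   output.
#' @param geometry a [sensor_geometry()].
#' @param thresholds a [load_thresholds()] used for the ground truth.
#' @param sample_rate_hz sampling rate (default 20).
#' @param peak_jitter_sd relative SD of per-stance peak variation.
#' @return list with `recordings` (list of [insole_recording()]s) and
#'   `ground_truth` (one-row data frame: participant_id, day, t_load_h,
#'   i_overall_bwh, t_high_h, i_high_bwh).
#' @export
simulate_day <- function(profile, schedule, artifacts = NULL, seed,
                         geometry = sensor_geometry(),
                         thresholds = load_thresholds(),
                         sample_rate_hz = 20, peak_jitter_sd = 0.05) {
  if (missing(seed) || is.null(seed))
    stop("seed must be provided", call. = FALSE)
  stopifnot(inherits(profile, "participant_profile"))
  validate_schedule(schedule)
  set.seed(as.integer(seed %% 2147483629L))
  day <- if (!is.null(profile$current_day)) profile$current_day else 1L

  gt <- c(t_load_h = 0, i_overall_bwh = 0, t_high_h = 0, i_high_bwh = 0)
  recordings <- list()
  session_idx <- 0L

  # split schedule into worn sessions at nonwear bouts
  is_nw <- vapply(schedule, function(b) b$kind == "nonwear", logical(1))
  grp <- cumsum(is_nw)
  for (g in unique(grp)) {
    bouts <- schedule[grp == g & !is_nw]
    # ground truth for the nonwear bout itself is zero; skip
    if (length(bouts) == 0) next
    session_idx <- session_idx + 1L
    durs <- vapply(bouts, function(b) b$duration_s, numeric(1))
    total <- sum(durs)
    n <- floor(total * sample_rate_hz)
    t <- (seq_len(n) - 1) / sample_rate_hz
    load <- numeric(n)
    phase <- rep(0.7, n)
    t0 <- 0
    for (b in bouts) {
      idx <- which(t >= t0 & t < t0 + b$duration_s)
      bl <- bout_load(b, t[idx] - t0, peak_jitter_sd)
      load[idx] <- bl$load
      phase[idx] <- bl$p
      gt <- gt + analytic_summary(bl$stances, bl$const, thresholds)
      t0 <- t0 + b$duration_s
    }
    f <- forces_from_load(load, phase, geometry, profile$bw_n)
    rec <- insole_recording(f$f_heel, f$f_mid, f$f_fore,
                            sample_rate_hz = sample_rate_hz,
                            participant_id = profile$id, day = day,
                            session = session_idx)
    if (!is.null(artifacts) && length(artifacts) > 0)
      rec <- inject_artifacts(rec, artifacts, bw_n = profile$bw_n,
                              geometry = geometry)
    recordings[[session_idx]] <- rec
  }
  list(recordings = recordings,
       ground_truth = data.frame(participant_id = profile$id,
                                 day = as.integer(day),
                                 t_load_h = gt[["t_load_h"]],
                                 i_overall_bwh = gt[["i_overall_bwh"]],
                                 t_high_h = gt[["t_high_h"]],
                                 i_high_bwh = gt[["i_high_bwh"]],
                                 stringsAsFactors = FALSE))
}

#' Inject signal artifacts into a recording
#'
#' Produces a modified copy of a recording with a nonphysical artifact of
#' the kind the quality-control stage must detect:
#' * `"drift"`: a constant baseline offset, expressed as an estimated-load
#'   offset in xBW, applied to the forefoot channel from `onset_s`
#'   onwards (so unloaded segments read `offset_bw` instead of zero).
#' * `"erroneous"`: a whole-session constant offset (default 0.6 xBW),
#'   emulating incorrect sensor initialization / insole misfit; sessions
#'   so corrupted never return near zero and must be flagged.
#'
#' @param recording an [insole_recording()].
#' @param artifact_spec `NULL` or empty list (identity), or a list with
#'   `kind` (`"drift"` or `"erroneous"`), optional `offset_bw` (default
#'   0.1 for drift, 0.6 for erroneous) and `onset_s` (drift only,
#'   default 0).
#' @param bw_n body weight in newtons.
#' @param geometry a [sensor_geometry()] (the load offset is realized on
#'   the forefoot channel through the moment balance).
#' @param seed unused placeholder for future stochastic artifacts.
#' @return a modified copy; the input is untouched.
#' @export
inject_artifacts <- function(recording, artifact_spec, bw_n,
                             geometry = sensor_geometry(), seed = NULL) {
  stopifnot(inherits(recording, "insole_recording"))
  if (is.null(artifact_spec) || length(artifact_spec) == 0)
    return(recording)
  kind <- artifact_spec$kind
  if (is.null(kind) || !kind %in% c("drift", "erroneous"))
    stop("unknown artifact kind: ",
         if (is.null(kind)) "<missing>" else kind, call. = FALSE)
  out <- recording
  if (kind == "drift") {
    offset_bw <- if (is.null(artifact_spec$offset_bw)) 0.1 else
      artifact_spec$offset_bw
    onset_s <- if (is.null(artifact_spec$onset_s)) 0 else
      artifact_spec$onset_s
    idx <- which(sample_times(recording) >= onset_s)
  } else {
    offset_bw <- if (is.null(artifact_spec$offset_bw)) 0.6 else
      artifact_spec$offset_bw
    idx <- seq_len(n_samples(recording))
  }
  f_offset <- offset_bw * bw_n * geometry$r_at / geometry$r_fore
  out$f_fore[idx] <- out$f_fore[idx] + f_offset
  out
}

# --- participant profiles and cohort --------------------------------------

#' Participant profile
#'
#' @param id participant identifier.
#' @param mass_kg body mass (kg, > 0).
#' @param height_m body height (m).
#' @param age_y age in years.
#' @param visa_a VISA-A score, 0-100 (100 = asymptomatic).
#' @param pas Physical Activity Scale, integer 1-6.
#' @param latent_volume latent high-activity volume in `[0, 1]`; the
#'   unitless driver of both activity schedules and clinical measures in
#'   the generator.
#' @param g gravitational acceleration used for BW = mass x g.
#' @return object of class `participant_profile` with `bw_n` attached.
#' @export
participant_profile <- function(id, mass_kg, height_m = 1.72, age_y = 45,
                                visa_a = 60, pas = 4, latent_volume = 0.5,
                                g = 9.81) {
  if (!is.finite(mass_kg) || mass_kg <= 0)
    stop("mass_kg must be > 0", call. = FALSE)
  if (visa_a < 0 || visa_a > 100)
    stop("visa_a must be in [0, 100]", call. = FALSE)
  if (!pas %in% 1:6)
    stop("pas must be an integer in 1..6", call. = FALSE)
  structure(list(id = as.character(id), mass_kg = mass_kg,
                 bw_n = body_weight_n(mass_kg, g), height_m = height_m,
                 age_y = age_y, visa_a = visa_a, pas = as.integer(pas),
                 latent_volume = latent_volume, current_day = 1L),
            class = "participant_profile")
}

#' Default clinical effect specification
#'
#' Linear-plus-Gaussian-noise link between the latent high-activity volume
#' v in `[0, 1]` and each of the 13 clinical measures: value =
#' intercept + slope * v + N(0, sd), optionally rounded and clamped to the
#' measure's valid range. Age has a negative slope (older participants
#' engage in less dynamic activity); all function measures have positive
#' slopes. With v uniform on `[0, 1]` the implied population correlation
#' of each measure with v is `slope * sd(v) / sqrt(slope^2 var(v) + sd^2)`
#' (see [implied_effect_r()]).
#'
#' @param noise_scale multiplier on every noise SD (0 gives noiseless,
#'   exactly linear measures, except for rounding where specified).
#' @return named list of per-measure specs (intercept, slope, sd, round,
#'   lower, upper).
#' @export
default_effect_spec <- function(noise_scale = 1) {
  sp <- function(intercept, slope, sd, round = FALSE, lower = -Inf,
                 upper = Inf)
    list(intercept = intercept, slope = slope, sd = sd * noise_scale,
         round = round, lower = lower, upper = upper)
  list(
    pf_moment_isometric = sp(12, 8, 3),
    pf_moment_isokinetic_slow = sp(10, 7, 3),
    pf_moment_isokinetic_fast = sp(8, 6, 2),
    pf_power_isokinetic_slow = sp(15, 10, 4),
    pf_power_isokinetic_fast = sp(20, 14, 5),
    pf_work_isokinetic_slow = sp(18, 10, 4),
    pf_work_isokinetic_fast = sp(14, 9, 4),
    heel_raise_height_pbh = sp(4, 3, 0.8),
    cmj_height_pbh = sp(5, 6, 2),
    heel_raise_reps_incline = sp(8, 20, 5, lower = 0, upper = 30),
    age_y = sp(58, -22, 8, lower = 18, upper = 70),
    visa_a = sp(30, 55, 12, lower = 0, upper = 100),
    pas = sp(1.3, 4.4, 0.5, round = TRUE, lower = 1, upper = 6)
  )
}

#' Population correlation implied by an effect spec entry
#'
#' Closed-form Pearson correlation between the latent volume and a
#' clinical measure generated as `intercept + slope * v + N(0, sd)`:
#' `slope * sigma_v / sqrt(slope^2 sigma_v^2 + sd^2)` (before rounding or
#' clamping).
#'
#' @param spec one entry of [default_effect_spec()].
#' @param volume_sd SD of the latent volume (default `sqrt(1/12)`, the SD
#'   of a uniform `[0, 1]` variable).
#' @return implied correlation in `[-1, 1]`.
#' @export
implied_effect_r <- function(spec, volume_sd = sqrt(1 / 12)) {
  num <- spec$slope * volume_sd
  num / sqrt(num^2 + spec$sd^2)
}

#' Default activity schedule specification
#'
#' Parameters of the generator's day construction: peak stance loads and
#' cadences per activity kind, the probability model linking latent
#' volume to "active" (running/jumping) days, and a global duration scale
#' so that tests can run on compressed days while keeping the same
#' structure.
#'
#' @param scale multiplier on all bout durations (1 = full-length days of
#'   roughly 3.8 recorded hours).
#' @return named list of schedule parameters.
#' @export
default_schedule_spec <- function(scale = 1) {
  list(scale = scale, sample_rate_hz = 20,
       walk_peak_bw = 2.0, walk_peak_sd = 0.10, walk_cadence = 55,
       low_walk_peak_bw = 0.8, low_walk_cadence = 45,
       # cadences deliberately incommensurate with the 20 Hz grid so the
       # stance phase varies across steps and discretization averages out
       run_peak_bw = 4.3, run_peak_sd = 0.20, run_cadence = 82,
       jump_peak_bw = 5.2, jump_cadence = 31,
       p_active_base = 0.25, p_active_slope = 0.5,
       min_active_volume = 0.15,
       peak_jitter_sd = 0.05)
}

# One day's bout list. Draws per-bout peak variation from the current RNG
# stream; `active` marks a day containing a run (+ jump) session.
build_day_schedule <- function(spec, active) {
  s <- spec$scale
  wpk <- function() max(stats::rnorm(1, spec$walk_peak_bw,
                                     spec$walk_peak_sd), 0.5)
  b <- activity_bout
  bouts <- list(
    b("walk", 35 * 60 * s, wpk(), spec$walk_cadence),
    b("walk", 20 * 60 * s, spec$low_walk_peak_bw, spec$low_walk_cadence),
    b("rest", 10 * 60 * s),
    b("walk", 40 * 60 * s, wpk(), spec$walk_cadence),
    b("rest", 10 * 60 * s),
    b("nonwear", 10 * 60 * s),
    b("walk", 45 * 60 * s, wpk(), spec$walk_cadence),
    b("walk", 25 * 60 * s, spec$low_walk_peak_bw, spec$low_walk_cadence),
    b("rest", 10 * 60 * s))
  if (active) {
    rpk <- max(stats::rnorm(1, spec$run_peak_bw, spec$run_peak_sd), 3.3)
    bouts <- c(bouts, list(
      b("run", 25 * 60 * s, rpk, spec$run_cadence),
      b("jump", 3 * 60 * s, spec$jump_peak_bw, spec$jump_cadence)))
  }
  c(bouts, list(b("rest", 5 * 60 * s)))
}

#' Simulate a synthetic monitoring cohort
#'
#' Generates a full multi-day cohort: participant profiles with a latent
#' high-activity volume, clinical measures with a known linear + Gaussian
#' dependence on that volume, per-day activity schedules whose high-load
#' (run/jump) days occur with a volume-dependent probability, 20 Hz
#' insole recordings for every worn session, and the analytic per-day
#' ground-truth cumulative load summaries.
#'
#' All randomness derives from `seed`; identical calls are identical.
#'
#' @param n_participants number of participants (>= 1).
#' @param n_days monitoring days per participant.
#' @param effect_spec clinical effect specification
#'   (see [default_effect_spec()]).
#' @param seed integer seed.
#' @param schedule_spec see [default_schedule_spec()].
#' @param artifacts optional artifact spec applied to every recording
#'   (see [inject_artifacts()]); `NULL` for an artifact-free cohort.
#' @param geometry a [sensor_geometry()].
#' @param thresholds a [load_thresholds()] for the ground truth.
#' @param latent_volumes optional vector of latent volumes in `[0, 1]`
#'   (length `n_participants`) overriding the uniform draw, e.g. all
#'   zeros for a no-high-activity cohort.
#' @return object of class `synthetic_cohort`: list with `profiles`
#'   (data frame), `clinical` (data frame, one row per participant),
#'   `recordings` (list of [insole_recording()]s), `ground_truth`
#'   (per participant-day data frame), `latent` (data frame of volumes)
#'   and the generation parameters.
#' @export
simulate_cohort <- function(n_participants = 15, n_days = 10,
                            effect_spec = default_effect_spec(), seed,
                            schedule_spec = default_schedule_spec(),
                            artifacts = NULL,
                            geometry = sensor_geometry(),
                            thresholds = load_thresholds(),
                            latent_volumes = NULL) {
  if (missing(seed) || is.null(seed))
    stop("seed must be provided", call. = FALSE)
  if (!is.finite(n_participants) || n_participants < 1)
    stop("n_participants must be >= 1", call. = FALSE)
  n_participants <- as.integer(n_participants)
  n_days <- as.integer(n_days)
  set.seed(as.integer(seed %% 2147483629L))

  v <- if (is.null(latent_volumes)) stats::runif(n_participants) else {
    stopifnot(length(latent_volumes) == n_participants)
    as.numeric(latent_volumes)
  }
  ids <- sprintf("P%02d", seq_len(n_participants))
  mass <- pmin(pmax(stats::rnorm(n_participants, 95.6, 24.9), 55), 145)
  height <- pmin(pmax(stats::rnorm(n_participants, 1.72, 0.12), 1.50), 1.95)

  clin <- data.frame(participant_id = ids, mass_kg = mass,
                     height_m = height, stringsAsFactors = FALSE)
  for (m in names(effect_spec)) {
    spc <- effect_spec[[m]]
    val <- spc$intercept + spc$slope * v +
      stats::rnorm(n_participants, 0, spc$sd)
    if (isTRUE(spc$round)) val <- round(val)
    val <- pmin(pmax(val, spc$lower), spc$upper)
    clin[[m]] <- val
  }

  # per-day activity flags drawn up front so day seeds stay independent
  p_active <- ifelse(v < schedule_spec$min_active_volume, 0,
                     pmin(schedule_spec$p_active_base +
                            schedule_spec$p_active_slope * v, 0.95))
  active <- matrix(stats::runif(n_participants * n_days) <
                     rep(p_active, each = n_days),
                   nrow = n_days, ncol = n_participants)
  schedules <- vector("list", n_participants)
  for (i in seq_len(n_participants))
    schedules[[i]] <- lapply(seq_len(n_days), function(d)
      build_day_schedule(schedule_spec, active[d, i]))

  profiles <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pas_i <- clin$pas[i]
    if (!pas_i %in% 1:6) pas_i <- min(max(round(pas_i), 1), 6)
    profiles[[i]] <- participant_profile(
      id = ids[i], mass_kg = mass[i], height_m = height[i],
      age_y = clin$age_y[i], visa_a = clin$visa_a[i], pas = pas_i,
      latent_volume = v[i])
  }

  recordings <- list()
  gt_rows <- vector("list", n_participants * n_days)
  k <- 0L
  for (i in seq_len(n_participants)) {
    prof <- profiles[[i]]
    for (d in seq_len(n_days)) {
      prof$current_day <- d
      day_seed <- (as.numeric(seed) + 7919 * i + 104729 * d) %% 2147483629
      sim <- simulate_day(prof, schedules[[i]][[d]], artifacts = artifacts,
                          seed = day_seed, geometry = geometry,
                          thresholds = thresholds,
                          sample_rate_hz = schedule_spec$sample_rate_hz,
                          peak_jitter_sd = schedule_spec$peak_jitter_sd)
      recordings <- c(recordings, sim$recordings)
      k <- k + 1L
      gt_rows[[k]] <- sim$ground_truth
    }
  }

  prof_df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(participant_id = p$id, mass_kg = p$mass_kg, bw_n = p$bw_n,
               height_m = p$height_m, age_y = p$age_y, visa_a = p$visa_a,
               pas = p$pas, latent_volume = p$latent_volume,
               stringsAsFactors = FALSE)))
  structure(list(profiles = prof_df, clinical = clin,
                 recordings = recordings,
                 ground_truth = do.call(rbind, gt_rows),
                 latent = data.frame(participant_id = ids, volume = v,
                                     stringsAsFactors = FALSE),
                 seed = seed, n_participants = n_participants,
                 n_days = n_days, geometry = geometry,
                 thresholds = thresholds),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants x %d days, seed %s\n",
              x$n_participants, x$n_days, format(x$seed)))
  cat(sprintf("  %d recordings, %.1f recorded hours total\n",
              length(x$recordings),
              sum(vapply(x$recordings, duration_s, numeric(1))) / 3600))
  invisible(x)
}
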