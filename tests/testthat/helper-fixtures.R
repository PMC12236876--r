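# Shared fixtures: compressed-day cohorts and simple series builders.
# Test cohorts use the full default day structure at a reduced duration
# scale so the suite stays fast; the adherence threshold is scaled down
# with the days.

test_profile <- function(mass_kg = 80) participant_profile("P01", mass_kg)

# load series at constant level for a given duration
const_series <- function(load_bw, duration_s, rate = 20, id = "P01",
                         day = 1L) {
  tendon_load_series(rep(load_bw, round(duration_s * rate)),
                     sample_rate_hz = rate, participant_id = id,
                     day = day)
}

# a small synthetic cohort: full day structure, compressed durations
small_cohort <- function(seed = 11, n_participants = 4, n_days = 3,
                         scale = 0.08, ...) {
  simulate_cohort(n_participants = n_participants, n_days = n_days,
                  seed = seed,
                  schedule_spec = default_schedule_spec(scale = scale),
                  ...)
}

small_config <- function(seed = 11, n_participants = 4, n_days = 3,
                         scale = 0.08, ...) {
  default_run_config(seed = seed, n_participants = n_participants,
                     n_days = n_days, schedule_scale = scale,
                     adherence_min_h = 0.05, ...)
}

# one compressed active day for a single participant
one_day <- function(seed = 7, scale = 0.25, active = TRUE,
                    profile = test_profile()) {
  set.seed(seed)
  sch <- tendonload:::build_day_schedule(default_schedule_spec(scale),
                                         active = active)
  simulate_day(profile, sch, seed = seed + 1)
}

# pipeline summary of a recording list (no QC)
summarize_recordings <- function(recs, bw_n,
                                 geometry = sensor_geometry(),
                                 thresholds = load_thresholds()) {
  rows <- lapply(recs, function(r)
    as.data.frame(summarize_series(
      estimate_tendon_load(r, geometry, bw_n), thresholds)))
  do.call(rbind, rows)
}

# per-participant ground-truth normalized loads of a synthetic cohort
cohort_gt_loads <- function(cohort) {
  gt <- stats::aggregate(
    cohort$ground_truth[c("t_load_h", "i_overall_bwh", "t_high_h",
                          "i_high_bwh")],
    by = list(participant_id = cohort$ground_truth$participant_id),
    FUN = sum)
  gt$l_overall <- gt$i_overall_bwh / gt$t_load_h
  gt$l_high <- gt$i_high_bwh / gt$t_load_h
  gt
}
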