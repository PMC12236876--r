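# independent oracle for the stance closed forms: fine-grid quadrature of
# the continuous waveform (1 kHz rectangle rule)
quad_supra <- function(kind, peak, d, th, dt = 1e-4) {
  t <- seq(dt / 2, d - dt / 2, by = dt)
  w <- peak * tendonload:::stance_waveform(kind, t / d)
  over <- w >= th
  c(time = sum(over) * dt, impulse = sum(w[over]) * dt)
}

test_that("closed-form stance time/impulse match fine-grid quadrature", {
  cases <- expand.grid(kind = c("walk", "run"), peak = c(0.9, 2.5, 4.5),
                       d = c(0.3, 0.65), th = c(0.3, 3.0),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    q <- quad_supra(cs$kind, cs$peak, cs$d, cs$th)
    expect_equal(stance_supra_time(cs$peak, cs$d, cs$th), q[["time"]],
                 tolerance = 2e-3)
    expect_equal(stance_supra_impulse(cs$peak, cs$d, cs$th),
                 q[["impulse"]], tolerance = 2e-3)
  }
  # sub-threshold stance contributes nothing
  expect_equal(stance_supra_time(0.2, 0.6, 0.3), 0)
  expect_equal(stance_supra_impulse(2.9, 0.6, 3.0), 0)
})

test_that("stance profiles honor their construction contract", {
  geom <- sensor_geometry()
  # zero peak: all channels zero, estimated load identically zero
  sp0 <- simulate_stance_profile("walk", 0, 0.6, geom, bw_n = 700)
  expect_equal(sp0$f_fore, rep(0, n_samples(sp0)))
  expect_equal(estimate_tendon_load(sp0, geom, 700)$load_bw,
               rep(0, n_samples(sp0)))

  # walk at 2.5 xBW: estimated max within 1% of target
  sp <- simulate_stance_profile("walk", 2.5, 0.6, geom, bw_n = 660)
  m <- max(estimate_tendon_load(sp, geom, 660)$load_bw)
  expect_true(m >= 2.475 && m <= 2.525)

  # run at 4.5 xBW crosses the high-level threshold on a nonempty set
  sp2 <- simulate_stance_profile("run", 4.5, 0.3, geom, bw_n = 660)
  expect_gt(sum(estimate_tendon_load(sp2, geom, 660)$load_bw > 3.0), 0)

  expect_error(simulate_stance_profile("walk", 2, 0), "stance_duration")
  expect_error(simulate_stance_profile("rest", 2, 0.6), "kind")
})

test_that("simulated days are deterministic and analytically grounded", {
  prof <- test_profile()

  # same seed twice: identical recordings
  set.seed(1)
  sch <- tendonload:::build_day_schedule(default_schedule_spec(0.1), TRUE)
  d1 <- simulate_day(prof, sch, seed = 77)
  d2 <- simulate_day(prof, sch, seed = 77)
  expect_identical(d1$recordings, d2$recordings)
  expect_identical(d1$ground_truth, d2$ground_truth)

  # pure nonwear: no recordings, zero ground truth
  nw <- simulate_day(prof, list(activity_bout("nonwear", 600)), seed = 1)
  expect_length(nw$recordings, 0)
  expect_equal(nw$ground_truth$t_load_h, 0)

  # empty schedule: same
  e <- simulate_day(prof, list(), seed = 1)
  expect_length(e$recordings, 0)
  expect_equal(e$ground_truth$i_overall_bwh, 0)

  # one 36 s bout at constant 4.0 xBW: hand integration 4.0 * 36/3600
  cb <- simulate_day(prof, list(activity_bout("walk", 36, 4.0, 0)),
                     seed = 1)
  expect_equal(cb$ground_truth$t_load_h, 0.01)
  expect_equal(cb$ground_truth$i_overall_bwh, 0.04)
  expect_equal(cb$ground_truth$t_high_h, 0.01)
  expect_equal(cb$ground_truth$i_high_bwh, 0.04)

  expect_error(simulate_day(prof, list()), "seed")
})

test_that("day-level pipeline summaries track the analytic ground truth", {
  prof <- test_profile()
  d <- one_day(seed = 3, scale = 0.3, active = TRUE, profile = prof)
  expect_gt(length(d$recordings), 1)  # nonwear splits the day
  pip <- colSums(summarize_recordings(d$recordings, prof$bw_n)[
    c("t_load_h", "i_overall_bwh", "t_high_h", "i_high_bwh")])
  gt <- unlist(d$ground_truth[c("t_load_h", "i_overall_bwh", "t_high_h",
                                "i_high_bwh")])
  expect_equal(unname(pip), unname(gt), tolerance = 0.02)
})

test_that("artifact injection is pure and by construction detectable", {
  prof <- test_profile()
  d <- one_day(seed = 5, scale = 0.15, active = FALSE, profile = prof)
  rec <- d$recordings[[1]]

  # empty spec: identity
  expect_identical(inject_artifacts(rec, NULL, prof$bw_n), rec)
  expect_identical(inject_artifacts(rec, list(), prof$bw_n), rec)
  expect_error(inject_artifacts(rec, list(kind = "spikes"), prof$bw_n),
               "unknown artifact")

  # constant +0.1 xBW from t0: unloaded segments read 0.1 xBW, original
  # untouched
  before <- rec$f_fore
  dr <- inject_artifacts(rec, list(kind = "drift", offset_bw = 0.1),
                         prof$bw_n)
  expect_identical(rec$f_fore, before)
  load <- estimate_tendon_load(dr, sensor_geometry(), prof$bw_n)$load_bw
  clean <- estimate_tendon_load(rec, sensor_geometry(),
                                prof$bw_n)$load_bw
  unloaded <- clean == 0
  expect_gt(mean(unloaded), 0.05)
  expect_equal(median(load[unloaded]), 0.1, tolerance = 1e-6)

  # erroneous mode must trip the QC screen
  er <- inject_artifacts(rec, list(kind = "erroneous"), prof$bw_n)
  expect_true("constant_offset" %in%
                flag_erroneous(er, prof$bw_n)$flags)
})

test_that("cohort generation is seeded, validated and effect-faithful", {
  expect_error(simulate_cohort(0, 2, seed = 1), "n_participants")
  expect_error(simulate_cohort(2, 2), "seed")

  co1 <- small_cohort(seed = 21, n_participants = 2, n_days = 2)
  co2 <- small_cohort(seed = 21, n_participants = 2, n_days = 2)
  expect_identical(co1$recordings, co2$recordings)
  expect_identical(co1$clinical, co2$clinical)

  # zero latent volume everywhere: no high-level ground truth at all
  co0 <- small_cohort(seed = 22, n_participants = 3, n_days = 2,
                      latent_volumes = rep(0, 3))
  expect_equal(sum(co0$ground_truth$i_high_bwh), 0)

  # noiseless spec: clinical measures are exactly linear in the latent
  # volume (PAS is rounded to its 1-6 scale, so near- rather than
  # exactly linear)
  con <- small_cohort(seed = 23, n_participants = 8, n_days = 1,
                      scale = 0.02,
                      effect_spec = default_effect_spec(noise_scale = 0))
  v <- con$latent$volume
  for (m in setdiff(clinical_measure_names(), "pas"))
    expect_equal(abs(cor(v, con$clinical[[m]])), 1.0, tolerance = 1e-10)
  expect_gt(abs(cor(v, con$clinical$pas)), 0.95)
})

test_that("sampled correlations approach the closed-form implied r", {
  # generate many participants' clinical draws without any signal data
  spec <- default_effect_spec()
  set.seed(31)
  n <- 4000
  v <- runif(n)
  for (m in c("heel_raise_height_pbh", "visa_a", "age_y")) {
    sp <- spec[[m]]
    val <- sp$intercept + sp$slope * v + rnorm(n, 0, sp$sd)
    expect_equal(cor(v, val), implied_effect_r(sp), tolerance = 0.05)
  }
  expect_lt(implied_effect_r(spec$age_y), 0)  # age runs against volume
})

test_that("activity bouts and schedules are validated", {
  expect_error(activity_bout("swim", 10), "kind")
  expect_error(activity_bout("walk", 0), "duration")
  expect_error(activity_bout("walk", 10, -1), "peak_load_bw")
  expect_error(validate_schedule(list(activity_bout("walk", 5), 3)),
               "element 2")
  expect_silent(validate_schedule(list()))
})
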