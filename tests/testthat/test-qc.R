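test_that("drift correction is a no-op on clean signal", {
  prof <- test_profile()
  d <- one_day(seed = 13, scale = 0.15, active = FALSE, profile = prof)
  rec <- d$recordings[[1]]
  res <- correct_drift(rec, prof$bw_n)
  expect_false(res$report$corrected)
  expect_identical(res$recording, rec)
  expect_equal(res$report$disposition, "keep")
})

test_that("injected baseline offsets are detected and removed", {
  prof <- test_profile()
  d <- one_day(seed = 14, scale = 0.2, active = FALSE, profile = prof)
  rec <- d$recordings[[1]]
  geom <- sensor_geometry()
  clean_load <- estimate_tendon_load(rec, geom, prof$bw_n)$load_bw
  unloaded <- clean_load == 0

  dr <- inject_artifacts(rec, list(kind = "drift", offset_bw = 0.1),
                         prof$bw_n)
  res <- correct_drift(dr, prof$bw_n)
  expect_true(res$report$corrected)
  expect_equal(res$report$disposition, "keep")
  fixed_load <- estimate_tendon_load(res$recording, geom,
                                     prof$bw_n)$load_bw
  expect_lt(median(fixed_load[unloaded]), 0.02)

  # correction is idempotent
  res2 <- correct_drift(res$recording, prof$bw_n)
  expect_equal(res2$recording$f_fore, res$recording$f_fore)
  expect_equal(res2$recording$f_heel, res$recording$f_heel)
})

test_that("unrecoverable sessions are dropped with the right flag", {
  prof <- test_profile()
  d <- one_day(seed = 15, scale = 0.15, active = FALSE, profile = prof)
  rec <- d$recordings[[1]]

  # offset so large the session never returns near zero
  big <- inject_artifacts(rec, list(kind = "erroneous", offset_bw = 0.8),
                          prof$bw_n)
  res <- correct_drift(big, prof$bw_n)
  expect_true("drift_excessive" %in% res$report$flags)
  expect_equal(res$report$disposition, "drop")

  # shorter than the envelope window
  short <- insole_recording(rep(0, 100), rep(0, 100), rep(0, 100))
  res2 <- correct_drift(short, prof$bw_n)
  expect_true("too_short" %in% res2$report$flags)
  expect_equal(res2$report$disposition, "drop")
})

test_that("sub-fatal drift leaves post-QC metrics within 2% of clean", {
  prof <- test_profile()
  d <- one_day(seed = 16, scale = 0.4, active = TRUE, profile = prof)
  geom <- sensor_geometry()
  for (offset in c(0.08, 0.25)) {
    clean <- summarize_recordings(d$recordings, prof$bw_n)
    cl <- colSums(clean[c("t_load_h", "i_overall_bwh")])
    fixed <- lapply(d$recordings, function(r) {
      dr <- inject_artifacts(r, list(kind = "drift", offset_bw = offset,
                                     onset_s = 60), prof$bw_n)
      qc_recording(dr, prof$bw_n)$recording
    })
    fx <- colSums(summarize_recordings(fixed, prof$bw_n)[
      c("t_load_h", "i_overall_bwh")])
    expect_equal(unname(fx), unname(cl), tolerance = 0.02)
  }
})

test_that("erroneous-recording rules fire as specified", {
  prof <- test_profile()
  d <- one_day(seed = 17, scale = 0.15, active = FALSE, profile = prof)
  rec <- d$recordings[[1]]

  # normal wear: no flags
  expect_length(flag_erroneous(rec, prof$bw_n)$flags, 0)

  # always-loaded session (bad initialization): rule (a)
  er <- inject_artifacts(rec, list(kind = "erroneous"), prof$bw_n)
  rep_a <- flag_erroneous(er, prof$bw_n)
  expect_true("constant_offset" %in% rep_a$flags)
  expect_equal(rep_a$disposition, "drop")

  # 30 s session: rule (c)
  short <- insole_recording(rep(0, 600), rep(0, 600), rep(0, 600))
  expect_true("too_short" %in% flag_erroneous(short, prof$bw_n)$flags)

  # negative rail: rule (b)
  neg <- rec
  neg$f_mid <- neg$f_mid - 0.2 * prof$bw_n
  expect_true("negative_rail" %in% flag_erroneous(neg, prof$bw_n)$flags)

  expect_error(flag_erroneous(insole_recording(numeric(0), numeric(0),
                                               numeric(0)), 700),
               "empty")
})

test_that("adherence check excludes sparse wearers", {
  mk <- function(h) data.frame(participant_id = "P01",
                               day = seq_along(h), t_load_h = h)
  # the 1-3 recorded hours per day case, against a 4 h threshold
  expect_equal(check_adherence(mk(c(0.5, 1.2, 2.9)), 4), "exclude")
  expect_equal(check_adherence(mk(c(6, 7, 6.5)), 4), "keep")
  # degenerate threshold keeps everyone
  expect_equal(check_adherence(mk(c(0.1, 0.1)), 0), "keep")
})

test_that("QC changes no metric materially on an artifact-free cohort", {
  co <- small_cohort(seed = 18, n_participants = 2, n_days = 2,
                     scale = 0.15)
  bw <- setNames(co$profiles$bw_n, co$profiles$participant_id)
  raw <- do.call(rbind, lapply(co$recordings, function(r)
    as.data.frame(summarize_series(estimate_tendon_load(
      r, sensor_geometry(), bw[[r$participant_id]])))))
  qcd <- do.call(rbind, lapply(co$recordings, function(r) {
    res <- qc_recording(r, bw[[r$participant_id]])
    expect_equal(res$report$disposition, "keep")
    as.data.frame(summarize_series(estimate_tendon_load(
      res$recording, sensor_geometry(), bw[[r$participant_id]])))
  }))
  expect_equal(sum(qcd$i_overall_bwh), sum(raw$i_overall_bwh),
               tolerance = 0.001)
  expect_equal(sum(qcd$t_load_h), sum(raw$t_load_h), tolerance = 0.001)
})
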