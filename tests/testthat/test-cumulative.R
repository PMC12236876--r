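test_that("piecewise-constant series match closed-form integrals exactly", {
  th <- load_thresholds()

  # below the overall threshold: nothing accumulates
  s1 <- summarize_series(const_series(0.25, 3600), th)
  expect_equal(unlist(s1[c("t_load_h", "i_overall_bwh", "t_high_h",
                           "i_high_bwh")], use.names = FALSE),
               c(0, 0, 0, 0))

  # 36 s at 4.0 xBW: 0.01 h and 4.0 * 36/3600 = 0.04 xBW.h at both levels
  s2 <- summarize_series(const_series(4.0, 36), th)
  expect_equal(s2$t_load_h, 0.01)
  expect_equal(s2$i_overall_bwh, 0.04)
  expect_equal(s2$t_high_h, 0.01)
  expect_equal(s2$i_high_bwh, 0.04)

  # between thresholds: counts toward overall only
  s3 <- summarize_series(const_series(1.0, 2 * 3600), th)
  expect_equal(s3$t_load_h, 2)
  expect_equal(s3$i_overall_bwh, 2)
  expect_equal(s3$t_high_h, 0)
  expect_equal(s3$i_high_bwh, 0)

  # empty series: all-zero summary
  s4 <- summarize_series(tendon_load_series(numeric(0)), th)
  expect_equal(s4$t_load_h, 0)
  expect_equal(s4$i_high_bwh, 0)
})

test_that("threshold comparison is closed at the threshold", {
  th <- load_thresholds()
  s <- summarize_series(const_series(0.3, 360), th)  # exactly at overall
  expect_equal(s$t_load_h, 0.1)
  expect_equal(s$i_overall_bwh, 0.03)
  s2 <- summarize_series(const_series(3.0, 360), th)  # exactly at high
  expect_equal(s2$t_high_h, 0.1)
})

test_that("summaries are additive over concatenation and monotone", {
  set.seed(5)
  a <- pmax(rnorm(2000, 1, 1.2), 0)
  b <- pmax(rnorm(1500, 2, 1.5), 0)
  th <- load_thresholds()
  whole <- summarize_series(tendon_load_series(c(a, b)), th)
  pa <- summarize_series(tendon_load_series(a), th)
  pb <- summarize_series(tendon_load_series(b), th)
  for (f in c("t_load_h", "i_overall_bwh", "t_high_h", "i_high_bwh"))
    expect_equal(whole[[f]], pa[[f]] + pb[[f]])

  # appending a supra-high bout strictly increases all four quantities
  more <- summarize_series(tendon_load_series(c(a, rep(3.5, 40))), th)
  for (f in c("t_load_h", "i_overall_bwh", "t_high_h", "i_high_bwh"))
    expect_gt(more[[f]], pa[[f]])
})

test_that("summary invariants hold on random series", {
  th <- load_thresholds()
  set.seed(99)
  for (i in 1:20) {
    s <- summarize_series(
      tendon_load_series(pmax(rnorm(500, runif(1, 0, 3), 1.5), 0)), th)
    expect_lte(s$t_high_h, s$t_load_h)
    expect_lte(s$i_high_bwh, s$i_overall_bwh)
    expect_gte(s$i_overall_bwh, th$overall * s$t_load_h)
    expect_gte(s$i_high_bwh, th$high * s$t_high_h)
  }
})

test_that("participant aggregation divides impulse by total loading time", {
  df <- data.frame(participant_id = "P01", t_load_h = c(0.5, 1.5),
                   i_overall_bwh = c(0.45, 1.55), t_high_h = c(0.1, 0.1),
                   i_high_bwh = c(0.08, 0.08))
  agg <- aggregate_participant(df)
  expect_equal(agg$l_overall, 1.0)   # 2.0 / 2.0
  expect_equal(agg$l_high, 0.08)     # 0.16 / 2.0
  expect_true(agg$defined)
  expect_gte(agg$l_overall, 0.3)     # definition invariant
})

test_that("degenerate and mixed-participant aggregations are handled", {
  zero <- data.frame(participant_id = "P01", t_load_h = 0,
                     i_overall_bwh = 0, t_high_h = 0, i_high_bwh = 0)
  agg <- aggregate_participant(zero)
  expect_false(agg$defined)
  expect_true(is.na(agg$l_overall))

  mixed <- data.frame(participant_id = c("P01", "P02"),
                      t_load_h = c(1, 1), i_overall_bwh = c(1, 1),
                      t_high_h = c(0, 0), i_high_bwh = c(0, 0))
  expect_error(aggregate_participant(mixed), "multiple participants")
  expect_error(aggregate_participant(list()), "at least one")
})

test_that("thresholds must be ordered", {
  expect_error(load_thresholds(0.3, 0.2), "overall < high")
  expect_error(load_thresholds(0, 3), "overall < high")
})
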