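mk_days <- function(id, l_overall_by_day, t_load = 1,
                    l_high_by_day = 0 * l_overall_by_day) {
  data.frame(participant_id = id, day = seq_along(l_overall_by_day),
             t_load_h = t_load,
             i_overall_bwh = l_overall_by_day * t_load,
             t_high_h = 0, i_high_bwh = l_high_by_day * t_load,
             stringsAsFactors = FALSE)
}

test_that("MAPE arithmetic and zero-reference policy", {
  expect_equal(as.numeric(mape(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(mape(1.1, 1.0)), 10)
  expect_equal(as.numeric(mape(c(0.0, 0.2), c(0.1, 0.1))), 100)
  # reference zero: 0% if the estimate is also zero, else excluded
  m <- mape(c(0, 0.5, 2), c(0, 0, 1))
  expect_equal(as.numeric(m), (0 + 100) / 2)
  expect_equal(attr(m, "n_excluded"), 1)
  expect_error(mape(numeric(0), numeric(0)), "nonempty")
  expect_error(mape(1, c(1, 2)), "paired")
})

test_that("subset estimates enumerate combinations of the first six days", {
  d <- mk_days("P01", c(1, 1, 1, 1, 1, 1), l_high_by_day = 0.1)
  # identical days: every subset equals the full estimate
  for (k in 1:6) {
    est <- subsample_estimates(d, k)
    expect_equal(nrow(est), choose(6, k))
    expect_equal(est$l_overall, rep(1, choose(6, k)))
    expect_equal(est$l_high, rep(0.1, choose(6, k)))
  }
  # k = 6 is the single first-six-days subset
  expect_equal(nrow(subsample_estimates(d, 6)), 1)

  # two days with equal loading time, day l_high 0.0 and 0.2
  d2 <- mk_days("P02", c(1, 1), l_high_by_day = c(0.0, 0.2))
  ref <- aggregate_participant(d2)
  expect_equal(ref$l_high, 0.1)
  est1 <- subsample_estimates(d2, 1)
  expect_setequal(est1$l_high, c(0.0, 0.2))
  expect_true(all(est1$limited))  # fewer than six recorded days

  expect_error(subsample_estimates(d, 0), "between 1 and 6")
  expect_error(subsample_estimates(d, 7), "between 1 and 6")
  # more days requested than available: zero rows
  expect_equal(nrow(subsample_estimates(mk_days("P03", c(1, 1)), 3)), 0)
})

test_that("fast path equals exhaustive naive enumeration on a toy cohort", {
  set.seed(8)
  toy <- do.call(rbind, lapply(c("A", "B", "C"), function(id)
    mk_days(id, runif(6, 0.8, 1.4), t_load = runif(6, 0.5, 2),
            l_high_by_day = runif(6, 0, 0.3))))
  for (k in c(1, 3, 5)) {
    for (id in c("A", "B", "C")) {
      sub <- toy[toy$participant_id == id, ]
      est <- subsample_estimates(sub, k)
      combos <- combn(6, k)
      # independent recomputation: direct ratio of summed impulses/times
      naive <- apply(combos, 2, function(ix)
        sum(sub$i_overall_bwh[ix]) / sum(sub$t_load_h[ix]))
      expect_equal(est$l_overall, naive)
      naive_high <- apply(combos, 2, function(ix)
        sum(sub$i_high_bwh[ix]) / sum(sub$t_load_h[ix]))
      expect_equal(est$l_high, naive_high)
    }
  }
})

test_that("subsampling the full day set reproduces the reference exactly", {
  set.seed(9)
  toy <- do.call(rbind, lapply(c("A", "B"), function(id)
    mk_days(id, runif(6, 0.8, 1.4), t_load = runif(6, 0.5, 2),
            l_high_by_day = runif(6, 0, 0.3))))
  res <- subsampling_curve(toy, ks = 6)
  expect_equal(res$mape_pct, c(0, 0), tolerance = 1e-12)
  expect_equal(res$r, c(1, 1), tolerance = 1e-12)
})

test_that("identical-day cohorts give zero MAPE at every k", {
  toy <- do.call(rbind, lapply(c("A", "B", "C"), function(id)
    mk_days(id, rep(runif(1, 0.8, 1.4), 6),
            l_high_by_day = rep(runif(1, 0, 0.3), 6))))
  res <- subsampling_curve(toy)
  expect_equal(res$mape_pct, rep(0, nrow(res)), tolerance = 1e-12)
})

test_that("curve input validation", {
  single <- mk_days("A", 1)
  expect_error(subsampling_curve(single), ">= 2 days")
})

test_that("day summaries collapse sessions and participants correctly", {
  df <- data.frame(participant_id = c("A", "A", "A", "B"),
                   day = c(1, 1, 2, 1), session = c(1, 2, 1, 1),
                   t_load_h = c(0.2, 0.3, 0.4, 1),
                   i_overall_bwh = c(0.2, 0.3, 0.5, 1.2),
                   t_high_h = 0, i_high_bwh = 0)
  dd <- day_summaries(df)
  expect_equal(nrow(dd), 3)
  expect_equal(dd$t_load_h[dd$participant_id == "A" & dd$day == 1], 0.5)
  ps <- participant_summaries(dd)
  expect_equal(ps$l_overall[ps$participant_id == "A"], 1.0 / 0.9)
  expect_equal(ps$days_used, c(2, 1))
})
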