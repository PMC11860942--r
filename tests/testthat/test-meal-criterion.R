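test_that("gaps are feeder-free time in minutes, empty for single visits", {
  v <- make_clean_visits(c("2018-03-01 08:00:00", "2018-03-01 08:04:00",
                           "2018-03-01 08:05:00"),
                         c(120, 60, 30), 10)
  g <- compute_gaps(v)
  expect_equal(g$gap_min, c(2, 0))  # 08:02 -> 08:04, then back-to-back

  single <- make_clean_visits("2018-03-01 08:00:00", 120, 10)
  expect_equal(nrow(compute_gaps(single)), 0)
})

test_that("Pstart follows the at-risk ratio definition (hand-enumerated sets)", {
  cur <- estimate_pstart(c(0.5, 1.5, 2.5, 11, 14))
  expect_equal(cur$raw[cur$t == 0], 1 / 5)
  expect_equal(cur$raw[cur$t == 1], 1 / 4)
  expect_equal(cur$raw[cur$t == 2], 1 / 3)
  expect_true(all(cur$raw[cur$t %in% c(3:10, 12, 13)] == 0))
  expect_equal(cur$raw[cur$t == 11], 1 / 2)
  expect_equal(cur$raw[cur$t == 14], 1)
  expect_true(all(is.na(cur$raw[cur$t > 14])))

  cur2 <- estimate_pstart(c(0.1, 0.4, 0.9))
  expect_equal(cur2$raw[1], 1)
  expect_true(all(is.na(cur2$raw[-1])))

  cur3 <- estimate_pstart(c(5.2, 5.9))
  expect_true(all(cur3$raw[cur3$t <= 4] == 0))
  expect_true(all(cur3$n_at_risk[cur3$t <= 5] == 2))
  expect_equal(cur3$raw[cur3$t == 5], 1)

  expect_error(estimate_pstart(numeric(0)), "no intervals")
})

test_that("gaps beyond the window are censored into the at-risk counts only", {
  cur <- estimate_pstart(c(2.5, 70, 90), t_max = 60)
  expect_equal(cur$n_at_risk, c(3L, 3L, 3L, rep(2L, 57)))
  expect_equal(sum(cur$n_events), 1)  # only the gap below t_max is an event
  expect_equal(cur$raw[cur$t == 2], 1 / 3)
})

test_that("Pstart invariants hold on random gap sets", {
  set.seed(101)
  for (i in 1:5) {
    gaps <- c(rexp(300, 1 / 0.8), 5 + rlnorm(100, log(30), 1))
    cur <- estimate_pstart(gaps)
    ok <- !is.na(cur$raw)
    expect_true(all(cur$raw[ok] >= 0 & cur$raw[ok] <= 1))
    expect_true(all(diff(cur$n_at_risk) <= 0))
    expect_equal(sum(cur$n_events), sum(gaps < 60))
    if (max(gaps) < 60) {
      last <- max(which(cur$n_at_risk > 0))
      expect_equal(cur$raw[last], 1)
    }
  }
})

test_that("rolling smoothing averages defined bins with truncated edges", {
  cur <- tibble::tibble(t = 0:5, raw = c(0.5, 0.4, 0.3, 0.1, 0.05, NA),
                        n_events = 0L, n_at_risk = 1L)
  sm <- smooth_curve(cur, window = 5)
  expect_equal(sm$smoothed[3], mean(c(0.5, 0.4, 0.3, 0.1, 0.05)))
  expect_equal(sm$smoothed[1], mean(c(0.5, 0.4, 0.3)))          # edge truncation
  expect_equal(sm$smoothed[6], mean(c(0.1, 0.05)))              # NA skipped

  const <- tibble::tibble(t = 0:9, raw = rep(0.2, 10))
  expect_true(all(smooth_curve(const)$smoothed == 0.2))
  expect_error(smooth_curve(const, window = 4), "odd")
})

test_that("criterion sits at the first negative-to-positive turn", {
  cur <- tibble::tibble(t = 0:6,
                        smoothed = c(0.30, 0.20, 0.12, 0.08, 0.07, 0.09, 0.15))
  expect_equal(find_criterion(cur)$criterion, 4L)
  expect_equal(find_criterion(cur)$source, "sign-change")

  # V-shape with minimum at bin 9
  vshape <- tibble::tibble(t = 0:18, smoothed = c(9:0, 1:9) / 20)
  expect_equal(find_criterion(vshape)$criterion, 9L)

  mono <- tibble::tibble(t = 0:9, smoothed = seq(0.5, 0.05, length.out = 10))
  res <- find_criterion(mono)
  expect_equal(res$source, "no-sign-change")
  expect_equal(res$criterion, 9L)

  expect_equal(find_criterion(tibble::tibble(t = 0:4,
                                             smoothed = c(0.3, NA, NA, NA, 0.1)))$source,
               "too-few-bins")
})

test_that("zero plateaus inside a descent do not end the criterion scan", {
  cur <- tibble::tibble(t = 0:8,
                        smoothed = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1, 0.2, 0.3, 0.4))
  # descent ends at bin 2; plateau of the minimum runs to bin 5; first bin wins
  expect_equal(find_criterion(cur)$criterion, 2L)
})

test_that("an exactly constant hazard triggers the no-sign-change fallback", {
  # the discrete hazard of an exponential gap law is flat: no interior minimum
  cur <- tibble::tibble(t = 0:29, smoothed = rep(0.25, 30))
  expect_equal(find_criterion(cur)$source, "no-sign-change")
  # and the empirical raw curve from exponential gaps is approximately flat
  set.seed(7)
  gaps <- rexp(50000, rate = 1 / 4)
  cur2 <- estimate_pstart(gaps, t_max = 20)
  theo <- 1 - exp(-1 / 4)
  expect_lt(max(abs(cur2$raw[cur2$n_at_risk > 2000] - theo)), 0.03)
})

test_that("cohort criteria use pooled fallback below the gap threshold", {
  co <- small_cohort()
  few <- make_clean_visits(c("2018-03-05 08:00:00", "2018-03-05 10:00:00",
                             "2018-03-05 14:00:00"), 60, 100,
                           animal_id = "SPARSE", pen_id = "P01", breed = "B1")
  visits <- dplyr::bind_rows(co$visits, few)
  cr <- criteria_for_cohort(visits, min_gaps = 50)
  expect_equal(cr$source[cr$animal_id == "SPARSE"], "pooled-fallback")
  rich <- cr[cr$n_gaps >= 50, ]
  expect_true(all(rich$source %in% c("individual", "individual-argmin")))
  expect_true(all(cr$criterion_min >= 1 & cr$criterion_min <= 60))
  expect_error(criteria_for_cohort(make_clean_visits("2018-03-05 08:00:00", 60, 100)),
               "no inter-visit gaps")
})
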