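pen_visits <- function(offsets_min, ids) {
  make_clean_visits(format(ts_utc("2018-03-01 08:00:00") + offsets_min * 60,
                           "%Y-%m-%d %H:%M:%S"),
                    duration_s = 30, intake_g = 50, animal_id = ids)
}

test_that("pen feeding events are maximal runs of start-to-start gaps", {
  # successive start gaps 1, 2, 30, 1 minutes with threshold 10 -> sizes 3, 2
  v <- pen_visits(cumsum(c(0, 1, 2, 30, 1)), c("A", "B", "A", "C", "B"))
  ev <- build_pen_events(v, threshold = 10)
  expect_equal(as.integer(table(ev$event_id)), c(3L, 2L))

  singletons <- build_pen_events(pen_visits(c(0, 20, 40), c("A", "B", "C")),
                                 threshold = 10)
  expect_equal(max(singletons$event_id), 3)
  expect_true(all(singletons$event_size == 1))

  one <- build_pen_events(pen_visits(c(0, 5, 10), c("A", "B", "C")), threshold = 10)
  expect_equal(max(one$event_id), 1)
})

test_that("Position is the mean standardised entry order", {
  v <- pen_visits(c(0, 1, 2), c("A", "B", "B"))
  pos <- compute_position(build_pen_events(v, threshold = 10))
  expect_equal(pos$Position[pos$animal_id == "A"], 1 / 3)
  expect_equal(pos$Position[pos$animal_id == "B"], mean(c(2 / 3, 1)))

  solo <- compute_position(build_pen_events(pen_visits(0, "A"), threshold = 10))
  expect_equal(solo$Position, 1)

  # always first in events of size 14
  v14 <- pen_visits(c(0:13, 100 + 0:13), c(sprintf("A%02d", 1:14), sprintf("A%02d", 1:14)))
  pos14 <- compute_position(build_pen_events(v14, threshold = 10))
  expect_equal(pos14$Position[pos14$animal_id == "A01"], 1 / 14)
})

test_that("uniformly random queue order gives Position near (n+1)/2n", {
  set.seed(33)
  n <- 12
  vals <- replicate(400, {
    ord <- sample(n)
    mean((seq_len(n) / n)[ord == 1])
  })
  expect_lt(abs(mean(vals) - (n + 1) / (2 * n)), 0.02)
  # and the estimator reproduces it through the event machinery
  ids <- sprintf("A%02d", 1:6)
  v <- pen_visits(0:5, sample(ids))
  pos <- compute_position(build_pen_events(v, threshold = 10))
  expect_equal(sort(pos$Position), (1:6) / 6)
})

test_that("preferred-time ratios use half-open clock windows", {
  v <- make_clean_visits(c("2018-03-01 07:30:00", "2018-03-01 09:00:00",
                           "2018-03-01 21:00:00"), 60, 100)
  pt <- compute_pref_time(v)
  expect_equal(pt$ratePrefTime_a, 1 / 3)
  expect_equal(pt$ratePrefTime_b, 1 / 3)

  all_in <- make_clean_visits(c("2018-03-01 09:00:00", "2018-03-01 15:30:00"), 60, 100)
  expect_equal(compute_pref_time(all_in)$ratePrefTime_a, 1)

  boundary <- make_clean_visits("2018-03-01 20:00:00", 60, 100)
  expect_equal(compute_pref_time(boundary)$ratePrefTime_a, 0)

  t1 <- compute_pref_time(v, window_b = "table1")
  expect_equal(t1$ratePrefTime_b, 2 / 3)  # 07:30 and 09:00 fall in 07-11
  expect_error(compute_pref_time(v, window_b = "nope"), "preset")
})

test_that("daily shares divide by the pen total and average over days", {
  daily <- tibble::tibble(
    animal_id = rep(c("A", "B", "C"), 2), pen_id = "P1", breed = "B1",
    day_index = rep(0:1, each = 3),
    TNM = c(2, 4, 2, 3, 3, 3), TNV = c(2, 4, 2, 3, 3, 3),
    FI_day = c(1000, 2000, 1000, 400, 400, 1200),
    OT_day = c(100, 100, 100, 100, 100, 100)
  )
  sh <- compute_daily_shares(daily)
  expect_equal(sh$rateFI[sh$animal_id == "B"], mean(c(0.5, 0.2)))
  expect_equal(sh$rateOT, rep(1 / 3, 3))
  expect_equal(sh$rateNM[sh$animal_id == "A"], mean(c(0.25, 1 / 3)))

  # zero pen-day totals are skipped for that trait
  daily0 <- daily
  daily0$FI_day[daily0$day_index == 1] <- 0
  sh0 <- compute_daily_shares(daily0)
  expect_equal(sh0$rateFI[sh0$animal_id == "B"], 0.5)
})

test_that("pen-day shares sum to one over members", {
  co <- small_cohort()
  shares <- dplyr::summarise(
    dplyr::group_by(co$daily, pen_id, day_index),
    s_nv = sum(TNV / sum(TNV)), s_nm = sum(TNM / sum(TNM)),
    s_fi = sum(FI_day / sum(FI_day)), s_ot = sum(OT_day / sum(OT_day)),
    .groups = "drop"
  )
  expect_true(all(abs(shares$s_nv - 1) < 1e-9))
  expect_true(all(abs(shares$s_nm - 1) < 1e-9))
  expect_true(all(abs(shares$s_fi - 1) < 1e-9))
  expect_true(all(abs(shares$s_ot - 1) < 1e-9))
})

test_that("dominance-driven access reproduces the expected sign pattern", {
  co <- small_cohort()
  rank <- social_rank_traits(co$visits, co$daily, co$criteria)
  expect_true(all(rank$Position > 0 & rank$Position <= 1))
  summ <- build_summary(co$meals, co$daily, rank,
                        tibble::tibble(animal_id = rank$animal_id))
  expect_gt(cor(summ$rateNM, summ$rateNV), 0.9)
  expect_lt(cor(summ$rateNM, summ$Position), 0)
  expect_lt(cor(summ$TNM, summ$Position), 0)
})
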