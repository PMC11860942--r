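test_that("simulation is reproducible and pens never double-book the feeder", {
  cfg <- sim_config(n_pens = 1, n_days = 20)
  s1 <- simulate_pens(cfg, seed = 42)
  s2 <- simulate_pens(cfg, seed = 42)
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$roster, s2$roster)
  s3 <- simulate_pens(cfg, seed = 43)
  expect_false(identical(s1$visits, s3$visits))

  v <- s1$visits[order(s1$visits$t_start), ]
  expect_true(all(as.numeric(v$t_start)[-1] >= head(as.numeric(v$t_end), -1)))
  expect_true(all(v$duration_s > 0))
  expect_true(all(v$intake_g >= 0))
  expect_true(all(v$weight_g > 0))
})

test_that("pens are independent substreams of the root seed", {
  one <- simulate_pens(sim_config(n_pens = 1, n_days = 10), seed = 9)
  two <- simulate_pens(sim_config(n_pens = 2, n_days = 10), seed = 9)
  expect_identical(one$visits, two$visits[two$visits$pen_id == "P01", ])
})

test_that("without dominance effects no systematic feeder order emerges", {
  cfg <- sim_config(n_pens = 4, n_days = 15, dom_tnm = 0, dom_pref = 0,
                    dom_rate = 0, dom_queue = FALSE)
  sim <- simulate_pens(cfg, seed = 77)
  cl <- clean_visits(sim$visits, sim$roster)
  ev <- build_pen_events(cl$visits, threshold = 9)
  pos <- compute_position(ev)
  j <- dplyr::inner_join(pos, sim$truth$animals, by = "animal_id")
  ct <- stats::cor.test(j$dominance, j$Position)
  expect_gt(ct$p.value, 0.001)
})

test_that("zero growth noise lets the regression recover the configured gain", {
  cfg <- sim_config(n_pens = 1, n_days = 12, adg_sd_gd = 0, weight_noise_sd_g = 0)
  sim <- simulate_pens(cfg, seed = 5)
  cl <- clean_visits(sim$visits, sim$roster)
  for (a in unique(cl$visits$animal_id)[1:5]) {
    va <- cl$visits[cl$visits$animal_id == a, ]
    age <- va$day_index + (as.numeric(va$t_start) %% 86400) / 86400
    expect_equal(compute_adg_reg(age, va$weight_g), 950, tolerance = 1e-3)
  }
})

test_that("the theoretical hazard trough sits in the 9-10 minute bin", {
  hz <- theoretical_hazard(sim_config())
  expect_gte(hz$argmin, 9)
  expect_lt(hz$argmin, 10)
  expect_true(all(hz$curve$hazard >= 0 & hz$curve$hazard <= 1, na.rm = TRUE))
})

test_that("removing the within-meal component leaves a rising post-shift hazard", {
  cfg <- sim_config(nvm_extra_mean = 0)
  hz <- theoretical_hazard(cfg)
  expect_equal(hz$p_within, 0)
  expect_true(all(hz$curve$hazard[hz$curve$t < cfg$between_shift_min] == 0))
  post <- hz$curve$hazard[hz$curve$t >= 6 & hz$curve$t <= 25]
  expect_true(all(diff(post) > 0))
})

test_that("doubling every gap-law time scale doubles the trough location", {
  cfg1 <- sim_config()
  cfg2 <- sim_config(
    within_gap_mean_min = cfg1$within_gap_mean_min * 2,
    within_int_median_min = cfg1$within_int_median_min * 2,
    within_gap_max_min = cfg1$within_gap_max_min * 2,
    between_shift_min = cfg1$between_shift_min * 2,
    between_cap_min = cfg1$between_cap_min * 2,
    tnm_day0 = cfg1$tnm_day0 / 2, tnm_peak = cfg1$tnm_peak / 2,
    tnm_late = cfg1$tnm_late / 2
  )
  a1 <- theoretical_hazard(cfg1)$argmin
  a2 <- theoretical_hazard(cfg2, t_max = 120)$argmin
  expect_gte(a2, 2 * a1 - 1)
  expect_lte(a2, 2 * a1 + 2)
})

test_that("hourly visit histogram peaks at the configured circadian modes", {
  co <- small_cohort()
  h <- as.integer(format(co$visits$t_start, "%H"))
  counts <- tabulate(h + 1, nbins = 24)
  # bimodal: both mode bins (9 and 17) beat the night floor and the midday dip
  expect_gt(counts[10], max(counts[1:7]))   # hour 9 vs hours 0-6
  expect_gt(counts[10], counts[14])         # hour 9 vs hour 13
  expect_gt(counts[18], counts[14])         # hour 17 vs hour 13
  expect_gt(counts[18], max(counts[22:24])) # hour 17 vs late night
})

test_that("an overstocked configuration is rejected up front", {
  expect_error(simulate_pens(sim_config(animals_per_pen = 80L), seed = 1),
               class = "penfeedr_config_error")
  expect_error(sim_config(nonsense = 1), class = "penfeedr_config_error")
})

test_that("the configuration round-trips through JSON losslessly", {
  cfg <- sim_config(n_pens = 5L, circadian_sd = 2.25)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg2 <- do.call(sim_config, back)
  expect_equal(unclass(cfg2), unclass(cfg))
})
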