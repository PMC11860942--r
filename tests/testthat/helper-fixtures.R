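# hand-built fixtures and cached simulations shared across test files

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# a visit table in the raw-log layout; times given as "YYYY-mm-dd HH:MM:SS"
make_visits <- function(t_start, duration_s, intake_g,
                        animal_id = "A1", pen_id = "P1", breed = "B1",
                        weight_g = 50000) {
  v <- tibble::tibble(
    pen_id = pen_id, animal_id = animal_id, breed = breed,
    t_start = ts_utc(t_start), duration_s = duration_s,
    intake_g = intake_g, weight_g = weight_g
  )
  v$t_end <- v$t_start + v$duration_s
  v
}

make_roster <- function(animal_id, pen_id = "P1", breed = "B1",
                        status = "alive", sex = "F",
                        ham_weight_g = NA_real_, loin_weight_g = NA_real_,
                        back_fat_g = NA_real_, half_carcass_weight_g = NA_real_) {
  tibble::tibble(animal_id = animal_id, pen_id = pen_id, breed = breed,
                 sex = sex, status = status,
                 ham_weight_g = ham_weight_g, loin_weight_g = loin_weight_g,
                 back_fat_g = back_fat_g,
                 half_carcass_weight_g = half_carcass_weight_g)
}

# pre-cleaned visits (already carry day_index) for tests that start mid-pipeline
make_clean_visits <- function(...) {
  v <- make_visits(...)
  v$date <- as.Date(v$t_start, tz = "UTC")
  v <- dplyr::group_by(v, pen_id)
  v <- dplyr::mutate(v, day_index = as.integer(date - min(date)))
  dplyr::ungroup(v)
}

# simulations are expensive; build each once per test run
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# small cohort for module-level checks
small_cohort <- function() {
  cached("small", {
    sim <- simulate_pens(sim_config(n_pens = 3, n_days = 30), seed = 42)
    cl <- clean_visits(sim$visits, sim$roster)
    criteria <- criteria_for_cohort(cl$visits)
    meals <- build_meals(cl$visits, criteria)
    agg <- aggregate_daily(meals)
    list(sim = sim, visits = cl$visits, criteria = criteria, meals = meals,
         daily = agg$daily, summary = agg$summary)
  })
}

# full-size cohort matching the study conditions (>= 200 animals, 60 days)
study_cohort <- function() {
  cached("study", {
    cfg <- sim_config(n_pens = 15, n_days = 60)
    sim <- simulate_pens(cfg, seed = 1)
    cl <- clean_visits(sim$visits, sim$roster)
    criteria <- criteria_for_cohort(cl$visits)
    meals <- build_meals(cl$visits, criteria)
    filt <- filter_meal_outliers(meals, seed = 1)
    agg <- aggregate_daily(filt$meals)
    hourly <- aggregate_hourly(filt$meals, agg$summary)
    list(cfg = cfg, sim = sim, visits = cl$visits, criteria = criteria,
         meals = meals, meals_kept = filt$meals, daily = agg$daily,
         summary = agg$summary, hourly = hourly)
  })
}

# independent exhaustive MCD oracle: examine every h-subset with combn
mcd_exhaustive_oracle <- function(X, alpha = 0.75) {
  X <- as.matrix(X)
  n <- nrow(X)
  h <- ceiling(alpha * n)
  best_det <- Inf
  best <- NULL
  combos <- utils::combn(n, h)
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    d <- det(stats::cov(X[idx, , drop = FALSE]))
    if (is.finite(d) && d < best_det) {
      best_det <- d
      best <- idx
    }
  }
  list(det = best_det, subset = best,
       mu = colMeans(X[best, , drop = FALSE]), S = stats::cov(X[best, , drop = FALSE]))
}
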