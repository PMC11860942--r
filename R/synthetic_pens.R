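#' Simulator configuration
#'
#' Builds (and validates) the parameter list for the synthetic pen
#' simulator. The defaults emulate the statistical structure of group-housed
#' growing-finishing pigs on single-feeder pens over a ~100-day fattening
#' period: bimodal circadian feeding intensity peaking in hour bins 9 and 17,
#' a meal-count trajectory rising to ~8.8 meals/day around day 14 and easing
#' to ~6.3 by day 85, daily intake growing ~1000 to ~3000 g/day while the
#' ingestion rate climbs 0.35 to 0.8 g/s, near-linear growth at ~950 g/day
#' from ~23 kg, and dominance-linked feeder access (queue priority, preferred
#' feeding windows, meal-frequency shift).
#'
#' Inter-visit gaps have two timescales. Within meals, gaps are mostly
#' seconds (exponential, mean 45 s) with a lognormal minutes-scale
#' "interruption" tail (contention pauses), both truncated at 20 min.
#' Between meals, gaps are a 5-min-shifted lognormal whose scale follows the
#' circadian intensity and the day's meal-count target; its `between_sdlog`
#' is calibrated (see [theoretical_hazard()]) so the combined gap hazard has
#' its minimum in the 9-10 min bin.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_pens = 2L,
    animals_per_pen = 14L,
    n_days = 100L,
    start_date = "2018-03-01",
    breeds = c("B1", "B2", "B3"),
    # circadian intensity: two wrapped-normal modes over a uniform floor
    circadian_modes = c(9.4, 17.4),   # clock hours, inside hour bins 9 and 17
    circadian_sd = 2.5,               # hours
    circadian_floor = 0.4,            # weight of the uniform component
    # meal-count trajectory (meals/day)
    tnm_day0 = 7.0, tnm_peak = 8.8, tnm_peak_day = 14,
    tnm_late = 6.3, tnm_late_day = 85,
    # visits per meal: NVM = 1 + Poisson(nvm_extra_mean)
    nvm_extra_mean = 0.35,
    # within-meal gap law (minutes)
    within_gap_mean_min = 0.75,
    within_int_prob = 0.45,
    within_int_median_min = 3,
    within_int_sdlog = 0.5,
    within_gap_max_min = 20,
    # between-meal gap law (minutes)
    between_shift_min = 5,
    between_sdlog = 1.0,
    between_cap_min = 1200,
    # intake and rate trajectories
    fi_day0_g = 1000, fi_day100_g = 3000,
    fim_sdlog = 0.25,
    rate_day0 = 0.35, rate_plateau = 0.8, rate_plateau_day = 88,
    rate_meal_sdlog = 0.10,
    # growth and the intake-gain coupling
    adg_mean_gd = 950, adg_sd_gd = 90,
    bws_mean_g = 23000, bws_sd_g = 2000,
    weight_noise_sd_g = 500,
    fi_adg_beta = 0.8, fi_animal_sd = 0.075, rate_animal_sd = 0.05,
    # carcass composition
    half_carcass_mean_g = 47000, half_carcass_sd_g = 3000,
    ham_pct_mean = 24, ham_pct_sd = 1.5,
    loin_pct_mean = 26, loin_pct_sd = 2,
    fat_pct_mean = 13, fat_pct_sd = 2,
    # dominance effect sizes
    dom_tnm = 0.10, dom_pref = 0.15, dom_rate = 0.08, dom_queue = TRUE,
    # occupancy queue
    max_wait_min = 30
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    pf_abort(paste0("unknown sim_config field(s): ", paste(unknown, collapse = ", ")),
             class = "penfeedr_config_error")
  }
  cfg[names(dots)] <- dots
  pf_assert(cfg$circadian_floor >= 0 && cfg$circadian_floor < 1,
            "circadian_floor must be in [0, 1)")
  pf_assert(all(c(cfg$tnm_day0, cfg$tnm_peak, cfg$tnm_late, cfg$fi_day0_g,
                  cfg$rate_day0, cfg$within_gap_mean_min, cfg$between_shift_min) > 0),
            "rates and means must be positive")
  pf_assert(cfg$nvm_extra_mean >= 0, "nvm_extra_mean must be non-negative")
  class(cfg) <- c("sim_config", "list")
  cfg
}

# ---- deterministic trajectories -------------------------------------------

tnm_traj <- function(day, cfg) {
  ifelse(day <= cfg$tnm_peak_day,
         cfg$tnm_day0 + (cfg$tnm_peak - cfg$tnm_day0) * day / cfg$tnm_peak_day,
         ifelse(day <= cfg$tnm_late_day,
                cfg$tnm_peak + (cfg$tnm_late - cfg$tnm_peak) *
                  (day - cfg$tnm_peak_day) / (cfg$tnm_late_day - cfg$tnm_peak_day),
                cfg$tnm_late))
}

fi_traj <- function(day, cfg) {
  cfg$fi_day0_g + (cfg$fi_day100_g - cfg$fi_day0_g) * day / 100
}

rate_traj <- function(day, cfg) {
  pmin(cfg$rate_plateau,
       cfg$rate_day0 + (cfg$rate_plateau - cfg$rate_day0) * day / cfg$rate_plateau_day)
}

# bimodal circadian profile, normalised to mean 1 over the clock; wrapped
circadian_relative <- function(h, cfg, floor = cfg$circadian_floor) {
  bim <- function(x) {
    v <- 0
    for (m in cfg$circadian_modes) {
      for (k in -1:1) v <- v + stats::dnorm(x, m + 24 * k, cfg$circadian_sd)
    }
    v / length(cfg$circadian_modes)
  }
  grid <- seq(0, 24, by = 0.05)
  z <- mean(bim(grid))                  # so that bim/z has clock mean 1
  floor + (1 - floor) * bim(h %% 24) / z
}

# E[min(LN(meanlog = log(m), sdlog = s), cap)]
lnorm_capped_mean <- function(m, s, cap) {
  z <- log(cap / m) / s
  m * exp(s^2 / 2) * pnorm(z - s) + cap * (1 - pnorm(z))
}

mean_within_gap_min <- function(cfg) {
  (1 - cfg$within_int_prob) * cfg$within_gap_mean_min +
    cfg$within_int_prob *
      lnorm_capped_mean(cfg$within_int_median_min, cfg$within_int_sdlog,
                        cfg$within_gap_max_min)
}

# expected meal span (min) on a given day for an animal with multipliers
expected_tm_min <- function(day, cfg, fi_mult = 1, rate_mult = 1, tnm_mult = 1) {
  m_day <- tnm_traj(day, cfg) * tnm_mult
  fim <- fi_traj(day, cfg) * fi_mult / m_day
  otm_min <- fim / (rate_traj(day, cfg) * rate_mult) / 60
  otm_min + cfg$nvm_extra_mean * mean_within_gap_min(cfg)
}

# solve the between-gap lognormal scale from a target mean idle gap (min)
base_m_solver <- function(cfg) {
  grid_m <- exp(seq(log(1), log(5000), length.out = 400))
  grid_e <- lnorm_capped_mean(grid_m, cfg$between_sdlog, cfg$between_cap_min)
  function(target) {
    pf_assert(all(target > 0), "infeasible meal-count target (non-positive idle time)")
    stats::approx(grid_e, grid_m, xout = target, rule = 2)$y
  }
}

# target mean between-meal gap so that meals/day matches the trajectory
between_base_m <- function(day, cfg, fi_mult = 1, rate_mult = 1, tnm_mult = 1,
                           solver = base_m_solver(cfg)) {
  m_day <- tnm_traj(day, cfg) * tnm_mult
  idle <- 1440 / m_day - expected_tm_min(day, cfg, fi_mult, rate_mult, tnm_mult) -
    cfg$between_shift_min
  solver(idle)
}

# ---- theoretical gap hazard oracle ----------------------------------------

# binned discrete hazard of a gap mixture; laws given as CDF closures
hazard_from_cdf <- function(cdf, t_max = 60) {
  t <- 0:t_max
  Ft <- cdf(t)
  hz <- (Ft[-1] - Ft[-length(Ft)]) / (1 - Ft[-length(Ft)])
  tibble::tibble(t = t[-length(t)], hazard = hz)
}

#' Theoretical inter-visit gap hazard of a simulator configuration
#'
#' Numerically evaluates the per-minute discrete hazard of the inter-visit
#' gap mixture a configuration implies: within-meal gaps (exponential bulk
#' plus lognormal interruption tail, truncated) and between-meal gaps
#' (shifted lognormal whose scale is mixed over clock hours, weighted by the
#' circadian intensity, and over days, weighted by expected meal counts).
#' Component weights are the expected gap counts per meal
#' (`E[NVM] - 1` within-meal gaps vs one between-meal gap).
#'
#' This is the independent oracle against which the empirical Pstart
#' criterion estimates are checked: its argmin bin is the generator's true
#' meal-criterion trough.
#'
#' @param config A [sim_config()].
#' @param t_max Window in minutes (default 60).
#' @param hour_step,day_step Mixture grids (defaults 0.25 h, every 2nd day).
#' @return List with `curve` (tibble `t`, `hazard`), `argmin` (left edge of
#'   the minimum-hazard bin, minutes) and `p_within`.
#' @export
theoretical_hazard <- function(config, t_max = 60, hour_step = 0.25, day_step = 2) {
  cfg <- config
  p_w <- cfg$nvm_extra_mean / (1 + cfg$nvm_extra_mean)
  days <- seq(0, cfg$n_days - 1, by = day_step)
  hours <- seq(0, 24 - hour_step, by = hour_step)
  r_h <- circadian_relative(hours, cfg)
  w_h <- r_h / sum(r_h)                       # occurrence-weighted clock mixture
  w_d <- tnm_traj(days, cfg); w_d <- w_d / sum(w_d)
  solver <- base_m_solver(cfg)
  base_m <- between_base_m(days, cfg, solver = solver)

  cdf_within <- function(t) {
    # truncation by censoring at the cap: all mass at or below the cap
    bulk <- stats::pexp(pmin(t, cfg$within_gap_max_min), rate = 1 / cfg$within_gap_mean_min)
    bulk[t >= cfg$within_gap_max_min] <- 1
    tail_ <- stats::plnorm(pmin(t, cfg$within_gap_max_min),
                           log(cfg$within_int_median_min), cfg$within_int_sdlog)
    tail_[t >= cfg$within_gap_max_min] <- 1
    (1 - cfg$within_int_prob) * bulk + cfg$within_int_prob * tail_
  }
  cdf_between <- function(t) {
    x <- pmax(t - cfg$between_shift_min, 0)
    out <- numeric(length(t))
    for (di in seq_along(days)) {
      scale_dh <- base_m[di] / r_h
      for (hi in seq_along(hours)) {
        out <- out + w_d[di] * w_h[hi] *
          stats::plnorm(x, log(scale_dh[hi]), cfg$between_sdlog)
      }
    }
    out
  }
  cdf <- function(t) p_w * cdf_within(t) + (1 - p_w) * cdf_between(t)
  curve <- hazard_from_cdf(cdf, t_max)
  # locate the trough the same way the criterion scan does: the bin holding
  # the local minimum at the first negative-to-positive turn of the hazard
  scan <- curve
  scan$smoothed <- scan$hazard
  fc <- find_criterion(scan)
  list(curve = curve, argmin = fc$criterion, p_within = p_w)
}

# ---- the simulator ---------------------------------------------------------

draw_within_gaps_min <- function(n, cfg) {
  if (n == 0) return(numeric(0))
  tail_ <- runif(n) < cfg$within_int_prob
  g <- numeric(n)
  g[!tail_] <- rexp(sum(!tail_), rate = 1 / cfg$within_gap_mean_min)
  g[tail_] <- rlnorm(sum(tail_), log(cfg$within_int_median_min), cfg$within_int_sdlog)
  pmin(g, cfg$within_gap_max_min)
}

simulate_pen <- function(cfg, pen_index, seed) {
  set.seed(seed)
  A <- cfg$animals_per_pen
  pen_id <- sprintf("P%02d", pen_index)
  breed <- cfg$breeds[(pen_index - 1) %% length(cfg$breeds) + 1]
  animal_id <- sprintf("%sA%02d", pen_id, seq_len(A))

  dom <- rnorm(A)
  adg <- rnorm(A, cfg$adg_mean_gd, cfg$adg_sd_gd)
  bws <- rnorm(A, cfg$bws_mean_g, cfg$bws_sd_g)
  fi_mult <- pmax(0.5, 1 + cfg$fi_adg_beta * (adg - cfg$adg_mean_gd) / cfg$adg_mean_gd +
                    rnorm(A, 0, cfg$fi_animal_sd))
  rate_mult <- pmax(0.5, 1 - cfg$dom_rate * dom + rnorm(A, 0, cfg$rate_animal_sd))
  tnm_mult <- pmax(0.5, 1 + cfg$dom_tnm * dom)
  floor_i <- pmin(0.9, pmax(0.05, cfg$circadian_floor * (1 - cfg$dom_pref * dom)))

  # per-animal-per-day between-gap lognormal scales
  days <- 0:(cfg$n_days - 1)
  solver <- base_m_solver(cfg)
  base_m <- matrix(0, nrow = cfg$n_days, ncol = A)
  for (a in seq_len(A)) {
    base_m[, a] <- between_base_m(days, cfg, fi_mult[a], rate_mult[a], tnm_mult[a],
                                  solver = solver)
  }

  # circadian warp per animal: meal starts follow an inhomogeneous renewal
  # process via time-rescaling, so the between-meal gap keeps its lognormal
  # law on the operational clock (local scale base_m / r(h)) while meals
  # concentrate where the intensity is high, without lag
  h_grid <- seq(0, 24, by = 0.05)
  bim_grid <- circadian_relative(h_grid, cfg, floor = 0)   # pure bimodal, mean 1
  r_grid <- lapply(seq_len(A), function(a) floor_i[a] + (1 - floor_i[a]) * bim_grid)
  # cumulative intensity over one day (hours of operational time)
  rcum_grid <- lapply(r_grid, function(r) c(0, cumsum((r[-1] + r[-length(r)]) / 2 * 0.05)))
  warp <- function(a, h) {            # clock hour -> operational hours
    stats::approx(h_grid, rcum_grid[[a]], xout = h, rule = 2)$y
  }
  unwarp <- function(a, v) {          # operational hours -> clock hour
    stats::approx(rcum_grid[[a]], h_grid, xout = v, rule = 2)$y
  }
  day_op <- vapply(rcum_grid, function(rc) rc[length(rc)], numeric(1)) # = 24
  draw_between_gap_s <- function(a, t_s) {
    day <- min(floor(t_s / 86400), cfg$n_days - 1) + 1
    L_min <- min(rlnorm(1, log(base_m[day, a]), cfg$between_sdlog), cfg$between_cap_min)
    t_ref <- t_s + cfg$between_shift_min * 60       # refractory period, real time
    d0 <- floor(t_ref / 86400)
    h0 <- (t_ref - d0 * 86400) / 3600
    v_target <- warp(a, h0) + L_min / 60            # operational hours
    d_extra <- floor(v_target / day_op[a])
    h1 <- unwarp(a, v_target - d_extra * day_op[a])
    t_land <- (d0 + d_extra) * 86400 + h1 * 3600
    round(t_land) - t_s
  }

  horizon_s <- cfg$n_days * 86400
  next_req <- vapply(seq_len(A), function(a) draw_between_gap_s(a, 0), numeric(1))
  feeder_free <- 0
  n_dropped <- 0L

  cap_guess <- as.integer(cfg$n_days * max(10, 2 * cfg$tnm_peak) * (1 + cfg$nvm_extra_mean) * A)
  va <- integer(cap_guess); vs <- numeric(cap_guess); vd <- numeric(cap_guess)
  vi <- numeric(cap_guess); vw <- numeric(cap_guess)
  nv <- 0L

  repeat {
    r_min <- min(next_req)
    if (r_min >= horizon_s) break
    t_serve <- max(r_min, feeder_free)
    waiting <- which(next_req <= t_serve)
    overdue <- waiting[t_serve - next_req[waiting] > cfg$max_wait_min * 60]
    if (length(overdue) > 0) {
      # give up and come back later: the planned meal is skipped
      for (a in overdue) {
        n_dropped <- n_dropped + 1L
        give_up <- next_req[a] + cfg$max_wait_min * 60
        next_req[a] <- give_up + draw_between_gap_s(a, give_up)
      }
      next
    }
    a <- if (isTRUE(cfg$dom_queue)) {
      waiting[which.max(dom[waiting])]         # contested access: dominant first
    } else {
      waiting[which.min(next_req[waiting])]    # first come, first served
    }
    day <- min(floor(t_serve / 86400), cfg$n_days - 1)
    m_day <- tnm_traj(day, cfg) * tnm_mult[a]
    nvm <- 1L + rpois(1, cfg$nvm_extra_mean)
    fim <- fi_traj(day, cfg) * fi_mult[a] / m_day *
      rlnorm(1, -cfg$fim_sdlog^2 / 2, cfg$fim_sdlog)
    rate <- rate_traj(day, cfg) * rate_mult[a] *
      rlnorm(1, -cfg$rate_meal_sdlog^2 / 2, cfg$rate_meal_sdlog)
    otm_s <- fim / rate
    props <- rexp(nvm); props <- props / sum(props)
    dur <- pmax(1, round(otm_s * props))
    intake <- round(fim * dur / sum(dur), 1)
    gaps_s <- pmax(1, round(draw_within_gaps_min(nvm - 1L, cfg) * 60))
    starts <- t_serve + cumsum(c(0, dur[-nvm] + gaps_s))
    ends <- starts + dur
    for (k in seq_len(nvm)) {
      nv <- nv + 1L
      va[nv] <- a; vs[nv] <- starts[k]; vd[nv] <- dur[k]; vi[nv] <- intake[k]
      vw[nv] <- max(1000, round(bws[a] + adg[a] * starts[k] / 86400 +
                                  rnorm(1, 0, cfg$weight_noise_sd_g)))
    }
    feeder_free <- ends[nvm]
    next_req[a] <- feeder_free + draw_between_gap_s(a, feeder_free)
  }

  idx <- seq_len(nv)
  origin <- as.POSIXct(paste0(cfg$start_date, " 00:00:00"), tz = "UTC")
  visits <- tibble::tibble(
    pen_id = pen_id,
    animal_id = animal_id[va[idx]],
    breed = breed,
    t_start = origin + vs[idx],
    duration_s = vd[idx],
    intake_g = vi[idx],
    weight_g = vw[idx]
  )
  visits$t_end <- visits$t_start + visits$duration_s

  roster <- tibble::tibble(
    animal_id = animal_id, pen_id = pen_id, breed = breed,
    sex = if (breed[1] == cfg$breeds[1]) "M" else "F",
    status = "alive",
    half_carcass_weight_g = round(rnorm(A, cfg$half_carcass_mean_g, cfg$half_carcass_sd_g)),
    ham_weight_g = NA_real_, loin_weight_g = NA_real_, back_fat_g = NA_real_
  )
  roster$ham_weight_g <- round(rnorm(A, cfg$ham_pct_mean, cfg$ham_pct_sd) / 100 *
                                 roster$half_carcass_weight_g)
  roster$loin_weight_g <- round(rnorm(A, cfg$loin_pct_mean, cfg$loin_pct_sd) / 100 *
                                  roster$half_carcass_weight_g)
  roster$back_fat_g <- round(rnorm(A, cfg$fat_pct_mean, cfg$fat_pct_sd) / 100 *
                               roster$half_carcass_weight_g)
  roster <- roster[, c("animal_id", "pen_id", "breed", "sex", "status",
                       "ham_weight_g", "loin_weight_g", "back_fat_g",
                       "half_carcass_weight_g")]

  truth <- tibble::tibble(
    animal_id = animal_id, pen_id = pen_id, breed = breed,
    dominance = dom, adg_gd = adg, bws_g = bws,
    fi_mult = fi_mult, rate_mult = rate_mult, tnm_mult = tnm_mult,
    circadian_floor = floor_i
  )
  list(visits = visits, roster = roster, truth = truth, n_dropped = n_dropped)
}

#' Simulate feeder-visit logs for a cohort of pens
#'
#' Generates, pen by pen, per-animal meal schedules from the configured
#' circadian intensity and gap laws, realises each meal as visits with
#' durations, intakes and scale weights, and resolves single-feeder occupancy
#' with a queue: a meal due while the feeder is busy waits until it is free
#' (ties go to the more dominant animal; waits beyond `max_wait_min` drop the
#' meal). Per-pen random substreams are derived from the root seed, so each
#' pen is reproducible in isolation and runs are byte-identical given
#' (config, seed).
#'
#' @param config A [sim_config()].
#' @param seed Integer root seed.
#' @return A list with `visits` (tibble in the raw-log layout of
#'   [read_visits()]), `roster`, `truth` (per-animal latent values plus the
#'   theoretical hazard trough `criterion_trough_min` and per-pen dropped-meal
#'   counts) and `config`.
#' @export
simulate_pens <- function(config = sim_config(), seed = 1) {
  cfg <- config
  # stocking feasibility: expected occupation must stay below 95% of the day
  occ <- vapply(0:(cfg$n_days - 1), function(d) {
    cfg$animals_per_pen * tnm_traj(d, cfg) * expected_tm_min(d, cfg)
  }, numeric(1))
  if (max(occ) > 0.95 * 1440) {
    pf_abort(sprintf(
      "infeasible config: expected feeder occupation %.0f%% of the day exceeds 95%%",
      100 * max(occ) / 1440), class = "penfeedr_config_error")
  }
  pens <- lapply(seq_len(cfg$n_pens), function(p) {
    simulate_pen(cfg, p, child_seed(seed, p))
  })
  hz <- theoretical_hazard(cfg)
  list(
    visits = dplyr::bind_rows(lapply(pens, `[[`, "visits")),
    roster = dplyr::bind_rows(lapply(pens, `[[`, "roster")),
    truth = list(
      animals = dplyr::bind_rows(lapply(pens, `[[`, "truth")),
      criterion_trough_min = hz$argmin,
      n_dropped_meals = vapply(pens, `[[`, integer(1), "n_dropped")
    ),
    config = cfg
  )
}
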