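#' Merge visits into meals
#'
#' Consecutive visits of an animal whose feeder-free gap (end of one visit to
#' start of the next) is strictly below the animal's meal criterion belong to
#' the same meal. A gap equal to or above the criterion starts a new meal.
#'
#' Per-meal traits:
#' * `NVM` number of visits in the meal
#' * `OTM` occupation time (sum of visit durations, s)
#' * `TM`  time to complete the meal (first start to last end, s)
#' * `FIM` intake in the meal (g)
#' * `FR`  feeding rate `FIM / OTM` (g/s)
#' * `FRM` meal-level rate `FIM / TM` (g/s)
#' * `IBM` interval between meals: start-to-start difference from the
#'   animal's previous meal (s); `NA` for its first meal.
#'
#' Zero-duration meals have no defined feeding rate; they are flagged
#' `valid = FALSE` and should be excluded from trait tables (counted in the
#' `n_invalid` attribute).
#'
#' @param visits Cleaned visit tibble (must carry `day_index`).
#' @param criteria Criterion tibble from [criteria_for_cohort()] (or any
#'   tibble with `animal_id`, `criterion_min`).
#' @return A tibble of meals with identifiers (`animal_id`, `pen_id`,
#'   `breed`), `meal_id`, `day_index`, `hour`, timestamps, the traits above
#'   and a `valid` flag.
#' @export
build_meals <- function(visits, criteria) {
  pf_assert("day_index" %in% names(visits),
            "visits must be cleaned (day_index missing); run clean_visits() first")
  unresolved <- setdiff(unique(visits$animal_id), criteria$animal_id)
  if (length(unresolved) > 0) {
    pf_abort(paste0("no meal criterion resolvable for animal(s): ",
                    paste(head(unresolved, 5), collapse = ", ")))
  }
  v <- dplyr::left_join(visits, criteria[, c("animal_id", "criterion_min")],
                        by = "animal_id")
  v <- dplyr::arrange(v, .data$animal_id, .data$t_start)
  v <- dplyr::mutate(
    dplyr::group_by(v, .data$animal_id),
    gap_prev = mins_between(dplyr::lag(.data$t_end), .data$t_start),
    new_meal = is.na(.data$gap_prev) | .data$gap_prev >= .data$criterion_min,
    meal_id = cumsum(.data$new_meal)
  )
  meals <- dplyr::summarise(
    dplyr::group_by(v, .data$animal_id, .data$meal_id),
    pen_id = dplyr::first(.data$pen_id),
    breed = dplyr::first(.data$breed),
    t_start = min(.data$t_start),
    t_end = max(.data$t_end),
    day_index = dplyr::first(.data$day_index),
    NVM = dplyr::n(),
    OTM = sum(.data$duration_s),
    FIM = sum(.data$intake_g),
    .groups = "drop_last"
  )
  meals <- dplyr::mutate(
    meals,
    TM = secs_between(.data$t_start, .data$t_end),
    FR = ifelse(.data$OTM > 0, .data$FIM / .data$OTM, NA_real_),
    FRM = ifelse(.data$TM > 0, .data$FIM / .data$TM, NA_real_),
    IBM = secs_between(dplyr::lag(.data$t_start), .data$t_start),
    hour = clock_hour(.data$t_start),
    valid = .data$OTM > 0
  )
  meals <- dplyr::ungroup(meals)
  meals <- dplyr::select(
    meals, "animal_id", "pen_id", "breed", "meal_id", "day_index", "hour",
    "t_start", "t_end", "NVM", "OTM", "TM", "FIM", "FR", "FRM", "IBM", "valid")
  attr(meals, "n_invalid") <- sum(!meals$valid)
  meals
}

#' Daily feeding-behaviour traits and observation summary
#'
#' Additive traits are summed per animal and day; ratio traits are recomputed
#' from the summed numerator and denominator (never averaged across meals).
#' A meal belongs to the day its first visit starts. Days on which an animal
#' has no meals are absent, not zero-filled.
#'
#' @param meals Meal tibble from [build_meals()] (invalid meals are dropped).
#' @return A list with `daily` (per animal-day: `TNM`, `TNV`, `OT_day`,
#'   `TM_day`, `FI_day`, `FR_day`, `FRM_day`, `mean_FIM`, `mean_IBM`) and
#'   `summary` (per animal: `ND` days observed, `TFI` total intake in grams,
#'   `ADFI = TFI / ND` in g/day).
#' @export
aggregate_daily <- function(meals) {
  meals <- meals[meals$valid, , drop = FALSE]
  daily <- dplyr::summarise(
    dplyr::group_by(meals, .data$animal_id, .data$pen_id, .data$breed, .data$day_index),
    TNM = dplyr::n(),
    TNV = sum(.data$NVM),
    OT_day = sum(.data$OTM),
    TM_day = sum(.data$TM),
    FI_day = sum(.data$FIM),
    mean_FIM = mean(.data$FIM),
    mean_IBM = if (all(is.na(.data$IBM))) NA_real_ else mean(.data$IBM, na.rm = TRUE),
    .groups = "drop"
  )
  daily <- dplyr::mutate(
    daily,
    FR_day = ifelse(.data$OT_day > 0, .data$FI_day / .data$OT_day, NA_real_),
    FRM_day = ifelse(.data$TM_day > 0, .data$FI_day / .data$TM_day, NA_real_)
  )
  summary <- dplyr::summarise(
    dplyr::group_by(daily, .data$animal_id, .data$pen_id, .data$breed),
    ND = dplyr::n_distinct(.data$day_index),
    TFI = sum(.data$FI_day),
    .groups = "drop"
  )
  summary$ADFI <- summary$TFI / summary$ND
  list(daily = daily, summary = summary)
}

#' Hourly feeding-behaviour traits
#'
#' Traits are summed within each clock hour per animal and divided by the
#' animal's number of observed days, so each value is a per-day average for
#' that hour of day. Hours with no meals are zero-filled. Hourly rates are
#' ratios of the hourly sums.
#'
#' @param meals Meal tibble from [build_meals()].
#' @param summary Observation summary from [aggregate_daily()] (for `ND`).
#' @return Tibble with one row per animal and hour 0..23: `TNM`, `TNV`,
#'   `OTM`, `TM`, `FIM` (per-day averages) and hourly `FR`, `FRM`.
#' @export
aggregate_hourly <- function(meals, summary) {
  meals <- meals[meals$valid, , drop = FALSE]
  hourly <- dplyr::summarise(
    dplyr::group_by(meals, .data$animal_id, .data$hour),
    n_meals = dplyr::n(),
    n_visits = sum(.data$NVM),
    ot = sum(.data$OTM),
    tm = sum(.data$TM),
    fi = sum(.data$FIM),
    .groups = "drop"
  )
  grid <- tidyr::expand_grid(animal_id = summary$animal_id, hour = 0:23)
  hourly <- dplyr::left_join(grid, hourly, by = c("animal_id", "hour"))
  hourly <- dplyr::mutate(hourly, dplyr::across(c("n_meals", "n_visits", "ot", "tm", "fi"),
                                                ~ tidyr::replace_na(.x, 0)))
  hourly <- dplyr::left_join(hourly, summary[, c("animal_id", "ND")], by = "animal_id")
  dplyr::transmute(
    hourly,
    animal_id = .data$animal_id,
    hour = .data$hour,
    TNM = .data$n_meals / .data$ND,
    TNV = .data$n_visits / .data$ND,
    OTM = .data$ot / .data$ND,
    TM = .data$tm / .data$ND,
    FIM = .data$fi / .data$ND,
    FR = ifelse(.data$ot > 0, .data$fi / .data$ot, NA_real_),
    FRM = ifelse(.data$tm > 0, .data$fi / .data$tm, NA_real_)
  )
}
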