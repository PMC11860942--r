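#' Segment a pen's visits into feeding events
#'
#' A pen-level feeding event is a maximal run of visits (any animal) in which
#' each consecutive start-to-start gap is at most `threshold` minutes.
#' Feeding events are the unit over which the feeder-entry order (Position)
#' is standardised.
#'
#' @param visits Cleaned visits of one or more pens.
#' @param threshold Gap threshold in minutes. Scalar, or a named numeric
#'   vector keyed by `pen_id` (the wrapper [social_rank_traits()] uses each
#'   pen's median meal criterion).
#' @return The visits with added `event_id` (per pen), `event_order` (k, the
#'   entry order within the event) and `event_size` (n).
#' @export
build_pen_events <- function(visits, threshold) {
  visits <- dplyr::arrange(visits, .data$pen_id, .data$t_start)
  thr <- function(pen) {
    if (length(threshold) == 1 && is.null(names(threshold))) return(as.numeric(threshold))
    pf_assert(pen %in% names(threshold), paste0("no event threshold for pen ", pen))
    as.numeric(threshold[[pen]])
  }
  visits <- dplyr::mutate(
    dplyr::group_by(visits, .data$pen_id),
    .gap = mins_between(dplyr::lag(.data$t_start), .data$t_start),
    event_id = cumsum(is.na(.data$.gap) | .data$.gap > thr(dplyr::cur_group()$pen_id))
  )
  visits <- dplyr::mutate(
    dplyr::group_by(visits, .data$pen_id, .data$event_id),
    event_order = dplyr::row_number(),
    event_size = dplyr::n()
  )
  dplyr::select(dplyr::ungroup(visits), -".gap")
}

#' Feeder-entry Position
#'
#' Within an event of n visits, the k-th visit has standardised order k/n.
#' An animal's value for an event is the mean standardised order of its
#' visits in that event; its Position is the mean of those per-event values
#' over all events it appears in. Low Position means the animal tends to
#' reach the feeder early — a priority-of-access proxy.
#'
#' @param events Visits with event columns from [build_pen_events()].
#' @return Tibble `animal_id`, `Position` (in (0, 1]).
#' @export
compute_position <- function(events) {
  per_event <- dplyr::summarise(
    dplyr::group_by(events, .data$pen_id, .data$event_id, .data$animal_id),
    value = mean(.data$event_order / .data$event_size),
    .groups = "drop"
  )
  dplyr::summarise(dplyr::group_by(per_event, .data$animal_id),
                   Position = mean(.data$value), .groups = "drop")
}

#' Preferred-time visit ratios
#'
#' Share of an animal's visits starting inside a union of half-open clock
#' windows `[start, end)` (hours). Window presets follow the two printed
#' definitions of the narrow preferred window:
#' * `window_b = "methods"`: 08:00–10:00 and 15:00–17:00
#' * `window_b = "table1"`: 07:00–11:00 and 14:00–18:00
#'
#' @param visits Cleaned visit tibble.
#' @param window_a List of `c(start, end)` hour pairs; default `[8, 20)`.
#' @param window_b List of hour pairs, or one of the preset names above.
#' @return Tibble `animal_id`, `ratePrefTime_a`, `ratePrefTime_b`.
#' @export
compute_pref_time <- function(visits,
                              window_a = list(c(8, 20)),
                              window_b = "methods") {
  if (is.character(window_b)) {
    window_b <- switch(window_b,
      methods = list(c(8, 10), c(15, 17)),
      table1 = list(c(7, 11), c(14, 18)),
      pf_abort("unknown window_b preset; use 'methods' or 'table1'")
    )
  }
  in_windows <- function(h, windows) {
    Reduce(`|`, lapply(windows, function(w) h >= w[1] & h < w[2]))
  }
  h <- clock_hour_frac(visits$t_start)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(animal_id = visits$animal_id,
                                   in_a = in_windows(h, window_a),
                                   in_b = in_windows(h, window_b)),
                    .data$animal_id),
    ratePrefTime_a = mean(.data$in_a),
    ratePrefTime_b = mean(.data$in_b),
    .groups = "drop"
  )
}

#' Daily pen-share rates
#'
#' For each pen and day, each animal's share of the pen total of visits
#' (`rateNV`), meals (`rateNM`), intake (`rateFI`) and occupation time
#' (`rateOT`); the trait is the mean share over the animal's observed days.
#' The denominator includes the focal animal, so shares sum to 1 over pen
#' members each day. Pen-days with a zero total for a trait are skipped for
#' that trait.
#'
#' @param daily Daily trait tibble from [aggregate_daily()].
#' @return Tibble `animal_id`, `rateNV`, `rateNM`, `rateFI`, `rateOT`.
#' @export
compute_daily_shares <- function(daily) {
  shares <- dplyr::mutate(
    dplyr::group_by(daily, .data$pen_id, .data$day_index),
    share_NV = if (sum(.data$TNV) > 0) .data$TNV / sum(.data$TNV) else NA_real_,
    share_NM = if (sum(.data$TNM) > 0) .data$TNM / sum(.data$TNM) else NA_real_,
    share_FI = if (sum(.data$FI_day) > 0) .data$FI_day / sum(.data$FI_day) else NA_real_,
    share_OT = if (sum(.data$OT_day) > 0) .data$OT_day / sum(.data$OT_day) else NA_real_
  )
  dplyr::summarise(
    dplyr::group_by(dplyr::ungroup(shares), .data$animal_id),
    rateNV = mean(.data$share_NV, na.rm = TRUE),
    rateNM = mean(.data$share_NM, na.rm = TRUE),
    rateFI = mean(.data$share_FI, na.rm = TRUE),
    rateOT = mean(.data$share_OT, na.rm = TRUE),
    .groups = "drop"
  )
}

#' All social-ranking traits
#'
#' Convenience wrapper: segments pen feeding events (threshold = the pen
#' members' median meal criterion unless given), computes Position,
#' preferred-time ratios and daily pen shares, and joins them per animal.
#'
#' @param visits Cleaned visit tibble.
#' @param daily Daily traits from [aggregate_daily()].
#' @param criteria Criterion tibble (used for the default event threshold).
#' @param event_threshold Optional scalar threshold in minutes overriding the
#'   pen-median criterion.
#' @param window_a,window_b Passed to [compute_pref_time()].
#' @return Tibble with one row per animal: `Position`, `ratePrefTime_a`,
#'   `ratePrefTime_b`, `rateNV`, `rateNM`, `rateFI`, `rateOT`.
#' @export
social_rank_traits <- function(visits, daily, criteria, event_threshold = NULL,
                               window_a = list(c(8, 20)), window_b = "methods") {
  if (is.null(event_threshold)) {
    members <- dplyr::distinct(visits, .data$pen_id, .data$animal_id)
    members <- dplyr::left_join(members, criteria[, c("animal_id", "criterion_min")],
                                by = "animal_id")
    med <- dplyr::summarise(dplyr::group_by(members, .data$pen_id),
                            thr = median(.data$criterion_min, na.rm = TRUE),
                            .groups = "drop")
    event_threshold <- setNames(med$thr, med$pen_id)
  }
  events <- build_pen_events(visits, event_threshold)
  out <- compute_position(events)
  out <- dplyr::full_join(out, compute_pref_time(visits, window_a, window_b),
                          by = "animal_id")
  dplyr::full_join(out, compute_daily_shares(daily), by = "animal_id")
}
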