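#' Read a raw feeder-visit log
#'
#' Parses a CSV export of electronic-feeder visit events. Each row is one
#' visit: which animal, in which pen, when it started, how long it stayed,
#' how much it ate, and the body weight registered by the feeder scale.
#'
#' Malformed rows (unparseable timestamp, non-numeric duration/intake/weight)
#' are not silently dropped: they are counted and kept in the attached parse
#' report, and removed from the returned table.
#'
#' @param path Path to the visit CSV.
#' @param dialect Optional named character vector mapping the canonical column
#'   names (`pen_id`, `animal_id`, `breed`, `t_start`, `duration_s`,
#'   `intake_g`, `weight_g`) to the names used in the file, e.g.
#'   `c(t_start = "visit_time")`. Unmapped columns keep the canonical name.
#' @return A tibble of visits with typed columns `pen_id`, `animal_id`,
#'   `breed` (character), `t_start`, `t_end` (POSIXct, UTC), `duration_s`,
#'   `intake_g`, `weight_g` (numeric), sorted by pen and start time, with a
#'   `parse_report` attribute (`n_rows`, `n_malformed`).
#' @export
read_visits <- function(path, dialect = NULL) {
  pf_assert(file.exists(path), paste0("visit file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  canonical <- c("pen_id", "animal_id", "breed", "t_start",
                 "duration_s", "intake_g", "weight_g")
  names_map <- setNames(canonical, canonical)
  if (!is.null(dialect)) names_map[names(dialect)] <- unname(dialect)
  missing_cols <- canonical[!names_map[canonical] %in% names(raw)]
  if (length(missing_cols) > 0) {
    pf_abort(paste0("visit file is missing required column(s): ",
                    paste(names_map[missing_cols], collapse = ", ")),
             class = "penfeedr_config_error")
  }
  out <- tibble::tibble(
    pen_id     = raw[[names_map["pen_id"]]],
    animal_id  = raw[[names_map["animal_id"]]],
    breed      = raw[[names_map["breed"]]],
    t_start    = suppressWarnings(lubridate::ymd_hms(raw[[names_map["t_start"]]], tz = "UTC")),
    duration_s = suppressWarnings(as.numeric(raw[[names_map["duration_s"]]])),
    intake_g   = suppressWarnings(as.numeric(raw[[names_map["intake_g"]]])),
    weight_g   = suppressWarnings(as.numeric(raw[[names_map["weight_g"]]]))
  )
  malformed <- is.na(out$t_start) | is.na(out$duration_s) | out$duration_s < 0 |
    (!is.na(out$intake_g) & out$intake_g < 0)
  out <- out[!malformed, , drop = FALSE]
  out$t_end <- out$t_start + out$duration_s
  out <- dplyr::arrange(out, .data$pen_id, .data$t_start)
  attr(out, "parse_report") <- list(n_rows = nrow(raw), n_malformed = sum(malformed))
  out
}

#' Read a pen/animal roster
#'
#' @param path Path to the roster CSV with columns `animal_id`, `pen_id`,
#'   `breed`, `sex`, `status` (one of alive/dead/culled) and optional carcass
#'   columns `ham_weight_g`, `loin_weight_g`, `back_fat_g`,
#'   `half_carcass_weight_g`.
#' @return A tibble, one row per animal.
#' @export
read_roster <- function(path) {
  pf_assert(file.exists(path), paste0("roster file not found: ", path))
  ros <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("animal_id", "pen_id", "breed", "sex", "status")
  missing_cols <- setdiff(required, names(ros))
  if (length(missing_cols) > 0) {
    pf_abort(paste0("roster is missing required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             class = "penfeedr_config_error")
  }
  pf_assert(!anyDuplicated(ros$animal_id), "roster animal_id values must be unique")
  for (col in c("ham_weight_g", "loin_weight_g", "back_fat_g", "half_carcass_weight_g")) {
    if (!col %in% names(ros)) ros[[col]] <- NA_real_
  }
  ros$animal_id <- as.character(ros$animal_id)
  ros$pen_id <- as.character(ros$pen_id)
  tibble::as_tibble(ros)
}

#' Clean a visit log against a roster
#'
#' Applies the record-exclusion rules, in order, with first-match attribution
#' so the report counts are unambiguous:
#'
#' 1. `dead_or_culled_pen`: all visits of any pen whose roster contains a
#'    dead or culled animal;
#' 2. `boundary_day`: for each remaining pen, all visits dated on that pen's
#'    first and last calendar day (recording starts and stops mid-day, so
#'    those days are incomplete);
#' 3. `missing_or_unknown_id`: rows with missing fields or an `animal_id`
#'    that does not resolve to the roster.
#'
#' Overlapping visits within a pen (impossible on a single feeder) are treated
#' as a device error: the later visit is truncated to start at the earlier
#' visit's end (intake is preserved) and a count is reported.
#'
#' The cleaned table gains `date` and a per-pen `day_index` (0 = first
#' retained day). Boundary-day trimming only applies to raw tables: a table
#' that already carries `day_index` has been cleaned before, so cleaning is
#' idempotent.
#'
#' @param visits Visit tibble from [read_visits()] (or the simulator).
#' @param roster Roster tibble from [read_roster()].
#' @return A list with `visits` (cleaned tibble) and `report` (a cleaning
#'   report: `n_input`, `n_removed_by_rule`, `n_overlap_truncated`,
#'   `n_output`).
#' @export
clean_visits <- function(visits, roster) {
  pf_assert(nrow(visits) > 0, "no visits to clean")
  n_input <- nrow(visits)
  removed <- c(dead_or_culled_pen = 0L, boundary_day = 0L, missing_or_unknown_id = 0L)
  already_indexed <- "day_index" %in% names(visits)

  # rule (a): pens containing dead or culled animals
  bad_pens <- unique(roster$pen_id[roster$status %in% c("dead", "culled")])
  is_bad_pen <- visits$pen_id %in% bad_pens
  removed["dead_or_culled_pen"] <- sum(is_bad_pen)
  visits <- visits[!is_bad_pen, , drop = FALSE]

  # rule (b): first and last calendar day per pen (raw tables only)
  if (nrow(visits) > 0) {
    visits$date <- as.Date(visits$t_start, tz = "UTC")
    if (!already_indexed) {
      bounds <- dplyr::summarise(dplyr::group_by(visits, .data$pen_id),
                                 first_day = min(.data$date),
                                 last_day = max(.data$date), .groups = "drop")
      visits <- dplyr::left_join(visits, bounds, by = "pen_id")
      is_boundary <- visits$date == visits$first_day | visits$date == visits$last_day
      removed["boundary_day"] <- sum(is_boundary)
      visits <- visits[!is_boundary, !(names(visits) %in% c("first_day", "last_day")),
                       drop = FALSE]
    }
  }

  # rule (c): missing values or animal ids absent from the roster
  if (nrow(visits) > 0) {
    core <- c("pen_id", "animal_id", "t_start", "duration_s", "intake_g", "weight_g")
    has_na <- rowSums(is.na(visits[, core, drop = FALSE])) > 0 |
      visits$animal_id == "" | !(visits$animal_id %in% roster$animal_id)
    removed["missing_or_unknown_id"] <- sum(has_na)
    visits <- visits[!has_na, , drop = FALSE]
  }

  if (nrow(visits) == 0) {
    pf_abort("all visits removed: table is empty after cleaning",
             class = "penfeedr_empty_error")
  }

  visits <- dplyr::arrange(visits, .data$pen_id, .data$t_start)

  # repair physically impossible overlaps within a pen
  n_truncated <- 0L
  visits <- dplyr::group_modify(dplyr::group_by(visits, .data$pen_id), function(df, key) {
    prev_end <- dplyr::lag(cummax(as.numeric(df$t_end)))
    overlap <- !is.na(prev_end) & as.numeric(df$t_start) < prev_end
    if (any(overlap)) {
      n_truncated <<- n_truncated + sum(overlap)
      new_start <- pmin(prev_end[overlap], as.numeric(df$t_end)[overlap])
      df$t_start[overlap] <- as.POSIXct(new_start, origin = "1970-01-01", tz = "UTC")
      df$duration_s[overlap] <- as.numeric(df$t_end[overlap]) - new_start
    }
    df
  })
  visits <- dplyr::ungroup(visits)

  # per-pen day indices from the first retained date
  visits <- dplyr::mutate(dplyr::group_by(visits, .data$pen_id),
                          day_index = as.integer(.data$date - min(.data$date)))
  visits <- dplyr::arrange(dplyr::ungroup(visits), .data$pen_id, .data$t_start)

  report <- list(n_input = n_input,
                 n_removed_by_rule = as.list(removed),
                 n_overlap_truncated = n_truncated,
                 n_output = nrow(visits))
  list(visits = visits, report = report)
}

#' Write a cleaning report as JSON
#'
#' @param report The `report` element returned by [clean_visits()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
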