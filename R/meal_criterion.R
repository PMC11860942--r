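#' Inter-visit gaps per animal
#'
#' For each animal, the gap from the end of one visit to the start of its
#' next visit, in minutes (feeder-free time). Gaps are the raw material of
#' the Pstart hazard from which the meal criterion is estimated.
#'
#' @param visits Cleaned visit tibble (see [clean_visits()]).
#' @return A tibble with one row per gap: `animal_id`, `breed`, `gap_min`.
#'   Animals with fewer than two visits contribute no rows.
#' @export
compute_gaps <- function(visits) {
  visits <- dplyr::arrange(visits, .data$animal_id, .data$t_start)
  gaps <- dplyr::mutate(
    dplyr::group_by(visits, .data$animal_id),
    gap_min = mins_between(dplyr::lag(.data$t_end), .data$t_start),
    breed = .data$breed
  )
  gaps <- dplyr::ungroup(gaps)
  gaps <- gaps[!is.na(gaps$gap_min), c("animal_id", "breed", "gap_min")]
  # clock precision can make a truncated back-to-back visit land microscopically early
  gaps$gap_min <- pmax(gaps$gap_min, 0)
  tibble::as_tibble(gaps)
}

#' Discrete hazard of starting a new visit (Pstart)
#'
#' Within each 1-minute bin `[t, t + 1)`, the observed probability of an
#' animal starting its next visit, given it has not yet done so:
#' `raw(t) = #(gaps in [t, t+1)) / #(gaps >= t)`. Gaps at or beyond `t_max`
#' are censored: they stay in every bin's at-risk count but enter no
#' numerator.
#'
#' @param gaps Numeric vector of inter-visit gaps in minutes (one animal, or
#'   a pooled set).
#' @param t_max Search window in minutes (default 60).
#' @return A `pstart_curve` tibble with columns `t` (left bin edge, 0-based),
#'   `n_events`, `n_at_risk` and `raw` (`NA` where no gaps remain at risk).
#' @export
estimate_pstart <- function(gaps, t_max = 60) {
  gaps <- gaps[!is.na(gaps)]
  if (length(gaps) == 0) pf_abort("no intervals: cannot estimate Pstart")
  pf_assert(all(gaps >= 0), "gaps must be non-negative")
  t <- 0:(t_max - 1)
  bin <- floor(gaps)
  n_events <- vapply(t, function(tt) sum(bin == tt), integer(1))
  n_at_risk <- vapply(t, function(tt) sum(gaps >= tt), integer(1))
  raw <- ifelse(n_at_risk > 0, n_events / n_at_risk, NA_real_)
  out <- tibble::tibble(t = t, n_events = n_events, n_at_risk = n_at_risk, raw = raw)
  class(out) <- c("pstart_curve", class(out))
  out
}

#' Rolling-average smoothing of a Pstart curve
#'
#' Centred rolling mean of the defined raw hazard values; windows are
#' truncated at the edges and skip undefined bins.
#'
#' @param curve A `pstart_curve` from [estimate_pstart()].
#' @param window Odd positive window width in minutes (default 5).
#' @return The curve with an added `smoothed` column.
#' @export
smooth_curve <- function(curve, window = 5) {
  pf_assert(window >= 1 && window %% 2 == 1, "window must be an odd positive integer")
  half <- (window - 1) / 2
  n <- nrow(curve)
  raw <- curve$raw
  smoothed <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    vals <- raw[lo:hi]
    if (any(!is.na(vals))) smoothed[i] <- mean(vals, na.rm = TRUE)
  }
  curve$smoothed <- smoothed
  curve
}

#' Locate the meal criterion on a smoothed Pstart curve
#'
#' Scans successive differences of the smoothed hazard from t = 0. The
#' criterion is the bin holding the local minimum at the first boundary where
#' the difference turns from negative (possibly through a run of exact zeros)
#' to strictly positive. A zero-run inside a descent does not end the scan;
#' when a strictly positive difference ends it, the criterion is the first
#' bin of the plateau holding the minimum value. If the curve never turns
#' back up, the argmin of the smoothed curve is returned with
#' `source = "no-sign-change"`.
#'
#' @param curve A smoothed `pstart_curve` (see [smooth_curve()]).
#' @return A list with `criterion` (minutes, positive integer), `source`
#'   (`"sign-change"` or `"no-sign-change"`), or `NULL` criterion with
#'   `source = "too-few-bins"` when fewer than 3 smoothed bins are defined
#'   (callers should pool animals).
#' @export
find_criterion <- function(curve) {
  pf_assert("smoothed" %in% names(curve), "curve must be smoothed first")
  ok <- !is.na(curve$smoothed)
  if (sum(ok) < 3) {
    return(list(criterion = NULL, source = "too-few-bins"))
  }
  t <- curve$t[ok]
  s <- curve$smoothed[ok]
  d <- diff(s)
  seen_negative <- FALSE
  plateau_start <- NA_integer_
  for (i in seq_along(d)) {
    if (d[i] < 0) {
      seen_negative <- TRUE
      plateau_start <- t[i + 1]
    } else if (d[i] > 0) {
      if (seen_negative) {
        return(list(criterion = max(1L, as.integer(plateau_start)),
                    source = "sign-change"))
      }
      # ascending before any descent: keep scanning from here
      seen_negative <- FALSE
      plateau_start <- NA_integer_
    }
    # d[i] == 0: plateau, keep the first bin of the current minimum
  }
  list(criterion = max(1L, as.integer(t[which.min(s)])), source = "no-sign-change")
}

#' Meal criteria for a cohort
#'
#' Estimates a per-animal meal criterion from each animal's inter-visit gap
#' hazard. Animals with too few gaps for a stable individual curve fall back
#' to the criterion estimated from all gaps of their breed pooled together.
#'
#' @param visits Cleaned visit tibble.
#' @param min_gaps Minimum number of gaps for individual estimation
#'   (default 50).
#' @param t_max Hazard search window in minutes (default 60).
#' @param window Smoothing window in minutes (default 5).
#' @return Tibble with `animal_id`, `breed`, `n_gaps`, `criterion_min`,
#'   `source` (`individual`, `individual-argmin`, or `pooled-fallback`).
#' @export
criteria_for_cohort <- function(visits, min_gaps = 50, t_max = 60, window = 5) {
  gaps <- compute_gaps(visits)
  if (nrow(gaps) == 0) pf_abort("cohort has no inter-visit gaps")

  pooled_criterion <- function(g) {
    cur <- smooth_curve(estimate_pstart(g, t_max = t_max), window = window)
    res <- find_criterion(cur)
    if (is.null(res$criterion)) pf_abort("pooled Pstart curve has too few defined bins")
    res$criterion
  }
  pooled <- lapply(split(gaps$gap_min, gaps$breed), pooled_criterion)

  animals <- dplyr::distinct(visits, .data$animal_id, .data$breed)
  res <- lapply(seq_len(nrow(animals)), function(i) {
    aid <- animals$animal_id[i]
    brd <- animals$breed[i]
    g <- gaps$gap_min[gaps$animal_id == aid]
    if (length(g) >= min_gaps) {
      cur <- smooth_curve(estimate_pstart(g, t_max = t_max), window = window)
      fc <- find_criterion(cur)
      if (!is.null(fc$criterion)) {
        src <- if (fc$source == "sign-change") "individual" else "individual-argmin"
        return(tibble::tibble(animal_id = aid, breed = brd, n_gaps = length(g),
                              criterion_min = fc$criterion, source = src))
      }
    }
    tibble::tibble(animal_id = aid, breed = brd, n_gaps = length(g),
                   criterion_min = pooled[[brd]], source = "pooled-fallback")
  })
  dplyr::bind_rows(res)
}
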