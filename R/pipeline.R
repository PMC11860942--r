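#' Run the full phenotyping pipeline
#'
#' Orchestrates simulate (or load) -> clean -> meal criteria -> meals ->
#' outlier filter -> daily/hourly traits -> social rank -> performance ->
#' per-animal summary -> correlations, writing each stage's artifact as plain
#' CSV/JSON into `out_dir` together with a manifest (row counts and MD5
#' checksums) and the resolved configuration, so any stage can be audited or
#' re-run in isolation. Reruns with the same configuration and seed are
#' checksum-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param visits_path,roster_path CSV inputs for a real-data run; when `NULL`
#'   a synthetic cohort is generated instead.
#' @param sim A [sim_config()] for the synthetic run.
#' @param seed Integer seed for the simulation and the MCD subset search.
#' @param min_gaps,t_max,window Meal-criterion settings
#'   (see [criteria_for_cohort()]).
#' @param event_threshold,window_a,window_b Social-rank settings
#'   (see [social_rank_traits()]).
#' @param mcd_alpha,mcd_factor,mcd_level Outlier-filter settings; set
#'   `filter_outliers = FALSE` to skip filtering.
#' @param alpha Correlation significance threshold.
#' @return Invisibly, a list with all in-memory stage tables and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         visits_path = NULL, roster_path = NULL,
                         sim = sim_config(), seed = 1,
                         min_gaps = 50, t_max = 60, window = 5,
                         event_threshold = NULL,
                         window_a = list(c(8, 20)), window_b = "methods",
                         filter_outliers = TRUE,
                         mcd_alpha = 0.75, mcd_factor = 5, mcd_level = 0.999,
                         alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  emit_csv <- function(tab, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tab, path, progress = FALSE)
    artifacts[[name]] <<- list(file = basename(path), rows = nrow(tab),
                               md5 = unname(tools::md5sum(path)))
  }
  emit_json <- function(obj, name) {
    path <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    artifacts[[name]] <<- list(file = basename(path), md5 = unname(tools::md5sum(path)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pf_abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if (is.null(visits_path)) {
    simres <- stage("simulate", simulate_pens(sim, seed = seed))
    visits_raw <- simres$visits
    roster <- simres$roster
    emit_csv(simres$truth$animals, "truth_animals")
    emit_json(list(criterion_trough_min = simres$truth$criterion_trough_min,
                   n_dropped_meals = simres$truth$n_dropped_meals), "truth")
  } else {
    if (is.null(roster_path)) {
      pf_abort("pipeline stage 'clean' failed: a roster CSV is required with real-data input")
    }
    visits_raw <- stage("read", read_visits(visits_path))
    roster <- stage("read", read_roster(roster_path))
  }

  cleaned <- stage("clean", clean_visits(visits_raw, roster))
  visits <- cleaned$visits
  emit_json(cleaned$report, "cleaning_report")
  emit_csv(visits, "visits_clean")

  criteria <- stage("criterion",
                    criteria_for_cohort(visits, min_gaps = min_gaps,
                                        t_max = t_max, window = window))
  emit_csv(criteria, "criteria")

  meals <- stage("meals", build_meals(visits, criteria))
  emit_csv(meals, "meals")

  if (filter_outliers) {
    filt <- stage("outliers",
                  filter_meal_outliers(meals, alpha = mcd_alpha,
                                       factor = mcd_factor, level = mcd_level,
                                       seed = seed))
    meals_kept <- filt$meals
    emit_json(filt$report, "outlier_report")
  } else {
    meals_kept <- meals[meals$valid, , drop = FALSE]
  }
  emit_csv(meals_kept, "meals_kept")

  agg <- stage("traits-daily", aggregate_daily(meals_kept))
  emit_csv(agg$daily, "traits_daily")
  emit_csv(agg$summary, "observation_summary")
  hourly <- stage("traits-hourly", aggregate_hourly(meals_kept, agg$summary))
  emit_csv(hourly, "traits_hourly")

  rank <- stage("rank", social_rank_traits(visits, agg$daily, criteria,
                                           event_threshold = event_threshold,
                                           window_a = window_a, window_b = window_b))
  emit_csv(rank, "rank_traits")

  perf <- stage("performance", performance_traits(visits, agg$summary, roster))
  emit_csv(perf, "performance")

  summary_tab <- stage("summary", build_summary(meals_kept, agg$daily, rank, perf))
  emit_csv(summary_tab, "animal_summary")

  cors <- stage("correlate", dplyr::bind_rows(lapply(
    split(summary_tab, summary_tab$breed),
    function(df) {
      out <- pearson_matrix(df, alpha = alpha)
      out$breed <- df$breed[1]
      out
    })))
  emit_csv(cors, "correlations")

  resolved <- list(seed = seed, min_gaps = min_gaps, t_max = t_max, window = window,
                   window_a = window_a, window_b = window_b,
                   filter_outliers = filter_outliers, mcd_alpha = mcd_alpha,
                   mcd_factor = mcd_factor, mcd_level = mcd_level, alpha = alpha,
                   sim = if (is.null(visits_path)) unclass(sim) else NULL,
                   visits_path = visits_path, roster_path = roster_path)
  emit_json(resolved, "config_resolved")
  config_md5 <- artifacts[["config_resolved"]]$md5
  manifest <- list(config_md5 = config_md5, artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(visits = visits, criteria = criteria, meals = meals,
                 meals_kept = meals_kept, daily = agg$daily,
                 summary = agg$summary, hourly = hourly, rank = rank,
                 performance = perf, animal_summary = summary_tab,
                 correlations = cors, manifest = manifest))
}
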