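# End-to-end report: simulate -> annotate -> stats -> timing -> regress,
# plus small programmatic fixtures for testing edge cases.

#' Run the full analysis pipeline on simulated cohorts
#'
#' Simulates a control cohort (and optionally a Notch-blockade cohort),
#' runs every analysis stage and assembles a report: cohort composition,
#' division/delamination counts, deltaA-negative growth curve, division
#' likelihoods, the interval-censored activation-timing fit, the division
#' logistic regression with type II Wald tests, the fate model of
#' deltaA-negative mothers, and a side-by-side table of recovered versus
#' configured activation rates next to the reference constants of the prior
#' reservoir/operational model (gamma_r = 0.007/day, gamma_o = 0.023/day,
#' 61/39 split). Deterministic given `(params, seed)`; sub-seeds are
#' derived from `seed` and recorded in the report.
#'
#' @param params a [sim_params()] object for the control cohort.
#' @param n_tracks initial tracks in the control cohort (default 828).
#' @param seed integer master seed.
#' @param ly optional list for a blockade cohort: `n_tracks` (default 261),
#'   `movie_days` (default 7), `imaging_gaps` (default `c(1, 2)`); `NULL`
#'   skips it.
#' @param n_boot bootstrap resamples for the growth curve.
#' @return A list of class `nsc_report` (see details above); stage names
#'   prefix any stage failure.
#' @export
run_pipeline <- function(params = sim_params(), n_tracks = 828L, seed = 1L,
                         ly = list(n_tracks = 261L, movie_days = 7,
                                   imaging_gaps = c(1, 2)),
                         n_boot = 200L) {
  stopifnot(inherits(params, "sim_params"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- list(control = seed, ly = seed + 1L, growth = seed + 2L)

  forest <- stage("simulate", simulate_cohort(params, n_tracks,
                                              seeds$control))
  events <- stage("annotate", detect_divisions(forest))
  delams <- stage("annotate", detect_delaminations(forest))
  modes_dc <- stage("annotate", classify_division_mode(events, forest, 0L))
  trajectories <- stage("annotate", vapply(
    track_ids(forest),
    function(id) classify_delta_trajectory(get_track(forest, id)),
    character(1)))

  set.seed(seeds$growth)
  growth <- stage("stats", normalized_growth(forest, "neg",
                                             n_boot = n_boot))
  n_trk <- length(track_ids(forest))
  likelihood <- stage("stats", division_likelihood(
    sum(events$from_quiescence), n_trk, params$movie_days))
  freq <- stage("stats", division_frequency_per_track(forest))
  conservation <- stage("stats", area_conservation(events, forest))
  recovered <- stage("stats", activation_rate_by_status(forest))

  durations <- stage("timing", extract_durations(forest))
  timing <- stage("timing", if (any(is.finite(durations$upper)))
    fit_exponential_ic(durations) else NULL)

  rows <- stage("regress", build_regression_table(forest))
  ly_report <- NULL
  if (!is.null(ly)) {
    ly_params <- params
    ly_params$movie_days <- ly$movie_days %||% 7
    ly_params$imaging_gaps <- ly$imaging_gaps %||% c(1, 2)
    ly_params <- apply_ly(ly_params, 0)
    ly_forest <- stage("simulate", simulate_cohort(
      ly_params, ly$n_tracks %||% 261L, seeds$ly))
    ly_events <- stage("annotate", detect_divisions(ly_forest, 1L))
    ly_rows <- stage("regress", build_regression_table(ly_forest, 1L))
    ly_report <- list(
      n_tracks = length(track_ids(ly_forest)),
      n_divisions = nrow(ly_events),
      likelihood = division_likelihood(nrow(ly_events),
                                       ly$n_tracks %||% 261L,
                                       ly_params$movie_days))
    rows <- rbind(rows, ly_rows)
  }
  regression <- stage("regress", if (sum(rows$divided) >= 2L &&
                                       sum(!rows$divided) >= 2L)
    fit_division_logistic(rows) else NULL)
  fate_rows <- rows[rows$divided & !rows$delta_pos & !is.na(rows$fate), ,
                    drop = FALSE]
  fate <- stage("regress", if (nrow(fate_rows) >= 1L)
    fit_fate_multinomial(fate_rows) else NULL)

  ref <- params$reference_constants
  status0 <- vapply(track_ids(forest), function(id)
    isTRUE(delta_status(get_track(forest, id)$delta_score[1L])),
    logical(1))
  parameter_table <- data.frame(
    quantity = c("gamma_neg (/day)", "gamma_pos (/day)",
                 "deltaA_neg fraction"),
    configured = c(params$gamma_neg, params$gamma_pos,
                   (1 - params$frac_initial_np) *
                     (1 - params$frac_initial_pos)),
    recovered = c(if (is.null(recovered$neg)) NA else recovered$neg$rate,
                  if (is.null(recovered$pos)) NA else recovered$pos$rate,
                  mean(!status0)),
    reference = c(ref$gamma_r, ref$gamma_o, ref$reservoir_fraction),
    stringsAsFactors = FALSE)

  structure(list(
    seeds = seeds, params = params,
    composition = list(
      n_tracks = n_trk,
      n_root_tracks = n_tracks,
      n_divisions = nrow(events),
      n_from_quiescence = sum(events$from_quiescence),
      n_delaminations = nrow(delams),
      trajectory_counts = table(trajectories),
      mode_counts_dc = table(modes_dc$mode)),
    growth = growth, likelihood = likelihood, frequency = freq,
    conservation = conservation, timing = timing,
    recovered_rates = recovered, regression = regression, fate = fate,
    parameter_table = parameter_table, ly = ly_report),
    class = "nsc_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nsc_report <- function(x, ...) {
  cat("<nsc_report>\n")
  cat("  tracks:", x$composition$n_tracks,
      "(", x$composition$n_root_tracks, "roots ),",
      x$composition$n_divisions, "divisions (",
      x$composition$n_from_quiescence, "from quiescence ),",
      x$composition$n_delaminations, "delaminations\n")
  cat("  division likelihood:", signif(x$likelihood$rate, 3),
      "/cell/day\n")
  if (!is.null(x$timing))
    cat("  activation-to-cytokinesis rate:", signif(x$timing$rate, 3),
        "/day (median", signif(exponential_median(x$timing$rate), 2),
        "d)\n")
  cat("  recovered vs configured rates:\n")
  print(x$parameter_table, row.names = FALSE)
  invisible(x)
}

#' Small bundled fixture datasets
#'
#' Builds, in code, a set of small datasets covering every event type and
#' the edge cases the test suite exercises: a hand-written forest with a
#' division at an early time point, a censored daughter, a delamination, a
#' deltaA switch and missing scores; a simulated forest with ground truth;
#' and a snapshot table. All forests validate against the data model, and
#' every event type occurs at least once.
#'
#' @param seed integer seed for the simulated parts.
#' @return list with `hand` (a `lineage_forest`), `sim` (a simulated
#'   `lineage_forest` with truth attribute), `snapshot` (a cell table).
#' @export
fixture_suite <- function(seed = 42L) {
  hand_points <- rbind(
    # mother dividing at tp 2 after two quiet intervals
    data.frame(fish_id = "F1", treatment = "control", track_id = "M1",
               parent_id = NA, tp_index = 0:2, day = c(0, 2, 5),
               area_um2 = c(100, 101, 102), delta_score = c(0L, 0L, 0L),
               marker_on = c(FALSE, FALSE, TRUE),
               event = c("none", "none", "division")),
    # daughter 1: stays negative, long requiescence
    data.frame(fish_id = "F1", treatment = "control", track_id = "M1.1",
               parent_id = "M1", tp_index = 3:7,
               day = c(7, 10, 12, 15, 17),
               area_um2 = c(50, 50.5, 51, 51.5, 52),
               delta_score = 0L, marker_on = FALSE, event = "none"),
    # daughter 2: turns positive at DC+1, delaminates (censored < 4 d
    # would be tp 3 only); here tracked 5 days then delamination
    data.frame(fish_id = "F1", treatment = "control", track_id = "M1.2",
               parent_id = "M1", tp_index = 3:5, day = c(7, 10, 12),
               area_um2 = c(9, 8.5, 8),
               delta_score = c(0L, 2L, 3L), marker_on = FALSE,
               event = c("none", "none", "delamination")),
    # early divider: division at tp 1 (no quiescence established)
    data.frame(fish_id = "F2", treatment = "control", track_id = "E1",
               parent_id = NA, tp_index = 0:1, day = c(0, 2),
               area_um2 = c(80, 80), delta_score = c(1L, 1L),
               marker_on = TRUE, event = c("none", "division")),
    # censored daughters of the early divider (tracked < 4 days)
    data.frame(fish_id = "F2", treatment = "control", track_id = "E1.1",
               parent_id = "E1", tp_index = 2:3, day = c(5, 7),
               area_um2 = c(40, 40), delta_score = c(2L, 2L),
               marker_on = FALSE, event = "none"),
    data.frame(fish_id = "F2", treatment = "control", track_id = "E1.2",
               parent_id = "E1", tp_index = 2L, day = 5,
               area_um2 = 40, delta_score = 3L,
               marker_on = FALSE, event = "none"),
    # nondivider switching deltaA ON, with a missing score and area
    data.frame(fish_id = "F2", treatment = "control", track_id = "S1",
               parent_id = NA, tp_index = 0:4, day = c(0, 2, 5, 7, 10),
               area_um2 = c(110, NA, 111, 112, 113),
               delta_score = c(0L, 0L, NA, 2L, 2L),
               marker_on = FALSE, event = "none"))
  hand <- lineage_forest(hand_points)
  sim <- simulate_cohort(sim_params(), n_tracks = 60L, seed = seed)
  snapshot <- simulate_snapshot(sim_params(), n_cells = 200L,
                                seed = seed + 1L)
  fix <- list(hand = hand, sim = sim, snapshot = snapshot)
  stopifnot(all(EVENT_LEVELS %in% fix$hand$points$event))
  fix
}
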