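# Event annotation on lineage forests: divisions from quiescence, division
# modes by deltaA status of the daughter pair, deltaA expression
# trajectories, delaminations, daughter-pair area asymmetry, and
# post-division outcomes.

#' Detect division events
#'
#' One event per branching node of the forest. A division counts as
#' originating from quiescence when the mother accumulated at least
#' `min_quiet_intervals` division-free imaging intervals immediately before
#' dividing (two intervals, i.e. 4-5 days, by default — calibrated so that
#' an activation-to-cytokinesis delay of median 2.1 days, below 6 days in
#' 86% of cases, is unlikely to span them). Mother area and deltaA status
#' are read at the last pre-division time point (the MC).
#'
#' @param forest a `lineage_forest`.
#' @param min_quiet_intervals minimal number of division-free imaging
#'   intervals before the division (default 2).
#' @param delta_threshold score threshold for deltaA positivity.
#' @return data.frame with one row per division: `mother_track`,
#'   `daughter1`, `daughter2`, `division_tp` (the DC time point),
#'   `mc_tp`, `division_day`, `mc_day`, `from_quiescence`, `mother_area`,
#'   `mother_status`, `fish_id`, `treatment`.
#' @export
detect_divisions <- function(forest, min_quiet_intervals = 2L,
                             delta_threshold = 1L) {
  stopifnot(inherits(forest, "lineage_forest"))
  kids <- forest_children(forest)
  out <- vector("list", length(kids))
  for (i in seq_along(kids)) {
    mother <- names(kids)[i]
    dtr <- sort(kids[[i]])
    mrows <- get_track(forest, mother)
    n <- nrow(mrows)
    mc <- mrows[n, ]
    drows <- get_track(forest, dtr[1L])
    out[[i]] <- data.frame(
      mother_track = mother, daughter1 = dtr[1L], daughter2 = dtr[2L],
      division_tp = drows$tp_index[1L], mc_tp = mc$tp_index,
      division_day = drows$day[1L], mc_day = mc$day,
      from_quiescence = (n - 1L) >= min_quiet_intervals,
      mother_area = mc$area_um2,
      mother_status = delta_status(mc$delta_score, delta_threshold),
      fish_id = mc$fish_id, treatment = mc$treatment,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(mother_track = character(0), daughter1 = character(0),
               daughter2 = character(0), division_tp = integer(0),
               mc_tp = integer(0), division_day = numeric(0),
               mc_day = numeric(0), from_quiescence = logical(0),
               mother_area = numeric(0), mother_status = logical(0),
               fish_id = character(0), treatment = character(0))
  res[order(res$mother_track), , drop = FALSE]
}

#' Classify the deltaA division mode of a daughter pair
#'
#' Reads the deltaA status of both daughters `horizon` imaging time points
#' after the division time point (DC + horizon) and maps the unordered pair
#' to `neg_neg`, `neg_pos` or `pos_pos`. Strict horizons by default: a
#' daughter must have an observation exactly at DC + horizon; otherwise
#' (track too short, or score missing there) the event is `unclassifiable`.
#' Setting `allow_last_observation = TRUE` falls back to the nearest earlier
#' observed score.
#'
#' @param event one row of [detect_divisions()] output (or the whole frame;
#'   all rows are classified).
#' @param forest the `lineage_forest`.
#' @param horizon integer >= 0; 0 is DC itself.
#' @param delta_threshold score threshold for positivity.
#' @param allow_last_observation fall back to the last earlier score.
#' @return data.frame with columns `mother_track`, `horizon`, `mode`.
#' @export
classify_division_mode <- function(event, forest, horizon = 0L,
                                   delta_threshold = 1L,
                                   allow_last_observation = FALSE) {
  stopifnot(inherits(forest, "lineage_forest"), horizon >= 0L)
  status_at <- function(dtr, tp_target) {
    rows <- forest$points[forest$points$track_id == dtr, , drop = FALSE]
    hit <- rows$delta_score[rows$tp_index == tp_target]
    if (length(hit) == 0L && allow_last_observation) {
      earlier <- rows[rows$tp_index < tp_target & !is.na(rows$delta_score), ,
                      drop = FALSE]
      if (nrow(earlier) > 0L)
        hit <- earlier$delta_score[nrow(earlier)]
    }
    if (length(hit) == 0L || is.na(hit[1L])) return(NA)
    delta_status(hit[1L], delta_threshold)
  }
  one <- function(ev) {
    tp_target <- ev$division_tp + as.integer(horizon)
    s1 <- status_at(ev$daughter1, tp_target)
    s2 <- status_at(ev$daughter2, tp_target)
    if (is.na(s1) || is.na(s2)) return("unclassifiable")
    n_pos <- s1 + s2
    c("neg_neg", "neg_pos", "pos_pos")[n_pos + 1L]
  }
  modes <- vapply(seq_len(nrow(event)),
                  function(i) one(event[i, , drop = FALSE]), character(1))
  data.frame(mother_track = event$mother_track,
             horizon = rep(as.integer(horizon), nrow(event)),
             mode = modes, stringsAsFactors = FALSE)
}

#' Classify a track's deltaA expression trajectory
#'
#' Based on the ordered sequence of deltaA statuses over the scored time
#' points: no status change gives `always_on` / `always_off`, a single
#' change gives `switch_on` / `switch_off`, two or more changes give
#' `mixed`.
#'
#' @param track a track's points (data.frame from [get_track()]).
#' @param delta_threshold score threshold for positivity.
#' @return One of `"always_on"`, `"always_off"`, `"switch_on"`,
#'   `"switch_off"`, `"mixed"`.
#' @export
classify_delta_trajectory <- function(track, delta_threshold = 1L) {
  status <- delta_status(track$delta_score, delta_threshold)
  status <- status[!is.na(status)]
  if (length(status) == 0L)
    stop("track has no scored time points", call. = FALSE)
  runs <- rle(status)$values
  if (length(runs) == 1L) {
    if (runs[1L]) "always_on" else "always_off"
  } else if (length(runs) == 2L) {
    if (runs[2L]) "switch_on" else "switch_off"
  } else {
    "mixed"
  }
}

#' Daughter-pair apical area asymmetry
#'
#' Two areas count as asymmetric when their absolute difference is at least
#' `threshold_frac` of the larger one (inclusive). Using the larger daughter
#' as denominator keeps the measure in [0, 1).
#'
#' @param a1,a2 areas in um^2 (> 0); vectorized.
#' @param threshold_frac asymmetry threshold (default 0.20).
#' @return Logical vector.
#' @export
pair_area_asymmetry <- function(a1, a2, threshold_frac = 0.20) {
  if (any(c(a1, a2) <= 0, na.rm = TRUE))
    stop("areas must be positive", call. = FALSE)
  abs(a1 - a2) / pmax(a1, a2) >= threshold_frac
}

#' Detect delamination events
#'
#' Track interruption before the end of the recording, flagged as a
#' delamination event at the final point, corresponds to a cell leaving the
#' ventricular monolayer (differentiation). Returns the area and deltaA
#' status at that last point.
#'
#' @param forest a `lineage_forest`.
#' @param delta_threshold score threshold for positivity.
#' @return data.frame with columns `track_id`, `tp`, `day`, `last_area`,
#'   `last_status`.
#' @export
detect_delaminations <- function(forest, delta_threshold = 1L) {
  stopifnot(inherits(forest, "lineage_forest"))
  pts <- forest$points
  rows <- pts[pts$event == "delamination", , drop = FALSE]
  data.frame(track_id = rows$track_id, tp = rows$tp_index, day = rows$day,
             last_area = rows$area_um2,
             last_status = delta_status(rows$delta_score, delta_threshold),
             stringsAsFactors = FALSE)
}

#' Post-division outcome of each daughter
#'
#' For each daughter of a division: `reiterative_division` if the daughter
#' track itself ends in a division, `delamination` if it delaminates,
#' `requiescence` if no event occurs and the daughter was tracked for at
#' least `min_days` after the division, and `censored` otherwise. Nothing
#' is imputed for censored daughters.
#'
#' @param events output of [detect_divisions()].
#' @param forest the `lineage_forest`.
#' @param min_days minimal event-free tracking duration (days) to call
#'   requiescence (default 4).
#' @param delta_threshold score threshold for positivity.
#' @return data.frame with one row per daughter: `mother_track`,
#'   `daughter`, `daughter_status` (deltaA at the daughter's first point),
#'   `tracked_days`, `outcome`.
#' @export
post_division_outcome <- function(events, forest, min_days = 4,
                                  delta_threshold = 1L) {
  stopifnot(inherits(forest, "lineage_forest"))
  out <- vector("list", 2L * nrow(events))
  k <- 0L
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    for (dtr in c(ev$daughter1, ev$daughter2)) {
      rows <- get_track(forest, dtr)
      n <- nrow(rows)
      tracked <- rows$day[n] - rows$day[1L]
      terminal <- rows$event[n]
      outcome <- if (terminal == "division") "reiterative_division"
      else if (terminal == "delamination") "delamination"
      else if (tracked >= min_days) "requiescence"
      else "censored"
      k <- k + 1L
      out[[k]] <- data.frame(
        mother_track = ev$mother_track, daughter = dtr,
        daughter_status = delta_status(rows$delta_score[1L],
                                       delta_threshold),
        tracked_days = tracked, outcome = outcome,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}
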