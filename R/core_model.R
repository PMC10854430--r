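# Data model: long-format track tables, lineage forests, snapshot tables.
#
# A track is one cell's time series of apical area (um^2), deltaA reporter
# intensity score (0-3), proliferation-marker flag and a terminal event
# (division or delamination). Tracks are linked into a forest by parent ->
# two-daughter division edges.

TRACK_COLUMNS <- c("fish_id", "treatment", "track_id", "parent_id",
                   "tp_index", "day", "area_um2", "delta_score",
                   "marker_on", "event")

SNAPSHOT_COLUMNS <- c("hemisphere_id", "cell_id", "state", "area_um2",
                      "delta_positive")

EVENT_LEVELS <- c("none", "division", "delamination")
STATE_LEVELS <- c("qNSC", "aNSC_singlet", "aNP")
TREATMENT_LEVELS <- c("control", "LY")

#' Construct and validate a lineage forest
#'
#' A lineage forest holds a long-format table of track points (one row per
#' cell per imaging time point) plus the division edges implied by
#' `parent_id`. Construction validates the full invariant set: per-track
#' monotone time, imaging-day gaps within the configured set, events only at
#' the final point, exactly two daughters per dividing mother starting one
#' time point after the mother's last observation, and constant fish id and
#' treatment within a lineage tree.
#'
#' @param points data.frame with columns `fish_id`, `treatment`, `track_id`,
#'   `parent_id`, `tp_index` (0-based integer), `day` (real days),
#'   `area_um2` (> 0 or NA), `delta_score` (0-3 or NA), `marker_on`
#'   (logical or NA), `event` (`"none"`, `"division"`, `"delamination"`).
#' @param allowed_gaps numeric vector of permitted day gaps between
#'   consecutive imaging time points (default `c(2, 3)`, matching imaging
#'   every 2 to 3 days), or `NULL` to skip the gap check.
#' @param validate if `FALSE`, skip validation (internal use by the
#'   simulator, which constructs valid tables by design).
#' @return An object of class `lineage_forest`.
#' @export
lineage_forest <- function(points, allowed_gaps = c(2, 3), validate = TRUE) {
  points <- coerce_track_points(points)
  ord <- order(points$track_id, points$tp_index)
  points <- points[ord, , drop = FALSE]
  rownames(points) <- NULL
  if (validate) validate_track_points(points, allowed_gaps = allowed_gaps)
  structure(list(points = points, allowed_gaps = allowed_gaps),
            class = "lineage_forest")
}

coerce_track_points <- function(points) {
  stopifnot(is.data.frame(points))
  missing_cols <- setdiff(TRACK_COLUMNS, names(points))
  if (length(missing_cols) > 0L) {
    stop("track table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  points <- points[TRACK_COLUMNS]
  points$fish_id <- as.character(points$fish_id)
  points$treatment <- as.character(points$treatment)
  points$track_id <- as.character(points$track_id)
  points$parent_id <- as.character(points$parent_id)
  points$parent_id[!is.na(points$parent_id) & points$parent_id == ""] <- NA
  points$tp_index <- as.integer(points$tp_index)
  points$day <- as.numeric(points$day)
  points$area_um2 <- as.numeric(points$area_um2)
  points$delta_score <- as.integer(points$delta_score)
  points$marker_on <- as.logical(points$marker_on)
  points$event <- as.character(points$event)
  points$event[is.na(points$event) | points$event == ""] <- "none"
  points
}

validate_track_points <- function(points, allowed_gaps = c(2, 3),
                                  tol = 1e-6) {
  fail <- function(...) stop(..., call. = FALSE)
  if (nrow(points) == 0L) fail("track table has no rows")
  if (anyNA(points$track_id) || anyNA(points$tp_index) || anyNA(points$day))
    fail("track_id, tp_index and day must not be missing")
  if (any(points$tp_index < 0L)) fail("tp_index must be >= 0")
  if (any(points$day < 0)) fail("day must be >= 0")
  bad_area <- !is.na(points$area_um2) & points$area_um2 <= 0
  if (any(bad_area)) {
    fail("nonpositive area for track(s): ",
         paste(unique(points$track_id[bad_area]), collapse = ", "))
  }
  bad_score <- !is.na(points$delta_score) &
    !(points$delta_score %in% 0:3)
  if (any(bad_score)) {
    fail("delta_score outside {0,1,2,3} for track(s): ",
         paste(unique(points$track_id[bad_score]), collapse = ", "))
  }
  bad_event <- !(points$event %in% EVENT_LEVELS)
  if (any(bad_event)) {
    fail("unknown event value(s): ",
         paste(unique(points$event[bad_event]), collapse = ", "))
  }
  bad_trt <- !(points$treatment %in% TREATMENT_LEVELS)
  if (any(bad_trt)) {
    fail("unknown treatment value(s): ",
         paste(unique(points$treatment[bad_trt]), collapse = ", "))
  }

  by_track <- split(seq_len(nrow(points)), points$track_id)
  first_tp <- integer(length(by_track))
  last_tp <- integer(length(by_track))
  names(first_tp) <- names(last_tp) <- names(by_track)
  for (id in names(by_track)) {
    idx <- by_track[[id]]
    tp <- points$tp_index[idx]
    day <- points$day[idx]
    if (any(diff(tp) <= 0L))
      fail("tp_index not strictly increasing in track ", id)
    if (any(diff(day) <= 0))
      fail("day not strictly increasing in track ", id)
    if (!is.null(allowed_gaps)) {
      gaps <- diff(day)
      ok <- vapply(gaps, function(g) any(abs(g - allowed_gaps) < tol),
                   logical(1))
      if (!all(ok))
        fail("imaging-day gap outside allowed set in track ", id)
    }
    ev <- points$event[idx]
    if (any(ev[-length(ev)] != "none"))
      fail("event at non-final time point in track ", id)
    if (length(unique(points$fish_id[idx])) != 1L ||
        length(unique(points$treatment[idx])) != 1L)
      fail("fish_id/treatment not constant within track ", id)
    pid <- unique(points$parent_id[idx])
    if (length(pid) != 1L)
      fail("parent_id not constant within track ", id)
    first_tp[id] <- tp[1L]
    last_tp[id] <- tp[length(tp)]
  }

  meta_idx <- vapply(by_track, `[`, integer(1), 1L)
  parent <- points$parent_id[meta_idx]
  names(parent) <- names(by_track)
  known <- names(by_track)
  orphan <- !is.na(parent) & !(parent %in% known)
  if (any(orphan)) {
    fail("parent_id refers to unknown track(s): ",
         paste(unique(parent[orphan]), collapse = ", "))
  }
  kids <- table(parent[!is.na(parent)])
  if (any(kids != 2L)) {
    fail("division with != 2 daughters for track(s): ",
         paste(names(kids)[kids != 2L], collapse = ", "))
  }
  for (id in names(parent)[!is.na(parent)]) {
    p <- parent[[id]]
    if (first_tp[[id]] != last_tp[[p]] + 1L)
      fail("daughter ", id, " does not start one tp after mother ", p)
    if (points$event[by_track[[p]][length(by_track[[p]])]] != "division")
      fail("mother ", p, " lacks a terminal division event")
    if (points$fish_id[meta_idx[[id]]] != points$fish_id[meta_idx[[p]]] ||
        points$treatment[meta_idx[[id]]] != points$treatment[meta_idx[[p]]])
      fail("fish_id/treatment differ between mother ", p,
           " and daughter ", id)
  }
  # acyclicity: walk each track to its root; the tp condition already
  # forbids cycles but a corrupted table could still loop.
  for (id in names(parent)) {
    seen <- character(0)
    cur <- id
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) fail("cycle in parent links at track ", id)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  invisible(TRUE)
}

#' @export
print.lineage_forest <- function(x, ...) {
  ids <- unique(x$points$track_id)
  n_div <- sum(x$points$event == "division")
  n_del <- sum(x$points$event == "delamination")
  cat("<lineage_forest> ", length(ids), " tracks, ",
      nrow(x$points), " points, ", n_div, " divisions, ",
      n_del, " delaminations\n", sep = "")
  invisible(x)
}

#' @export
format.lineage_forest <- function(x, ...) {
  paste0("<lineage_forest: ", length(unique(x$points$track_id)), " tracks>")
}

#' Track ids of a forest
#' @param forest a `lineage_forest`.
#' @return Character vector of track ids.
#' @export
track_ids <- function(forest) unique(forest$points$track_id)

#' Extract one track's points
#' @param forest a `lineage_forest`.
#' @param id a track id.
#' @return data.frame of the track's points, ordered by `tp_index`.
#' @export
get_track <- function(forest, id) {
  rows <- forest$points[forest$points$track_id == id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown track id: ", id, call. = FALSE)
  rows
}

# parent -> c(daughter1, daughter2) mapping
forest_children <- function(forest) {
  pts <- forest$points
  first <- pts[!duplicated(pts$track_id), c("track_id", "parent_id")]
  first <- first[!is.na(first$parent_id), , drop = FALSE]
  split(first$track_id, first$parent_id)
}

#' Read a long-format track table
#'
#' Reads a comma-separated track table (header
#' `fish_id,treatment,track_id,parent_id,tp_index,day,area_um2,delta_score,
#' marker_on,event`; empty fields encode missing values) and returns a
#' validated [lineage_forest()]. Malformed fields raise a parse error naming
#' the offending line; invariant violations raise a validation error naming
#' the track.
#'
#' @param path path to a CSV file.
#' @param allowed_gaps permitted imaging-day gaps, see [lineage_forest()].
#' @return A `lineage_forest`.
#' @export
read_tracks <- function(path, allowed_gaps = c(2, 3)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0))
  missing_cols <- setdiff(TRACK_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("track table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col, what, integer = FALSE) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & x != "")
    if (length(bad) > 0L) {
      stop("parse error at line ", bad[1L] + 1L, ": ", what,
           " '", x[bad[1L]], "' is not numeric", call. = FALSE)
    }
    out[x == ""] <- NA
    if (integer) out <- as.integer(out)
    out
  }
  parse_bool <- function(col) {
    x <- raw[[col]]
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "true", "True", "1")] <- TRUE
    out[x %in% c("FALSE", "false", "False", "0")] <- FALSE
    bad <- which(is.na(out) & x != "")
    if (length(bad) > 0L) {
      stop("parse error at line ", bad[1L] + 1L, ": ", col,
           " '", x[bad[1L]], "' is not logical", call. = FALSE)
    }
    out
  }
  points <- data.frame(
    fish_id = raw$fish_id,
    treatment = raw$treatment,
    track_id = raw$track_id,
    parent_id = ifelse(raw$parent_id == "", NA, raw$parent_id),
    tp_index = parse_num("tp_index", "tp_index", integer = TRUE),
    day = parse_num("day", "day"),
    area_um2 = parse_num("area_um2", "area_um2"),
    delta_score = parse_num("delta_score", "delta_score", integer = TRUE),
    marker_on = parse_bool("marker_on"),
    event = raw$event,
    stringsAsFactors = FALSE
  )
  lineage_forest(points, allowed_gaps = allowed_gaps)
}

#' Write a track table
#'
#' Inverse of [read_tracks()]: writes the forest's points as CSV with empty
#' fields for missing values, so that `read_tracks(write_tracks(f))`
#' round-trips the data model.
#'
#' @param forest a `lineage_forest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(forest, path) {
  stopifnot(inherits(forest, "lineage_forest"))
  utils::write.csv(forest$points, path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' Read a static snapshot cell table
#'
#' Snapshot tables emulate fixed-tissue quantifications: one row per cell
#' with its hemisphere, state (`qNSC`, `aNSC_singlet`, `aNP`), apical area
#' and deltaA positivity.
#'
#' @param path path to a CSV file with header
#'   `hemisphere_id,cell_id,state,area_um2,delta_positive`.
#' @return data.frame of cells.
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_snapshot(cells)
  cells
}

#' Write a snapshot cell table
#' @param cells data.frame as returned by [simulate_snapshot()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(cells, path) {
  validate_snapshot(cells)
  utils::write.csv(cells, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

validate_snapshot <- function(cells) {
  missing_cols <- setdiff(SNAPSHOT_COLUMNS, names(cells))
  if (length(missing_cols) > 0L) {
    stop("snapshot table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(cells$state %in% STATE_LEVELS)) {
    stop("unknown state value(s): ",
         paste(setdiff(unique(cells$state), STATE_LEVELS), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(cells$area_um2) & cells$area_um2 <= 0))
    stop("nonpositive snapshot area", call. = FALSE)
  invisible(TRUE)
}

#' deltaA positivity from an intensity score
#'
#' The deltaA reporter signal is binned into integer intensity scores 0-3
#' (0 = no visible expression, 3 = strong). A cell counts as deltaA-positive
#' when any expression is visible, i.e. score >= 1 by default; the threshold
#' is configurable. Missing scores propagate as `NA`, never as `FALSE`.
#'
#' @param score integer vector of scores in 0-3 (NA allowed).
#' @param threshold minimal score counting as positive (default 1).
#' @return Logical vector (NA where the score is missing).
#' @export
delta_status <- function(score, threshold = 1L) {
  stopifnot(length(threshold) == 1L, threshold >= 0)
  bad <- !is.na(score) & !(score %in% 0:3)
  if (any(bad)) stop("delta_score outside {0,1,2,3}", call. = FALSE)
  ifelse(is.na(score), NA, score >= threshold)
}

#' A per-day rate with confidence interval
#'
#' Container for estimated per-day rates (activation rates, division
#' likelihoods, growth rates) together with a 95% confidence interval, the
#' implied doubling time `ln(2)/rate` and the number of events behind the
#' estimate.
#'
#' @param rate point estimate, per day.
#' @param ci_low,ci_high confidence bounds, per day.
#' @param n_events integer event count.
#' @return An object of class `rate_estimate`.
#' @export
rate_estimate <- function(rate, ci_low = NA_real_, ci_high = NA_real_,
                          n_events = NA_integer_) {
  stopifnot(is.numeric(rate), length(rate) == 1L)
  if (!is.na(ci_low) && !is.na(ci_high) &&
      !(ci_low <= rate + 1e-12 && rate <= ci_high + 1e-12))
    stop("confidence interval does not bracket the rate", call. = FALSE)
  structure(list(rate = rate, ci_low = ci_low, ci_high = ci_high,
                 doubling_time = ifelse(rate > 0, log(2) / rate, NA_real_),
                 n_events = as.integer(n_events)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate %.4g /day [95%% CI %.4g, %.4g], doubling time %.3g d, n = %s\n",
              x$rate, x$ci_low, x$ci_high, x$doubling_time,
              ifelse(is.na(x$n_events), "?", x$n_events)))
  invisible(x)
}
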