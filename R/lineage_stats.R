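# Descriptive and rate statistics: normalized apical-area growth curves,
# doubling times, per-cell-per-day division likelihoods with exact Poisson
# intervals, per-fish division frequencies, area conservation at division,
# and snapshot summaries with Mann-Whitney comparisons.

#' Normalized apical-area growth of nondividing tracks
#'
#' Selects nondividing tracks (no division event, no daughters), optionally
#' filtered by deltaA status (a track is `"neg"` when every scored point is
#' below threshold, `"pos"` when every scored point is at or above it),
#' normalizes each track's areas to its first observed area, and summarizes
#' per day (relative to each track's first observation) with the median and
#' a seeded percentile-bootstrap 95% CI over tracks. A per-day exponential
#' growth rate is fitted by log-linear regression of the median on the day.
#'
#' @param forest a `lineage_forest`.
#' @param status one of `"neg"`, `"pos"`, `"all"`.
#' @param delta_threshold score threshold for positivity.
#' @param include_delaminating keep tracks that end in delamination
#'   (default `FALSE`: growth is a quiescence-phase quantity).
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param conf confidence level (default 0.95).
#' @return An object of class `growth_curve`: list with `day_bins`,
#'   `median_normalized_area`, `ci_low`, `ci_high`, `n_per_bin`,
#'   `fitted_rate` (a [rate_estimate()]) and `n_tracks`.
#' @export
normalized_growth <- function(forest, status = c("neg", "pos", "all"),
                              delta_threshold = 1L,
                              include_delaminating = FALSE,
                              n_boot = 1000L, conf = 0.95) {
  stopifnot(inherits(forest, "lineage_forest"))
  status <- match.arg(status)
  pts <- forest$points
  mothers <- unique(pts$parent_id[!is.na(pts$parent_id)])
  last <- pts[!duplicated(pts$track_id, fromLast = TRUE), ]
  drop <- last$track_id[last$event == "division"]
  if (!include_delaminating)
    drop <- c(drop, last$track_id[last$event == "delamination"])
  keep <- setdiff(unique(pts$track_id), c(mothers, drop))

  series <- list()
  for (id in keep) {
    rows <- pts[pts$track_id == id, , drop = FALSE]
    st <- delta_status(rows$delta_score, delta_threshold)
    st <- st[!is.na(st)]
    if (length(st) == 0L) next
    if (status == "neg" && any(st)) next
    if (status == "pos" && !all(st)) next
    ok <- which(!is.na(rows$area_um2))
    if (length(ok) < 1L) next
    rows <- rows[ok, , drop = FALSE]
    series[[id]] <- data.frame(
      rel_day = rows$day - rows$day[1L],
      norm_area = rows$area_um2 / rows$area_um2[1L])
  }
  if (length(series) == 0L)
    stop("no nondividing tracks match the selection", call. = FALSE)

  long <- do.call(rbind, series)
  long$track <- rep(names(series), vapply(series, nrow, integer(1)))
  day_bins <- sort(unique(long$rel_day))
  med_at <- function(trks) {
    sub <- long[long$track %in% trks, ]
    vapply(day_bins, function(d) {
      v <- sub$norm_area[abs(sub$rel_day - d) < 1e-9]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1))
  }
  med <- med_at(names(series))
  n_per_bin <- vapply(day_bins, function(d)
    sum(abs(long$rel_day - d) < 1e-9), integer(1))

  boot <- matrix(NA_real_, n_boot, length(day_bins))
  ids <- names(series)
  for (b in seq_len(n_boot))
    boot[b, ] <- med_at(sample(ids, length(ids), replace = TRUE))
  alpha <- (1 - conf) / 2
  ci_low <- apply(boot, 2, stats::quantile, probs = alpha, na.rm = TRUE)
  ci_high <- apply(boot, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)

  pos_med <- med > 0 & !is.na(med)
  fit <- stats::lm(log(med[pos_med]) ~ day_bins[pos_med])
  slope <- unname(stats::coef(fit)[2L])
  ci <- tryCatch(suppressWarnings(stats::confint(fit)[2L, ]),
                 error = function(e) c(NA_real_, NA_real_))
  fitted_rate <- structure(
    list(rate = slope, ci_low = unname(ci[1L]), ci_high = unname(ci[2L]),
         doubling_time = ifelse(slope > 0, log(2) / slope, NA_real_),
         n_events = length(series)),
    class = "rate_estimate")

  structure(list(day_bins = day_bins, median_normalized_area = med,
                 ci_low = ci_low, ci_high = ci_high,
                 n_per_bin = n_per_bin, fitted_rate = fitted_rate,
                 n_tracks = length(series), status = status),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("<growth_curve> ", x$n_tracks, " tracks (", x$status, "), ",
      length(x$day_bins), " day bins, day ", max(x$day_bins),
      " median = ", round(x$median_normalized_area[length(x$day_bins)], 3),
      ", fitted rate ", signif(x$fitted_rate$rate, 3), " /day\n", sep = "")
  invisible(x)
}

#' Doubling time of an exponential per-day rate
#'
#' @param rate per-day rate (> 0).
#' @return `log(2) / rate`, in days.
#' @export
doubling_time <- function(rate) {
  if (any(rate <= 0)) stop("rate must be positive", call. = FALSE)
  log(2) / rate
}

#' Per-cell-per-day division likelihood
#'
#' Point estimate `n_divisions / (n_tracks * days)` with an exact Poisson
#' 95% CI on the event count divided by the exposure. The Poisson (rather
#' than binomial) interval reflects that divisions are rare events counted
#' over cell-time exposure.
#'
#' @param n_divisions number of divisions observed.
#' @param n_tracks number of tracked cells.
#' @param days observation duration in days.
#' @param conf confidence level (default 0.95).
#' @return A [rate_estimate()] (per cell per day).
#' @export
division_likelihood <- function(n_divisions, n_tracks, days, conf = 0.95) {
  if (n_divisions < 0) stop("negative division count", call. = FALSE)
  if (n_tracks <= 0 || days <= 0)
    stop("n_tracks and days must be positive", call. = FALSE)
  exposure <- n_tracks * days
  ci <- stats::poisson.test(n_divisions, conf.level = conf)$conf.int
  rate_estimate(n_divisions / exposure, ci[1L] / exposure,
                ci[2L] / exposure, n_events = n_divisions)
}

#' Per-fish division frequency of tracks
#'
#' Percentage of tracks with at least one division from quiescence during
#' the movie, computed per fish and summarized by mean and SEM across fish.
#' Optionally restricted to tracks of one deltaA status (status of the
#' track = its most prevalent scored status).
#'
#' @param forest a `lineage_forest`.
#' @param min_quiet_intervals passed to [detect_divisions()].
#' @param status `"all"`, `"neg"` or `"pos"`.
#' @param delta_threshold score threshold for positivity.
#' @return list with `per_fish` (data.frame `fish_id`, `n_tracks`,
#'   `n_dividing`, `percent`), `mean_percent`, `sem_percent`.
#' @export
division_frequency_per_track <- function(forest, min_quiet_intervals = 2L,
                                         status = c("all", "neg", "pos"),
                                         delta_threshold = 1L) {
  stopifnot(inherits(forest, "lineage_forest"))
  status <- match.arg(status)
  pts <- forest$points
  events <- detect_divisions(forest, min_quiet_intervals, delta_threshold)
  dividing <- unique(events$mother_track[events$from_quiescence])
  ids <- unique(pts$track_id)
  if (status != "all") {
    prevalent <- vapply(ids, function(id) {
      st <- delta_status(pts$delta_score[pts$track_id == id],
                         delta_threshold)
      st <- st[!is.na(st)]
      if (length(st) == 0L) return(NA)
      mean(st) >= 0.5
    }, logical(1))
    ids <- ids[!is.na(prevalent) & (prevalent == (status == "pos"))]
  }
  fish_of <- pts$fish_id[match(ids, pts$track_id)]
  per_fish <- do.call(rbind, lapply(unique(fish_of), function(f) {
    trks <- ids[fish_of == f]
    if (length(trks) == 0L) return(NULL)
    nd <- sum(trks %in% dividing)
    data.frame(fish_id = f, n_tracks = length(trks), n_dividing = nd,
               percent = 100 * nd / length(trks),
               stringsAsFactors = FALSE)
  }))
  empty <- setdiff(unique(pts$fish_id), per_fish$fish_id)
  if (length(empty) > 0L)
    warning("fish with 0 matching tracks excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
  m <- mean(per_fish$percent)
  sem <- if (nrow(per_fish) > 1L)
    stats::sd(per_fish$percent) / sqrt(nrow(per_fish)) else 0
  list(per_fish = per_fish, mean_percent = m, sem_percent = sem)
}

#' Apical-area conservation at division
#'
#' For each division with both daughter areas observed at DC, the ratio of
#' the summed daughter areas to the mother's area at MC. Under pure
#' cytokinesis the ratio is 1: each division halves the apical surface
#' without loss.
#'
#' @param events output of [detect_divisions()].
#' @param forest the `lineage_forest`.
#' @return list with `ratios` (data.frame `mother_track`, `ratio`),
#'   `median`, `iqr`, `n_skipped` (events with missing areas).
#' @export
area_conservation <- function(events, forest) {
  stopifnot(inherits(forest, "lineage_forest"))
  pts <- forest$points
  first_area <- function(id) {
    rows <- pts[pts$track_id == id, , drop = FALSE]
    rows$area_um2[1L]
  }
  out <- vector("list", nrow(events))
  skipped <- 0L
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    a1 <- first_area(ev$daughter1)
    a2 <- first_area(ev$daughter2)
    if (is.na(a1) || is.na(a2) || is.na(ev$mother_area)) {
      skipped <- skipped + 1L
      next
    }
    out[[i]] <- data.frame(mother_track = ev$mother_track,
                           ratio = (a1 + a2) / ev$mother_area,
                           stringsAsFactors = FALSE)
  }
  ratios <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(ratios))
    ratios <- data.frame(mother_track = character(0), ratio = numeric(0))
  list(ratios = ratios,
       median = if (nrow(ratios)) stats::median(ratios$ratio) else NA_real_,
       iqr = if (nrow(ratios)) stats::IQR(ratios$ratio) else NA_real_,
       n_skipped = skipped)
}

# Mann-Whitney U with midrank ties; exact enumeration (via the null
# distribution of the rank-sum statistic) when both groups are small and
# tie-free, otherwise normal approximation with tie correction.
mann_whitney <- function(x, y, exact_max = 20L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  use_exact <- !ties && n1 <= exact_max && n2 <= exact_max
  if (use_exact) {
    # two-sided exact p from the null distribution of U
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 1 - stats::pwilcox(u - 1, n1, n2))
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) /
         ((n1 + n2) * (n1 + n2 - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = u, p = p, exact = use_exact)
}

#' Summarize a snapshot cell table
#'
#' Per-group (state, optionally split by deltaA status) count, mean, SD and
#' median of apical areas, plus all pairwise Mann-Whitney U comparisons of
#' the area distributions (two-sided; exact for small tie-free groups,
#' normal approximation with tie correction otherwise).
#'
#' @param cells snapshot data.frame (see [simulate_snapshot()]).
#' @param by_status also split groups by `delta_positive`.
#' @param exact_max maximal group size for the exact Mann-Whitney p.
#' @return list with `groups` (summary data.frame) and `tests`
#'   (data.frame `group1`, `group2`, `U`, `p`, `exact`).
#' @export
snapshot_summary <- function(cells, by_status = FALSE, exact_max = 20L) {
  validate_snapshot(cells)
  key <- if (by_status)
    paste0(cells$state, ifelse(cells$delta_positive, "_pos", "_neg"))
  else cells$state
  groups_list <- split(cells$area_um2, key)
  groups_list <- groups_list[vapply(groups_list, length, integer(1)) > 0L]
  if (length(groups_list) < 2L)
    stop("need at least two nonempty groups", call. = FALSE)
  groups <- do.call(rbind, lapply(names(groups_list), function(g) {
    a <- groups_list[[g]]
    data.frame(group = g, n = length(a), mean = mean(a), sd = stats::sd(a),
               median = stats::median(a),
               delta_pos_frac = mean(cells$delta_positive[key == g]),
               stringsAsFactors = FALSE)
  }))
  combos <- utils::combn(names(groups_list), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    mw <- mann_whitney(groups_list[[g1]], groups_list[[g2]], exact_max)
    data.frame(group1 = g1, group2 = g2, U = mw$U, p = mw$p,
               exact = mw$exact, stringsAsFactors = FALSE)
  }))
  list(groups = groups, tests = tests)
}

#' Activation rates recovered from a simulated or annotated forest
#'
#' Estimates the per-day activation hazard separately for deltaA-negative
#' and deltaA-positive quiescent cells as (number of first marker onsets) /
#' (summed quiescent exposure in days), with exact Poisson CIs. Status is
#' the track's status before onset (first scored point); exposure runs from
#' a track's first observation to its marker onset (or last observation).
#' Tracks already marker-positive at their first point carry no observable
#' quiescent exposure and are skipped.
#'
#' @param forest a `lineage_forest`.
#' @param delta_threshold score threshold for positivity.
#' @return list with elements `neg` and `pos`, each a [rate_estimate()].
#' @export
activation_rate_by_status <- function(forest, delta_threshold = 1L) {
  stopifnot(inherits(forest, "lineage_forest"))
  pts <- forest$points
  ids <- unique(pts$track_id)
  events <- c(neg = 0L, pos = 0L)
  exposure <- c(neg = 0, pos = 0)
  for (id in ids) {
    rows <- pts[pts$track_id == id, , drop = FALSE]
    st0 <- delta_status(rows$delta_score[1L], delta_threshold)
    if (is.na(st0)) next
    grp <- if (st0) "pos" else "neg"
    on_idx <- which(!is.na(rows$marker_on) & rows$marker_on)
    # marker already ON at first observation: no quiescent exposure seen
    if (length(on_idx) > 0L && on_idx[1L] == 1L) next
    if (length(on_idx) > 0L) {
      events[grp] <- events[grp] + 1L
      exposure[grp] <- exposure[grp] + rows$day[on_idx[1L]] - rows$day[1L]
    } else if (rows$event[nrow(rows)] == "division") {
      # cytokinesis within the activation interval: the marker was never
      # imaged ON, but the division itself attests the activation
      events[grp] <- events[grp] + 1L
      exposure[grp] <- exposure[grp] + rows$day[nrow(rows)] - rows$day[1L]
    } else {
      exposure[grp] <- exposure[grp] + rows$day[nrow(rows)] - rows$day[1L]
    }
  }
  one <- function(grp) {
    if (exposure[grp] <= 0) return(NULL)
    ci <- stats::poisson.test(events[grp])$conf.int
    rate_estimate(events[grp] / exposure[grp], ci[1L] / exposure[grp],
                  ci[2L] / exposure[grp], n_events = events[grp])
  }
  list(neg = one("neg"), pos = one("pos"))
}
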