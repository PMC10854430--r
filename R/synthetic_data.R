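# Stochastic generator of NSC lineage forests and tissue snapshots.
#
# The generative model mirrors the lineage-progression picture the analysis
# assumes: quiescent NSCs activate with a status-dependent per-day hazard
# (deltaA-negative cells rarely, deltaA-positive cells ~4x more often),
# activated cells divide after an exponential activation-to-cytokinesis
# delay, divisions halve the apical area between two daughters, mothers not
# expressing deltaA produce one permanently negative and one positive
# daughter (binary asymmetry), deltaA-positive mothers produce two positive
# daughters of unequal score, quiescent negative cells grow slowly and
# exponentially, and small deltaA-positive cells delaminate.

#' Simulation parameters for the lineage-progression model
#'
#' Returns the full parameter set of the stochastic lineage simulator with
#' defaults set to the rates, growth laws and fate proportions measured in
#' the adult zebrafish pallium. Any parameter can be overridden by name.
#'
#' Key defaults: activation rates `gamma_neg = 0.0056` and
#' `gamma_pos = 0.0246` per day (doubling times 124 and 28 days);
#' activation-onset-to-cytokinesis rate `lambda_act = 0.326` per day (median
#' delay 2.1 days); quiescent growth of deltaA-negative cells
#' `log(1.3)/40` per day (30% in 40 days) and zero for positive cells;
#' delamination below 10 um^2 for deltaA-positive cells; 70% of the positive
#' daughters of a negative mother already scored ON at the first daughter
#' time point; 223/250 of positive daughters returning to quiescence;
#' per-movie deltaA switch rates 9/703 (OFF) and 5/703 (ON) among
#' nondividers; imaging every 2-3 days for 43 days; under Notch blockade
#' (LY411575) a shared division hazard of 0.0852 per cell per day.
#'
#' @param gamma_neg,gamma_pos per-day activation hazards of quiescent
#'   deltaA-negative / deltaA-positive NSCs.
#' @param area_coupling log-odds slope (per um^2) of the activation hazard
#'   on apical area around the status-specific reference area; 0 disables
#'   the area effect (the default: the data constrain only monotonicity,
#'   so the neutral value keeps the configured hazards exact).
#' @param area_ref named numeric, reference areas (um^2) for the area
#'   coupling, per status.
#' @param lambda_act per-day rate of the activation-onset-to-cytokinesis
#'   exponential delay.
#' @param growth_neg,growth_pos per-day multiplicative apical growth of
#'   quiescent deltaA-negative / positive cells.
#' @param delam_area_threshold area (um^2) below which cells may delaminate.
#' @param delam_requires_pos only deltaA-positive cells delaminate.
#' @param delam_rate per-day delamination hazard once below the threshold.
#' @param area_init list of `c(mean, sd)` (um^2) per state/status for
#'   initial-area lognormal draws.
#' @param division_asym_noise SD of the daughter area fraction around 0.5;
#'   the default 0.106 makes ~60% of daughter pairs differ by >= 20%.
#' @param smaller_gets_pos_prob probability that the deltaA-positive (or
#'   higher-scoring) daughter is the smaller of the pair.
#' @param fate_on_at_DC_prob probability that the positive daughter of a
#'   negative mother is already scored ON at the division time point rather
#'   than one time point later.
#' @param pospos_binary_frac fraction of positive/positive daughter pairs
#'   that later convert to a binary ON/OFF pair.
#' @param pospos_binary_lag_mean mean (days) of the exponential lag to that
#'   conversion.
#' @param switch_off_rate,switch_on_rate per-track-per-movie probabilities
#'   of a spontaneous deltaA switch in nondividing tracks.
#' @param requiescence_prob_pos probability that a deltaA-positive daughter
#'   returns to quiescence (else it re-divides without a quiescence phase).
#' @param frac_initial_pos fraction of initial NSC tracks that are
#'   deltaA-positive.
#' @param frac_initial_np fraction of initial tracks that are small
#'   aNP-like deltaA-positive cells (the delaminating pool).
#' @param imaging_gaps day gaps of the imaging grid, cycled (default
#'   `c(2, 3)`).
#' @param movie_days total imaging duration in days.
#' @param meas_noise_sd SD of multiplicative lognormal measurement noise on
#'   recorded areas (0 records true areas).
#' @param ly_rate per-cell-per-day division hazard under Notch blockade.
#' @param ly_start day from which Notch blockade applies (`NA` = never; see
#'   [apply_ly()]).
#' @param n_fish number of fish the tracks are distributed over.
#' @param state_mix named fractions of `qNSC`, `aNSC_singlet`, `aNP` cells
#'   in simulated snapshots.
#' @param delta_frac named fractions of deltaA-positive cells per state in
#'   simulated snapshots.
#' @param reference_constants prior-model constants reported for comparison
#'   only (reservoir/operational activation rates and split).
#' @return An object of class `sim_params` (a validated named list).
#' @export
sim_params <- function(gamma_neg = 0.0056,
                       gamma_pos = 0.0246,
                       area_coupling = 0,
                       area_ref = c(neg = 112, pos = 54),
                       lambda_act = 0.326,
                       growth_neg = log(1.3) / 40,
                       growth_pos = 0,
                       delam_area_threshold = 10,
                       delam_requires_pos = TRUE,
                       delam_rate = 0.15,
                       area_init = list(
                         qNSC = c(84, 8.9),
                         aNSC_singlet = c(54, 17.1),
                         aNP = c(10, 3.6),
                         qNSC_neg = c(112, 15.4),
                         qNSC_pos = c(54, 3.7),
                         aNSC_neg = c(91, 28.2),
                         aNSC_pos = c(32, 8.3)),
                       division_asym_noise = 0.106,
                       smaller_gets_pos_prob = 0.7,
                       fate_on_at_DC_prob = 0.7,
                       pospos_binary_frac = 0.05,
                       pospos_binary_lag_mean = 11.5,
                       switch_off_rate = 9 / 703,
                       switch_on_rate = 5 / 703,
                       requiescence_prob_pos = 223 / 250,
                       frac_initial_pos = 0.20,
                       frac_initial_np = 0.12,
                       imaging_gaps = c(2, 3),
                       movie_days = 43,
                       meas_noise_sd = 0.05,
                       ly_rate = 0.0852,
                       ly_start = NA_real_,
                       n_fish = 4L,
                       state_mix = c(qNSC = 0.80, aNSC_singlet = 0.06,
                                     aNP = 0.14),
                       delta_frac = c(qNSC = 0.23, aNSC_singlet = 0.87,
                                      aNP = 0.99),
                       reference_constants = list(gamma_r = 0.007,
                                                  gamma_o = 0.023,
                                                  reservoir_fraction = 0.61)) {
  p <- list(gamma_neg = gamma_neg, gamma_pos = gamma_pos,
            area_coupling = area_coupling, area_ref = area_ref,
            lambda_act = lambda_act, growth_neg = growth_neg,
            growth_pos = growth_pos,
            delam_area_threshold = delam_area_threshold,
            delam_requires_pos = delam_requires_pos,
            delam_rate = delam_rate, area_init = area_init,
            division_asym_noise = division_asym_noise,
            smaller_gets_pos_prob = smaller_gets_pos_prob,
            fate_on_at_DC_prob = fate_on_at_DC_prob,
            pospos_binary_frac = pospos_binary_frac,
            pospos_binary_lag_mean = pospos_binary_lag_mean,
            switch_off_rate = switch_off_rate,
            switch_on_rate = switch_on_rate,
            requiescence_prob_pos = requiescence_prob_pos,
            frac_initial_pos = frac_initial_pos,
            frac_initial_np = frac_initial_np,
            imaging_gaps = imaging_gaps, movie_days = movie_days,
            meas_noise_sd = meas_noise_sd, ly_rate = ly_rate,
            ly_start = ly_start, n_fish = as.integer(n_fish),
            state_mix = state_mix, delta_frac = delta_frac,
            reference_constants = reference_constants)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  rates <- c(p$gamma_neg, p$gamma_pos, p$lambda_act, p$delam_rate,
             p$ly_rate)
  chk(all(rates >= 0), "rates must be >= 0")
  chk(p$area_coupling >= 0, "area_coupling must be >= 0")
  probs <- c(p$fate_on_at_DC_prob, p$pospos_binary_frac,
             p$requiescence_prob_pos, p$frac_initial_pos,
             p$frac_initial_np, p$smaller_gets_pos_prob,
             p$switch_off_rate, p$switch_on_rate, p$state_mix, p$delta_frac)
  chk(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  chk(abs(sum(p$state_mix) - 1) < 1e-8, "state_mix must sum to 1")
  chk(all(vapply(p$area_init, function(a) all(a > 0), logical(1))),
      "area distributions must be positive")
  chk(all(p$imaging_gaps > 0), "imaging gaps must be positive")
  chk(p$movie_days > 0, "movie_days must be positive")
  chk(p$division_asym_noise >= 0 && p$meas_noise_sd >= 0,
      "noise SDs must be >= 0")
  invisible(TRUE)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> gamma_neg =", x$gamma_neg, "/d, gamma_pos =",
      x$gamma_pos, "/d, lambda_act =", x$lambda_act, "/d,",
      x$movie_days, "days", if (!is.na(x$ly_start))
        paste0("(LY from day ", x$ly_start, ")"), "\n")
  invisible(x)
}

#' Switch a parameter set to Notch-blockade (LY411575) mode
#'
#' From `start_day` onward, deltaA-negative and deltaA-positive NSCs share a
#' single elevated division hazard (`ly_rate`); the area coupling (if any)
#' and all fate rules at division are unchanged, matching the observation
#' that Notch blockade equalizes activation rates between statuses without
#' touching the asymmetric division fate of deltaA-negative mothers.
#'
#' @param params a [sim_params()] object.
#' @param start_day day at which blockade begins (default 0, i.e. the whole
#'   movie).
#' @return The modified `sim_params`.
#' @export
apply_ly <- function(params, start_day = 0) {
  stopifnot(inherits(params, "sim_params"))
  if (start_day < 0 || start_day >= params$movie_days)
    stop("ly start_day must lie within the movie", call. = FALSE)
  params$ly_start <- start_day
  params
}

# imaging grid: day 0, then gaps cycled until movie_days is reached
imaging_days <- function(params) {
  days <- 0
  i <- 0L
  repeat {
    g <- params$imaging_gaps[i %% length(params$imaging_gaps) + 1L]
    nxt <- days[length(days)] + g
    if (nxt > params$movie_days + 1e-9) break
    days <- c(days, nxt)
    i <- i + 1L
  }
  days
}

# lognormal with given mean and sd on the natural scale; retries guard the
# positivity contract for degenerate parameterizations
draw_area <- function(n, mean_sd, retries = 10L) {
  m <- mean_sd[1]
  s <- mean_sd[2]
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  for (k in seq_len(retries)) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    if (all(x > 0)) return(x)
  }
  stop("could not draw positive areas", call. = FALSE)
}

#' Simulate a cohort of NSC tracks
#'
#' Runs the stochastic lineage-progression model on the imaging grid and
#' returns a validated [lineage_forest()] carrying a ground-truth event log
#' (attribute `"truth"`): every division with its latent activation-onset
#' and cytokinesis times, every delamination, every spontaneous deltaA
#' switch, and the per-daughter requiescence/re-division decisions. The log
#' lets downstream annotation be tested against exact generator truth.
#'
#' Dynamics per cell and per imaging interval: a quiescent cell activates
#' with probability `1 - exp(-hazard * gap)` where the hazard is the
#' status-specific base rate, optionally modulated by apical area through a
#' logistic factor; once activated the proliferation marker is visible from
#' the next imaging day after onset and cytokinesis follows after an
#' exponential (`lambda_act`) delay; the division is recorded at the first
#' imaging day after cytokinesis, the mother's last point carrying the
#' division event and the two daughters (areas summing exactly to the
#' mother's, imbalance set by `division_asym_noise`) starting at the next
#' time point. deltaA fate rules: negative mothers yield one permanently
#' negative and one positive daughter (ON at DC with probability
#' `fate_on_at_DC_prob`, else at DC+1); positive mothers yield two positive
#' daughters with distinct scores, a configurable fraction of which convert
#' to ON/OFF after an exponential lag. Quiescent areas grow exponentially at
#' the status growth rate; deltaA-positive cells below the delamination
#' threshold delaminate with hazard `delam_rate`; nondividing root tracks
#' switch deltaA at the configured per-movie rates. Under LY
#' ([apply_ly()]), from `ly_start` both statuses share the `ly_rate`
#' division hazard (cytokinesis drawn directly, marker onset back-dated by
#' an exponential `lambda_act` delay), since that calibration constant is an
#' observed division rate over a short window.
#'
#' Identical `(params, n_tracks, seed)` give identical forests.
#'
#' @param params a [sim_params()] object.
#' @param n_tracks number of initial (root) tracks; daughters add tracks.
#' @param seed integer RNG seed.
#' @return A `lineage_forest` with attribute `"truth"`.
#' @export
simulate_cohort <- function(params, n_tracks, seed) {
  stopifnot(inherits(params, "sim_params"), n_tracks >= 1)
  set.seed(seed)
  days <- imaging_days(params)
  n_tp <- length(days)
  n_int <- n_tp - 1L
  treatment <- if (!is.na(params$ly_start)) "LY" else "control"

  # per-interval probability of a spontaneous deltaA switch in nondividers
  p_sw_on <- params$switch_on_rate / n_int
  p_sw_off <- params$switch_off_rate / n_int

  rows <- vector("list", 4L * n_tracks)
  n_rows <- 0L
  push_rows <- function(df) {
    n_rows <<- n_rows + 1L
    if (n_rows > length(rows)) rows[[2L * n_rows]] <<- NULL
    rows[[n_rows]] <<- df
  }
  log_div <- list(); log_del <- list(); log_sw <- list()
  log_act <- list(); log_dau <- list()

  # seed cells
  queue <- vector("list", 2L * n_tracks)
  q_head <- 1L; q_tail <- 0L
  push_cell <- function(cell) {
    q_tail <<- q_tail + 1L
    if (q_tail > length(queue)) queue[[2L * q_tail]] <<- NULL
    queue[[q_tail]] <<- cell
  }
  for (i in seq_len(n_tracks)) {
    u <- stats::runif(1)
    if (u < params$frac_initial_np) {
      area <- draw_area(1, params$area_init$aNP)
      score <- sample(2:3, 1)
    } else if (u < params$frac_initial_np +
               (1 - params$frac_initial_np) * params$frac_initial_pos) {
      area <- draw_area(1, params$area_init$qNSC_pos)
      score <- sample(1:3, 1)
    } else {
      area <- draw_area(1, params$area_init$qNSC_neg)
      score <- 0L
    }
    push_cell(list(id = sprintf("T%04d", i),
                   parent = NA_character_,
                   fish = paste0("F", 1L + (i - 1L) %% params$n_fish),
                   born_tp = 1L, area = area, score = score,
                   score_next = NA_integer_, off_day = NA_real_,
                   perm_neg = (score == 0L), root = TRUE,
                   reiterative = FALSE))
  }

  ly_on <- function(d) !is.na(params$ly_start) && d >= params$ly_start - 1e-9

  area_factor <- function(area, pos) {
    if (params$area_coupling == 0) return(1)
    ref <- if (pos) params$area_ref[["pos"]] else params$area_ref[["neg"]]
    2 * stats::plogis(params$area_coupling * (area - ref))
  }

  while (q_head <= q_tail) {
    cell <- queue[[q_head]]; q_head <- q_head + 1L
    id <- cell$id
    area <- cell$area
    score <- cell$score
    score_next <- cell$score_next
    off_day <- cell$off_day
    phase <- "q"
    onset_time <- NA_real_; onset_day <- NA_real_; cyto_time <- NA_real_
    if (cell$reiterative) {
      phase <- "a"
      onset_time <- days[cell$born_tp]
      onset_day <- days[cell$born_tp]
      cyto_time <- onset_time + stats::rexp(1, params$lambda_act)
    }
    tp_seq <- cell$born_tp:n_tp
    rec <- list(tp = integer(0), day = numeric(0), area = numeric(0),
                score = integer(0), marker = logical(0))
    ended <- FALSE; end_event <- "none"
    divided_here <- FALSE
    for (ti in tp_seq) {
      d <- days[ti]
      # scheduled score changes (score_next takes effect one tp after birth)
      if (!is.na(score_next) && ti > cell$born_tp) {
        score <- score_next; score_next <- NA_integer_
      }
      if (!is.na(off_day) && d >= off_day - 1e-9) {
        score <- 0L; off_day <- NA_real_
      }
      marker <- !is.na(onset_day) && d >= onset_day - 1e-9
      rec$tp <- c(rec$tp, ti - 1L)
      rec$day <- c(rec$day, d)
      a_obs <- if (params$meas_noise_sd > 0)
        area * exp(stats::rnorm(1, 0, params$meas_noise_sd)) else area
      rec$area <- c(rec$area, a_obs)
      rec$score <- c(rec$score, score)
      rec$marker <- c(rec$marker, marker)

      last_tp <- ti == n_tp
      gap <- if (!last_tp) days[ti + 1L] - d else NA_real_

      # division at the next imaging day?
      if (phase == "a" && !last_tp && cyto_time <= days[ti + 1L] + 1e-9) {
        end_event <- "division"; ended <- TRUE; divided_here <- TRUE
        mc_tp <- ti; break
      }
      if (last_tp) break

      # delamination once small (deltaA-positive by default)
      can_delam <- area < params$delam_area_threshold &&
        (!params$delam_requires_pos || score >= 1L)
      if (can_delam && phase == "q" &&
          stats::runif(1) < 1 - exp(-params$delam_rate * gap)) {
        end_event <- "delamination"; ended <- TRUE; break
      }

      if (phase == "q") {
        if (ly_on(d)) {
          haz <- params$ly_rate * area_factor(area, score >= 1L)
          if (stats::runif(1) < 1 - exp(-haz * gap)) {
            cyto_time <- stats::runif(1, d, days[ti + 1L])
            onset_time <- max(days[cell$born_tp],
                              cyto_time - stats::rexp(1, params$lambda_act))
            onset_day <- days[which(days >= onset_time - 1e-9)[1L]]
            phase <- "a"
            if (cyto_time <= days[ti + 1L] + 1e-9) {
              end_event <- "division"; ended <- TRUE
              divided_here <- TRUE; mc_tp <- ti
              break
            }
          }
        } else {
          pos <- score >= 1L
          base <- if (pos) params$gamma_pos else params$gamma_neg
          haz <- base * area_factor(area, pos)
          if (haz > 0 && stats::runif(1) < 1 - exp(-haz * gap)) {
            onset_time <- stats::runif(1, d, days[ti + 1L])
            onset_day <- days[ti + 1L]
            cyto_time <- onset_time + stats::rexp(1, params$lambda_act)
            phase <- "a"
            if (cyto_time <= days[ti + 1L] + 1e-9) {
              # cytokinesis within the same imaging interval: the mother is
              # last seen here and the daughters appear at the next tp
              end_event <- "division"; ended <- TRUE
              divided_here <- TRUE; mc_tp <- ti
              break
            }
          }
        }
        if (phase == "q" && cell$root) {
          # rare spontaneous switches in nondividing quiescent roots
          if (score == 0L && stats::runif(1) < p_sw_on) {
            score_next <- 2L
            log_sw[[length(log_sw) + 1L]] <-
              data.frame(track_id = id, tp = ti, day = days[ti + 1L],
                         direction = "on")
          } else if (score >= 1L && stats::runif(1) < p_sw_off) {
            score_next <- 0L
            log_sw[[length(log_sw) + 1L]] <-
              data.frame(track_id = id, tp = ti, day = days[ti + 1L],
                         direction = "off")
          }
        }
        if (phase == "q") {
          g <- if (score >= 1L) params$growth_pos else params$growth_neg
          if (g != 0) area <- area * exp(g * gap)
        }
      }
    }

    n_rec <- length(rec$tp)
    events <- rep("none", n_rec)
    if (ended) events[n_rec] <- end_event
    push_rows(data.frame(
      fish_id = cell$fish, treatment = treatment, track_id = id,
      parent_id = cell$parent, tp_index = rec$tp, day = rec$day,
      area_um2 = rec$area, delta_score = rec$score, marker_on = rec$marker,
      event = events, stringsAsFactors = FALSE))

    if (!is.na(onset_time)) {
      log_act[[length(log_act) + 1L]] <- data.frame(
        track_id = id, onset_time = onset_time, onset_day = onset_day,
        cyto_time = cyto_time, divided = divided_here)
    }
    if (end_event == "delamination") {
      log_del[[length(log_del) + 1L]] <- data.frame(
        track_id = id, tp = rec$tp[n_rec], day = rec$day[n_rec],
        area_true = area, score = score)
    }

    if (divided_here) {
      dc_tp <- mc_tp + 1L
      d_dc <- days[dc_tp]
      f <- 0.5 + stats::rnorm(1, 0, params$division_asym_noise)
      f <- min(max(f, 0.05), 0.95)
      a1 <- f * area; a2 <- (1 - f) * area
      mother_pos <- score >= 1L
      mk_id <- function(k) paste0(id, ".", k)
      if (!mother_pos) {
        s_on <- sample(1:3, 1, prob = c(0.45, 0.35, 0.2))
        on_at_dc <- stats::runif(1) < params$fate_on_at_DC_prob
        pos_small <- stats::runif(1) < params$smaller_gets_pos_prob
        a_small <- min(a1, a2); a_large <- max(a1, a2)
        a_pos <- if (pos_small) a_small else a_large
        a_neg <- area - a_pos
        requi <- stats::runif(1) < params$requiescence_prob_pos
        dau <- list(
          list(id = mk_id(1), area = a_neg, score = 0L,
               score_next = NA_integer_, off_day = NA_real_,
               perm_neg = TRUE, reiterative = FALSE),
          list(id = mk_id(2), area = a_pos,
               score = if (on_at_dc) s_on else 0L,
               score_next = if (on_at_dc) NA_integer_ else s_on,
               off_day = NA_real_, perm_neg = FALSE,
               reiterative = !requi))
        truth_mode <- "neg_pos"
      } else {
        ss <- sample(1:3, 2, replace = FALSE)
        pos_small <- stats::runif(1) < params$smaller_gets_pos_prob
        hi <- max(ss); lo <- min(ss)
        a_small <- min(a1, a2); a_large <- max(a1, a2)
        a_hi <- if (pos_small) a_small else a_large
        a_lo <- area - a_hi
        becomes_binary <- stats::runif(1) < params$pospos_binary_frac
        off_at <- if (becomes_binary)
          d_dc + stats::rexp(1, 1 / params$pospos_binary_lag_mean)
        else NA_real_
        dau <- list(
          list(id = mk_id(1), area = a_hi, score = hi,
               score_next = NA_integer_, off_day = NA_real_,
               perm_neg = FALSE,
               reiterative = stats::runif(1) >= params$requiescence_prob_pos),
          list(id = mk_id(2), area = a_lo, score = lo,
               score_next = NA_integer_, off_day = off_at,
               perm_neg = FALSE,
               reiterative = stats::runif(1) >= params$requiescence_prob_pos))
        truth_mode <- "pos_pos"
      }
      for (dd in dau) {
        push_cell(list(id = dd$id, parent = id, fish = cell$fish,
                       born_tp = dc_tp, area = dd$area, score = dd$score,
                       score_next = dd$score_next, off_day = dd$off_day,
                       perm_neg = dd$perm_neg, root = FALSE,
                       reiterative = dd$reiterative))
        log_dau[[length(log_dau) + 1L]] <- data.frame(
          track_id = dd$id, mother = id, born_tp = dc_tp - 1L,
          born_area = dd$area, reiterative = dd$reiterative)
      }
      log_div[[length(log_div) + 1L]] <- data.frame(
        mother_track = id, daughter1 = dau[[1]]$id, daughter2 = dau[[2]]$id,
        mc_tp = mc_tp - 1L, division_tp = dc_tp - 1L,
        mc_day = days[mc_tp], division_day = d_dc,
        mother_area_true = area, mother_pos = mother_pos,
        n_quiet_intervals = mc_tp - cell$born_tp,
        onset_time = onset_time, onset_day = onset_day,
        cyto_time = cyto_time,
        duration_truth = d_dc - onset_time,
        eventual_mode = truth_mode,
        d1_score_dc = dau[[1]]$score,
        d1_score_next = dau[[1]]$score_next,
        d1_off_day = dau[[1]]$off_day,
        d2_score_dc = dau[[2]]$score,
        d2_score_next = dau[[2]]$score_next,
        d2_off_day = dau[[2]]$off_day)
    }
  }

  points <- do.call(rbind, rows[seq_len(n_rows)])
  forest <- lineage_forest(points, allowed_gaps = unique(params$imaging_gaps),
                           validate = FALSE)
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  attr(forest, "truth") <- list(
    divisions = bind(log_div), delaminations = bind(log_del),
    switches = bind(log_sw), activations = bind(log_act),
    daughters = bind(log_dau), imaging_days = days, params = params,
    seed = seed)
  forest
}

#' Simulate a static tissue snapshot
#'
#' Draws a fixed-tissue-like cell table: states from the configured mixture,
#' apical areas from state-specific lognormals (means/SDs matching the
#' fixed-tissue quantifications: qNSC 84 +/- 8.9 um^2, aNSC singlets 54 +/-
#' 17.1, aNPs 10 +/- 3.6) and deltaA positivity from per-state fractions
#' (23% / 87% / 99%). Per-state area means, SDs and deltaA fractions
#' converge to the configured values as `n_cells` grows.
#'
#' @param params a [sim_params()] object.
#' @param n_cells number of cells.
#' @param seed integer RNG seed.
#' @param n_hemispheres hemispheres to distribute cells over.
#' @return data.frame with columns `hemisphere_id`, `cell_id`, `state`,
#'   `area_um2`, `delta_positive`.
#' @export
simulate_snapshot <- function(params, n_cells, seed, n_hemispheres = 4L) {
  stopifnot(inherits(params, "sim_params"), n_cells >= 1)
  set.seed(seed)
  states <- sample(names(params$state_mix), n_cells, replace = TRUE,
                   prob = params$state_mix)
  area <- numeric(n_cells)
  delta <- logical(n_cells)
  for (st in unique(states)) {
    idx <- which(states == st)
    area[idx] <- draw_area(length(idx), params$area_init[[st]])
    delta[idx] <- stats::runif(length(idx)) < params$delta_frac[[st]]
  }
  data.frame(
    hemisphere_id = paste0("H", 1L + (seq_len(n_cells) - 1L) %% n_hemispheres),
    cell_id = sprintf("C%05d", seq_len(n_cells)),
    state = states, area_um2 = area, delta_positive = delta,
    stringsAsFactors = FALSE)
}

#' Simulate interval-censored activation-to-cytokinesis durations
#'
#' Draws exponential durations at a known rate and censors them the way the
#' imaging grid censors marker-onset times: the onset falls uniformly on a
#' long grid of imaging days (gaps cycled from `gaps`), the marker is first
#' seen ON at the next imaging day and last seen OFF at the previous one,
#' while the division time is taken as exactly observed. Each duration
#' therefore becomes the interval `[max(0, c - t_on), c - t_off]` around the
#' true value, which always contains it. Durations still running at
#' `censor_at` days after onset are right-censored.
#'
#' @param n number of durations.
#' @param rate true exponential rate, per day.
#' @param gaps imaging-day gaps, cycled.
#' @param seed optional integer seed.
#' @param censor_at right-censoring horizon in days after marker onset
#'   (default `Inf`, no censoring).
#' @return data.frame with columns `lower`, `upper` (possibly `Inf`) and
#'   `truth` (the latent duration).
#' @export
simulate_durations <- function(n, rate = 0.326, gaps = c(2, 3),
                               seed = NULL, censor_at = Inf) {
  stopifnot(n >= 1, rate > 0)
  if (!is.null(seed)) set.seed(seed)
  span <- 1000
  grid <- cumsum(c(0, rep_len(gaps, ceiling(span / min(gaps)) + 5L)))
  o <- stats::runif(n, grid[2L], span)
  truth <- stats::rexp(n, rate)
  t_on <- grid[findInterval(o, grid, left.open = TRUE) + 1L]
  t_off <- grid[findInterval(o, grid, left.open = TRUE)]
  cc <- o + truth
  lower <- pmax(0, cc - t_on)
  upper <- cc - t_off
  cens <- truth > censor_at
  if (any(cens)) {
    lower[cens] <- pmax(0, o[cens] + censor_at - t_on[cens])
    upper[cens] <- Inf
  }
  data.frame(lower = lower, upper = upper, truth = truth)
}
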