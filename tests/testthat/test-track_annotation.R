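test_that("detected divisions equal the generator's event log exactly", {
  f <- simulate_cohort(quiet_params(), 400L, seed = 17L)
  tr <- attr(f, "truth")$divisions
  ev <- detect_divisions(f)
  expect_equal(nrow(ev), nrow(tr))
  tr <- tr[order(tr$mother_track), ]
  expect_equal(ev$mother_track, tr$mother_track)
  expect_equal(ev$division_tp, tr$division_tp)
  expect_equal(ev$mc_tp, tr$mc_tp)
  expect_equal(ev$division_day, tr$division_day)
  expect_equal(ev$mother_status, tr$mother_pos)
  expect_equal(ev$mother_area, tr$mother_area_true, tolerance = 1e-12)
  expect_equal(ev$from_quiescence, tr$n_quiet_intervals >= 2L)
})

test_that("from-quiescence flag follows the two-quiet-interval rule", {
  fix <- fixture_suite(seed = 42L)
  ev <- detect_divisions(fix$hand)
  expect_true(ev$from_quiescence[ev$mother_track == "M1"])
  expect_false(ev$from_quiescence[ev$mother_track == "E1"])
  # one quiet interval suffices if the threshold is lowered
  ev1 <- detect_divisions(fix$hand, min_quiet_intervals = 1L)
  expect_true(ev1$from_quiescence[ev1$mother_track == "E1"])
})

test_that("division detection is invariant to row order", {
  f <- simulate_cohort(sim_params(), 120L, seed = 23L)
  shuffled <- f$points[sample(nrow(f$points)), ]
  f2 <- lineage_forest(shuffled, allowed_gaps = c(2, 3))
  expect_equal(nrow(detect_divisions(f2)), nrow(detect_divisions(f)))
})

test_that("division modes map daughter status pairs, order-insensitively", {
  mk <- function(d1, d2) {
    f <- lineage_forest(simple_division_points(d1_scores = d1,
                                               d2_scores = d2))
    ev <- detect_divisions(f)
    classify_division_mode(ev, f, horizon = 1L)$mode
  }
  expect_equal(mk(c(0L, 0L), c(2L, 2L)), "neg_pos")
  expect_equal(mk(c(2L, 2L), c(0L, 0L)), "neg_pos")  # daughter exchange
  expect_equal(mk(c(1L, 1L), c(3L, 3L)), "pos_pos")
  expect_equal(mk(c(0L, 0L), c(0L, 0L)), "neg_neg")
  # horizon beyond the daughters' tracks, and missing score at horizon
  expect_equal(mk(c(0L, 0L), c(2L, 2L))[1L], "neg_pos")
  f <- lineage_forest(simple_division_points(d2_scores = c(2L, NA)))
  ev <- detect_divisions(f)
  expect_equal(classify_division_mode(ev, f, 1L)$mode, "unclassifiable")
  expect_equal(classify_division_mode(ev, f, 5L)$mode, "unclassifiable")
  expect_equal(classify_division_mode(ev, f, 5L,
                                      allow_last_observation = TRUE)$mode,
               "neg_pos")
})

test_that("modes on simulator output match the generator's fate schedule", {
  f <- simulate_cohort(quiet_params(), 400L, seed = 17L)
  tr <- attr(f, "truth")$divisions
  ev <- detect_divisions(f)
  score_at <- function(dc, nxt, off_day, h, day_h) {
    s <- if (h == 0L || is.na(nxt)) dc else nxt
    if (!is.na(off_day) && day_h >= off_day - 1e-9) s <- 0L
    s
  }
  for (h in c(0L, 1L, 4L)) {
    modes <- classify_division_mode(ev, f, h)
    for (i in seq_len(nrow(ev))) {
      dv <- tr[tr$mother_track == ev$mother_track[i], ]
      d1 <- get_track(f, dv$daughter1)
      tp_h <- dv$division_tp + h
      if (!(tp_h %in% d1$tp_index) ||
          !(tp_h %in% get_track(f, dv$daughter2)$tp_index)) {
        expect_equal(modes$mode[i], "unclassifiable")
        next
      }
      day_h <- d1$day[d1$tp_index == tp_h]
      s1 <- score_at(dv$d1_score_dc, dv$d1_score_next, dv$d1_off_day, h, day_h)
      s2 <- score_at(dv$d2_score_dc, dv$d2_score_next, dv$d2_off_day, h, day_h)
      expected <- c("neg_neg", "neg_pos", "pos_pos")[(s1 >= 1) + (s2 >= 1) + 1]
      expect_equal(modes$mode[i], expected)
    }
  }
})

test_that("negative mothers divide asymmetrically at every late horizon", {
  f <- simulate_cohort(sim_params(), 828L, seed = 1L)
  ev <- detect_divisions(f)
  negm <- ev[!ev$mother_status & ev$from_quiescence, ]
  m4 <- classify_division_mode(negm, f, 4L)$mode
  classifiable <- m4[m4 != "unclassifiable"]
  expect_gte(length(classifiable), 27)
  expect_true(all(classifiable == "neg_pos"))
})

test_that("deltaA trajectories classify status-change patterns", {
  mk_track <- function(scores) {
    data.frame(delta_score = scores)
  }
  expect_equal(classify_delta_trajectory(mk_track(c(0L, 0L, 0L))),
               "always_off")
  expect_equal(classify_delta_trajectory(mk_track(c(2L, 3L, 1L))),
               "always_on")
  expect_equal(classify_delta_trajectory(mk_track(c(0L, 0L, 2L, 3L))),
               "switch_on")
  expect_equal(classify_delta_trajectory(mk_track(c(2L, 0L, 0L))),
               "switch_off")
  expect_equal(classify_delta_trajectory(mk_track(c(2L, 0L, 1L))), "mixed")
  expect_equal(classify_delta_trajectory(mk_track(c(NA, 2L, NA))),
               "always_on")
  expect_error(classify_delta_trajectory(mk_track(c(NA, NA))),
               "no scored")
})

test_that("pair asymmetry uses the larger daughter, inclusively", {
  expect_true(pair_area_asymmetry(50, 40))   # exactly 20%
  expect_false(pair_area_asymmetry(50, 50))
  expect_true(pair_area_asymmetry(40, 50))
  expect_error(pair_area_asymmetry(-1, 50), "positive")
  # brute-force agreement over a grid of pairs
  grid <- expand.grid(a1 = seq(5, 150, length.out = 32),
                      a2 = seq(5, 150, length.out = 32))
  direct <- abs(grid$a1 - grid$a2) / pmax(grid$a1, grid$a2) >= 0.2
  expect_equal(pair_area_asymmetry(grid$a1, grid$a2), direct)
  # the default division imbalance makes ~60% of pairs asymmetric
  set.seed(99)
  fr <- pmin(pmax(0.5 + rnorm(20000, 0, 0.106), 0.05), 0.95)
  expect_lt(abs(mean(pair_area_asymmetry(fr, 1 - fr)) - 0.60), 0.02)
})

test_that("delaminations are small deltaA-positive cells", {
  f0 <- simulate_cohort(quiet_params(gamma_neg = 0, gamma_pos = 0,
                                     frac_initial_np = 0, delam_rate = 0),
                        30L, seed = 2L)
  expect_equal(nrow(detect_delaminations(f0)), 0L)
  f <- simulate_cohort(sim_params(), 828L, seed = 1L)
  del <- detect_delaminations(f)
  expect_gt(nrow(del), 50)
  expect_true(all(del$last_status))
  # in vivo the delaminating median is ~8 um^2; the simulated pool sits
  # below the 10 um^2 threshold, with division-chain daughters pulling the
  # median a little lower
  expect_gt(median(del$last_area), 5)
  expect_lt(median(del$last_area), 10)
})

test_that("post-division outcomes follow the first-event rule", {
  fix <- fixture_suite(seed = 42L)
  ev <- detect_divisions(fix$hand)
  out <- post_division_outcome(ev, fix$hand)
  get <- function(d) out$outcome[out$daughter == d]
  expect_equal(get("M1.1"), "requiescence")
  expect_equal(get("M1.2"), "delamination")
  expect_equal(get("E1.1"), "censored")   # tracked 2 d, no event
  expect_equal(get("E1.2"), "censored")   # single point
  # a daughter that divides again is reiterative
  pts <- rbind(
    simple_division_points(),
    data.frame(fish_id = "F1", treatment = "control", track_id = "D1.1",
               parent_id = "D1", tp_index = 5L, day = 12,
               area_um2 = 25, delta_score = 0L, marker_on = FALSE,
               event = "none"),
    data.frame(fish_id = "F1", treatment = "control", track_id = "D1.2",
               parent_id = "D1", tp_index = 5L, day = 12,
               area_um2 = 26, delta_score = 2L, marker_on = FALSE,
               event = "none"))
  pts$event[pts$track_id == "D1" & pts$tp_index == 4L] <- "division"
  f2 <- lineage_forest(pts)
  ev2 <- detect_divisions(f2)
  out2 <- post_division_outcome(ev2, f2)
  expect_equal(out2$outcome[out2$daughter == "D1"], "reiterative_division")
})

test_that("the generator draws requiescence at the configured proportion", {
  f <- simulate_cohort(sim_params(), 828L, seed = 1L)
  dau <- attr(f, "truth")$daughters
  dv <- attr(f, "truth")$divisions
  pos_d <- c(dv$daughter2[dv$eventual_mode == "neg_pos"],
             dv$daughter1[dv$eventual_mode == "pos_pos"],
             dv$daughter2[dv$eventual_mode == "pos_pos"])
  requi <- !dau$reiterative[dau$track_id %in% pos_d]
  p0 <- 223 / 250
  se <- sqrt(p0 * (1 - p0) / length(requi))
  expect_lt(abs(mean(requi) - p0), 4 * se)
})
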