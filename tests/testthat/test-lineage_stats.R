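test_that("doubling times invert per-day rates", {
  expect_equal(round(doubling_time(5.587e-3)), 124)
  expect_equal(round(doubling_time(2.460e-2)), 28)
  expect_equal(doubling_time(log(2)), 1)
  expect_error(doubling_time(0), "positive")
  # mutual inverse
  for (r in c(0.001, 0.05, 1.3)) {
    expect_equal(log(2) / doubling_time(r), r)
  }
})

test_that("division likelihood is the exposure-normalized Poisson rate", {
  ly <- division_likelihood(89, 261, 4)
  expect_equal(round(ly$rate, 4), 0.0852)
  expect_true(ly$ci_low < ly$rate && ly$rate < ly$ci_high)
  ctrl <- division_likelihood(125, 844, 35)
  expect_equal(round(ctrl$rate, 4), 0.0042)
  # pooling invariance: splitting the cohort and pooling counts is a no-op
  pooled <- division_likelihood(40 + 49, 261, 4)
  expect_equal(pooled$rate, ly$rate)
  split_sum <- (40 + 49) / (261 * 4)
  expect_equal(pooled$rate, split_sum)
  zero <- division_likelihood(0, 100, 10)
  expect_equal(zero$rate, 0)
  expect_equal(zero$ci_low, 0)
  expect_gt(zero$ci_high, 0)
  expect_error(division_likelihood(-1, 10, 10), "negative")
})

test_that("normalized growth recovers flat and exponential laws", {
  p0 <- quiet_params(gamma_neg = 0, gamma_pos = 0, growth_neg = 0,
                     frac_initial_np = 0, frac_initial_pos = 0,
                     delam_rate = 0)
  f0 <- simulate_cohort(p0, 40L, seed = 4L)
  set.seed(1)
  g0 <- normalized_growth(f0, "neg", n_boot = 100L)
  expect_true(all(abs(g0$median_normalized_area - 1) < 1e-12))
  expect_lt(abs(g0$fitted_rate$rate), 1e-12)
  expect_equal(g0$median_normalized_area[1L], 1)

  r <- 0.01
  p1 <- quiet_params(gamma_neg = 0, gamma_pos = 0, growth_neg = r,
                     frac_initial_np = 0, frac_initial_pos = 0,
                     delam_rate = 0)
  f1 <- simulate_cohort(p1, 40L, seed = 4L)
  set.seed(1)
  g1 <- normalized_growth(f1, "neg", n_boot = 100L)
  expect_equal(g1$fitted_rate$rate, r, tolerance = 1e-8)
  expect_error(normalized_growth(f1, "pos", n_boot = 10L), "no nondividing")
})

test_that("bootstrap CIs widen as the track sample shrinks", {
  p <- quiet_params(gamma_neg = 0, gamma_pos = 0, frac_initial_np = 0,
                    frac_initial_pos = 0, delam_rate = 0,
                    meas_noise_sd = 0.05)
  f <- simulate_cohort(p, 120L, seed = 8L)
  width_at_end <- function(forest, keep_n, seed) {
    set.seed(seed)
    keep <- sample(track_ids(forest), keep_n)
    sub <- lineage_forest(
      forest$points[forest$points$track_id %in% keep, ],
      allowed_gaps = c(2, 3), validate = FALSE)
    set.seed(seed)
    g <- normalized_growth(sub, "neg", n_boot = 300L)
    k <- length(g$day_bins)
    g$ci_high[k] - g$ci_low[k]
  }
  expect_lt(width_at_end(f, 120L, 7), width_at_end(f, 25L, 7))
})

test_that("area conservation holds exactly without noise and degrades with it", {
  f <- simulate_cohort(quiet_params(), 300L, seed = 3L)
  ev <- detect_divisions(f, min_quiet_intervals = 0L)
  ac <- area_conservation(ev, f)
  expect_gt(nrow(ac$ratios), 20)
  expect_true(all(abs(ac$ratios$ratio - 1) < 1e-12))
  expect_equal(ac$median, 1)

  sdev <- function(noise) {
    fz <- simulate_cohort(quiet_params(meas_noise_sd = noise), 300L,
                          seed = 3L)
    evz <- detect_divisions(fz, min_quiet_intervals = 0L)
    stats::sd(area_conservation(evz, fz)$ratios$ratio)
  }
  expect_lt(sdev(0.02), sdev(0.10))

  # the printed medians: two 45 um^2 daughters of a 102 um^2 mother
  expect_equal(round((45 + 45) / 102, 3), 0.882)
})

test_that("Mann-Whitney comparisons match brute-force enumeration", {
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1
  cells <- data.frame(
    hemisphere_id = "H1", cell_id = sprintf("C%02d", 1:6),
    state = rep(c("qNSC", "aNP"), each = 3),
    area_um2 = c(1, 2, 3, 4, 5, 6),
    delta_positive = FALSE)
  s <- snapshot_summary(cells)
  row <- s$tests[1, ]
  expect_true(row$exact)
  expect_equal(min(row$U, 9 - row$U), 0)
  expect_equal(row$p, 0.1)
  # independent oracle: enumerate all 20 assignments of ranks to group 1
  vals <- 1:6
  combos <- combn(6, 3)
  u_null <- apply(combos, 2, function(ix) {
    r <- rank(vals)
    sum(r[ix]) - 3 * 4 / 2
  })
  p_exact <- 2 * min(mean(u_null <= row$U), mean(u_null >= row$U))
  expect_equal(row$p, p_exact)

  # identical groups: p ~ 1 under the tie-corrected approximation
  same <- data.frame(
    hemisphere_id = "H1", cell_id = sprintf("C%02d", 1:40),
    state = rep(c("qNSC", "aNP"), each = 20),
    area_um2 = rep(c(5, 6, 7, 8), 10), delta_positive = FALSE)
  s2 <- snapshot_summary(same)
  expect_gt(s2$tests$p[1], 0.95)
  expect_false(s2$tests$exact[1])

  # simulated snapshot at the fixed-tissue defaults: qNSC vs aNSC areas
  # differ strongly
  snap <- simulate_snapshot(sim_params(), 4000L, seed = 12L)
  s3 <- snapshot_summary(snap)
  qa <- s3$tests[s3$tests$group1 %in% c("aNSC_singlet", "qNSC") &
                   s3$tests$group2 %in% c("aNSC_singlet", "qNSC"), ]
  expect_lt(qa$p, 1e-4)
  expect_error(snapshot_summary(cells[cells$state == "qNSC", ]),
               "two nonempty groups")
})

test_that("per-fish division frequencies recover generator rates", {
  f <- simulate_cohort(sim_params(), 400L, seed = 33L)
  freq <- division_frequency_per_track(f)
  expect_equal(sum(freq$per_fish$n_tracks), length(track_ids(f)))
  expect_true(freq$mean_percent > 0 && freq$mean_percent < 100)
  expect_gte(freq$sem_percent, 0)
  # positive tracks divide far more often than negative ones
  fp <- division_frequency_per_track(f, status = "pos")
  fn <- division_frequency_per_track(f, status = "neg")
  expect_gt(fp$mean_percent, fn$mean_percent)
  # no divisions anywhere -> 0% +/- 0
  p0 <- quiet_params(gamma_neg = 0, gamma_pos = 0, frac_initial_np = 0,
                     delam_rate = 0)
  f0 <- simulate_cohort(p0, 40L, seed = 2L)
  freq0 <- division_frequency_per_track(f0)
  expect_equal(freq0$mean_percent, 0)
  expect_equal(freq0$sem_percent, 0)
  # printed per-status frequencies: positive cells divide ~5.5x more often
  expect_equal(round(34.2 / 6.2, 1), 5.5)
})
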