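test_that("the regression table records pre-division and average covariates", {
  pts <- rbind(
    data.frame(fish_id = "F1", treatment = "control", track_id = "DIV",
               parent_id = NA, tp_index = 0:2, day = c(0, 2, 5),
               area_um2 = c(100, 90, 80), delta_score = c(0L, 0L, 2L),
               marker_on = FALSE, event = c("none", "none", "division")),
    data.frame(fish_id = "F1", treatment = "control", track_id = "DIV.1",
               parent_id = "DIV", tp_index = 3L, day = 7, area_um2 = 40,
               delta_score = 0L, marker_on = FALSE, event = "none"),
    data.frame(fish_id = "F1", treatment = "control", track_id = "DIV.2",
               parent_id = "DIV", tp_index = 3L, day = 7, area_um2 = 40,
               delta_score = 2L, marker_on = FALSE, event = "none"),
    data.frame(fish_id = "F1", treatment = "control", track_id = "ND",
               parent_id = NA, tp_index = 0:2, day = c(0, 2, 5),
               area_um2 = c(100, 110, 120), delta_score = c(0L, 0L, 1L),
               marker_on = FALSE, event = "none"))
  f <- lineage_forest(pts)
  rows <- build_regression_table(f, min_quiet_intervals = 2L)
  div <- rows[rows$track_id == "DIV", ]
  expect_true(div$divided)
  expect_equal(div$area, 80)          # last pre-division tp
  expect_true(div$delta_pos)          # status at MC
  expect_equal(div$fate, "neg_pos")
  nd <- rows[rows$track_id == "ND", ]
  expect_false(nd$divided)
  expect_equal(nd$area, 110)          # mean over the study period
  expect_false(nd$delta_pos)          # most prevalent status
})

test_that("the 2x2 logistic fit matches the closed-form saturated MLE", {
  rows <- data.frame(
    divided = c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8)),
    delta_pos = rep(c(TRUE, FALSE), each = 10))
  fit <- fit_division_logistic(rows, divided ~ delta_pos)
  expect_equal(unname(fit$coefficients[1]), stats::qlogis(0.2),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[2]),
               stats::qlogis(0.8) - stats::qlogis(0.2), tolerance = 1e-6)
  expect_equal(round(unname(fit$coefficients[1]), 3), -1.386)
  expect_equal(round(unname(fit$coefficients[2]), 3), 2.773)
  expect_lte(fit$iter, 25)
  expect_true(fit$converged)
})

test_that("degenerate outcomes raise a separation error", {
  rows <- data.frame(divided = rep(FALSE, 20), delta_pos = rep(c(TRUE, FALSE), 10))
  expect_error(fit_division_logistic(rows, divided ~ delta_pos),
               "one class")
  set.seed(70)
  sep <- data.frame(divided = rep(c(TRUE, FALSE), each = 10),
                    area = c(rnorm(10, 100), rnorm(10, 20)))
  w <- capture_warnings(fit <- fit_division_logistic(sep, divided ~ area))
  expect_true(any(grepl("separation", w)))
  expect_true(fit$separation)
})

test_that("a known logistic law is recovered within its Wald CI", {
  set.seed(75)
  n <- 2000L
  area <- runif(n, 20, 150)
  beta <- 0.02
  p <- stats::plogis(-4 + beta * area)
  rows <- data.frame(divided = runif(n) < p, area = area)
  fit <- fit_division_logistic(rows, divided ~ area)
  b <- fit$coefficients["area"]
  se <- sqrt(fit$vcov["area", "area"])
  expect_lt(abs(b - beta), 1.96 * se)
  # predicted probability is monotone in area for a positive coefficient
  pr <- predict_division_prob(fit, seq(20, 150, by = 10), delta_pos = FALSE)
  expect_true(all(diff(pr$prob) > 0))
})

test_that("type II Wald tests respect marginality", {
  set.seed(72)
  n <- 600L
  rows <- data.frame(area = runif(n, 20, 150),
                     delta_pos = runif(n) < 0.4)
  rows$divided <- runif(n) < stats::plogis(-3 + 0.015 * rows$area +
                                             1.2 * rows$delta_pos)
  fit <- fit_division_logistic(rows, divided ~ area * delta_pos)
  # highest-order term: tested in the full model; 1-df identity chi2 = z^2
  w_int <- wald_type2(fit, "area:delta_pos")
  z <- fit$coefficients["area:delta_posTRUE"] /
    sqrt(fit$vcov["area:delta_posTRUE", "area:delta_posTRUE"])
  expect_equal(w_int$chisq, unname(z^2), tolerance = 1e-10)
  expect_equal(w_int$df, 1L)
  expect_equal(w_int$p, stats::pchisq(unname(z^2), 1, lower.tail = FALSE))
  # main effect: tested with its interaction removed
  w_area <- wald_type2(fit, "area")
  g <- stats::glm(divided ~ area + delta_pos, stats::binomial(), rows)
  z2 <- (stats::coef(g)["area"] / sqrt(stats::vcov(g)["area", "area"]))^2
  expect_equal(w_area$chisq, unname(z2), tolerance = 1e-10)
  expect_error(wald_type2(fit, "nope"), "not in design")
  # definitional check: z = 1.96 on 1 df gives chi2 = 3.84, p = 0.05
  expect_equal(stats::pchisq(1.96^2, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
})

test_that("window rescaling follows the memoryless law", {
  expect_equal(rescale_probability(0, 35, 4), 0)
  expect_equal(rescale_probability(0.3, 10, 10), 0.3)
  # p35 = 0.5 over 35 days maps to 0.0762 over 4 days
  expect_equal(rescale_probability(0.5, 35, 4), 0.0761604, tolerance = 1e-6)
  expect_equal(rescale_probability(0.5, 35, 4),
               1 - exp(4 / 35 * log(0.5)), tolerance = 1e-12)
  expect_warning(out <- rescale_probability(1, 35, 4), "degenerate")
  expect_equal(out, 1)
  expect_error(rescale_probability(1.2, 35, 4), "0, 1")
  # composition and identity laws
  set.seed(73)
  for (i in 1:25) {
    p <- runif(1)
    a <- runif(1, 1, 50); b <- runif(1, 1, 50); cc <- runif(1, 1, 50)
    expect_equal(rescale_probability(rescale_probability(p, a, b), b, cc),
                 rescale_probability(p, a, cc), tolerance = 1e-12)
    expect_equal(rescale_probability(p, a, a), p, tolerance = 1e-12)
  }
})

test_that("the intercept-only multinomial equals empirical proportions", {
  rows <- data.frame(
    fish_id = "F1",
    fate = c("neg_pos", "neg_pos", "pos_pos", "neg_neg"))
  fit <- fit_fate_multinomial(rows, ~ 1)
  expect_false(fit$degenerate)
  probs <- fit$fitted[1, c("neg_pos", "pos_pos", "neg_neg")]
  expect_equal(unname(probs), c(0.5, 0.25, 0.25), tolerance = 1e-6)
  # per-fish saturated identity
  set.seed(74)
  rows2 <- data.frame(
    fish_id = rep(c("F1", "F2", "F3"), times = c(30, 40, 25)))
  rows2$fate <- c(sample(c("neg_pos", "pos_pos", "neg_neg"), 30, TRUE,
                         c(0.6, 0.3, 0.1)),
                  sample(c("neg_pos", "pos_pos", "neg_neg"), 40, TRUE,
                         c(0.2, 0.5, 0.3)),
                  sample(c("neg_pos", "pos_pos", "neg_neg"), 25, TRUE,
                         c(0.4, 0.4, 0.2)))
  # ensure all categories occur in every fish for a finite saturated MLE
  rows2$fate[c(1, 31, 71)] <- "neg_pos"
  rows2$fate[c(2, 32, 72)] <- "pos_pos"
  rows2$fate[c(3, 33, 73)] <- "neg_neg"
  fit2 <- fit_fate_multinomial(rows2, ~ fish_id)
  by_fish <- fate_probs_by_fish(fit2)
  for (fsh in c("F1", "F2", "F3")) {
    emp <- prop.table(table(rows2$fate[rows2$fish_id == fsh]))
    got <- unlist(by_fish[by_fish$fish_id == fsh, names(emp)])
    expect_equal(unname(got), unname(as.numeric(emp)), tolerance = 1e-6)
  }
  # single-category input is reported as degenerate, not fitted
  fit3 <- fit_fate_multinomial(data.frame(fish_id = "F1",
                                          fate = rep("neg_pos", 5)))
  expect_true(fit3$degenerate)
  expect_equal(fit3$categories, "neg_pos")
})
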