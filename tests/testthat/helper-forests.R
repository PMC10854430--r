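# Shared fixtures, built in code.

# one mother (3 quiet points) dividing into two daughters
simple_division_points <- function(d1_scores = c(0L, 0L),
                                   d2_scores = c(2L, 2L),
                                   d1_area = c(50, 51),
                                   d2_area = c(52, 53)) {
  rbind(
    data.frame(fish_id = "F1", treatment = "control", track_id = "M",
               parent_id = NA, tp_index = 0:2, day = c(0, 2, 5),
               area_um2 = c(100, 101, 102), delta_score = 0L,
               marker_on = c(FALSE, FALSE, TRUE),
               event = c("none", "none", "division")),
    data.frame(fish_id = "F1", treatment = "control", track_id = "D1",
               parent_id = "M", tp_index = 3:4, day = c(7, 10),
               area_um2 = d1_area, delta_score = d1_scores,
               marker_on = FALSE, event = "none"),
    data.frame(fish_id = "F1", treatment = "control", track_id = "D2",
               parent_id = "M", tp_index = 3:4, day = c(7, 10),
               area_um2 = d2_area, delta_score = d2_scores,
               marker_on = FALSE, event = "none"))
}

# parameters for a noise-free cohort whose every area is exact
quiet_params <- function(...) {
  args <- list(meas_noise_sd = 0, switch_on_rate = 0, switch_off_rate = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}
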