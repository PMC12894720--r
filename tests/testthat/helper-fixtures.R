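# Fixtures are built in code; all times in minutes post-insemination.

# one fertilized oocyte: fertilizing sperm pen [10,20] fus [30,32], plus a
# clearly earlier, a clearly later, and an overlapping non-fused penetrant
fixture_fertilized <- function() {
  chronogram(data.frame(
    oocyte_id = "o1",
    sperm_id = c("s_fert", "s_pre", "s_post", "s_amb"),
    pen_lower = c(10, 0, 40, 15),
    pen_upper = c(20, 5, 50, 31),
    fus_lower = c(30, NA, NA, NA),
    fus_upper = c(32, NA, NA, NA)),
    condition = "toy")
}

# three oocytes covering the three fates
fixture_three_fates <- function() {
  chronogram(
    sperm = data.frame(
      oocyte_id = c("a", "a", "b"),
      sperm_id = c("s1", "s2", "s1"),
      pen_lower = c(10, 60, 20),
      pen_upper = c(20, 80, 40),
      fus_lower = c(25, NA, NA),
      fus_upper = c(35, NA, NA)),
    oocytes = data.frame(oocyte_id = c("a", "b", "c"), horizon = 240))
}

# single fertilized oocyte with a degenerate fusion window at 60 and one
# extra penetrant on [50, 70]; closed-form post-fertilization count:
# P(pen in (60, 60+dt]) = dt/20 for dt in [0, 10]
fixture_halfwindow <- function() {
  chronogram(data.frame(
    oocyte_id = "o1", sperm_id = c("s1", "s2"),
    pen_lower = c(50, 50), pen_upper = c(60, 70),
    fus_lower = c(60, NA), fus_upper = c(60, NA)))
}

# count_curve-shaped object around externally supplied grid/mean values,
# for exercising the fitting functions on exact model curves
make_curve <- function(grid, mean, align = "first_fusion",
                       counted = "penetration", boot = NULL) {
  structure(list(grid = grid, mean = mean, ci_low = mean, ci_high = mean,
                 n_oocytes = NA_integer_, n_realizations = NA_integer_,
                 n_boot = if (is.null(boot)) 0L else nrow(boot),
                 align = align, counted = counted, grid_step = diff(grid[1:2]),
                 oocyte_curves = NULL, boot_curves = boot),
            class = "count_curve")
}

# hand-built ground truth for censoring tests
make_truth <- function(sperm, horizon = 240,
                       p = kinetic_params(n_oocytes = length(unique(sperm$oocyte_id)),
                                          horizon = horizon),
                       lm = landmark_set()) {
  oo <- unique(sperm$oocyte_id)
  t1 <- vapply(oo, function(oid) {
    f <- sperm$fus_time[sperm$oocyte_id == oid]
    if (all(is.na(f))) NA_real_ else min(f, na.rm = TRUE)
  }, numeric(1))
  for (col in c("head_disappearance", "pb2_onset", "pb2_angle_crossover",
                "pb2_complete"))
    if (is.null(sperm[[col]])) sperm[[col]] <- NA_real_
  structure(list(sperm = sperm,
                 oocytes = data.frame(oocyte_id = oo, horizon = horizon,
                                      first_fusion = unname(t1),
                                      stringsAsFactors = FALSE),
                 params = p, landmarks = lm, seed = NA, truncate_sd = 1),
            class = "truth_set")
}
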