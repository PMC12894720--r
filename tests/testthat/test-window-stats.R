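test_that("realizations respect degenerate windows and the seed contract", {
  ch <- chronogram(data.frame(
    oocyte_id = "o1", sperm_id = c("s1", "s2"),
    pen_lower = c(30, 50), pen_upper = c(30, 50),
    fus_lower = c(50, NA), fus_upper = c(50, NA)))
  r <- realize(ch, n = 5, seed = 1)
  expect_true(all(r$pen[1, ] == 30) && all(r$fus[1, ] == 50))
  expect_true(all(r$pen[2, ] == 50))
  expect_true(all(is.na(r$fus[2, ])))

  ch2 <- fixture_halfwindow()
  r1 <- realize(ch2, n = 50, seed = 99)
  r2 <- realize(ch2, n = 50, seed = 99)
  expect_identical(r1$pen, r2$pen)
  r3 <- realize(ch2, n = 50, seed = 100)
  expect_false(identical(r1$pen, r3$pen))
})

test_that("overlapping fused windows are sampled uniformly on the constrained triangle", {
  ch <- chronogram(data.frame(oocyte_id = "o1", sperm_id = "s1",
                              pen_lower = 0, pen_upper = 10,
                              fus_lower = 0, fus_upper = 10))
  n <- 20000
  r <- realize(ch, n = n, seed = 7)
  expect_true(all(r$fus >= r$pen))

  # independent oracle: rejection sampling from the product uniform
  set.seed(1234)
  op <- runif(4 * n, 0, 10); of <- runif(4 * n, 0, 10)
  keep <- of >= op
  op <- op[keep][1:n]; of <- of[keep][1:n]
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(r$pen) - mean(op)), 3 * sqrt(se(r$pen)^2 + se(op)^2))
  expect_lt(abs(mean(r$fus) - mean(of)), 3 * sqrt(se(r$fus)^2 + se(of)^2))
  # fusion marginal is stochastically larger than penetration
  expect_gt(mean(r$fus), mean(r$pen))
})

test_that("a shared window boundary forces the single feasible point", {
  ch <- chronogram(data.frame(oocyte_id = "o1", sperm_id = "s1",
                              pen_lower = 5, pen_upper = 10,
                              fus_lower = 0, fus_upper = 5))
  r <- realize(ch, n = 10, seed = 1)
  expect_true(all(r$pen == 5) && all(r$fus == 5))
})

test_that("post-fertilization penetration counts match the closed form", {
  cc <- count_curve(fixture_halfwindow(), "first_fusion", "penetration",
                    n_realizations = 4000, n_boot = 50, seed = 2)
  # P(pen in (60, 60+dt]) for pen ~ U[50, 70]; the aligning fusion is fixed
  p10 <- 0.5
  se10 <- sqrt(p10 * (1 - p10) / 4000)
  expect_equal(cc$mean[cc$grid == 0], 0)
  expect_lt(abs(cc$mean[cc$grid == 10] - p10), 3 * se10)
  expect_true(all(diff(cc$mean) >= 0))
  expect_true(all(cc$ci_low <= cc$mean & cc$mean <= cc$ci_high))
})

test_that("count-curve means match closed-form expectations on a 3-sperm fixture", {
  # fusion fixed at 60; extra penetrants U[55,95] and U[100,140]:
  # E[count(dt)] = sum_i P(pen_i in (60, 60+dt])
  ch <- chronogram(data.frame(
    oocyte_id = "o1", sperm_id = c("s1", "s2", "s3"),
    pen_lower = c(50, 55, 100), pen_upper = c(60, 95, 140),
    fus_lower = c(60, NA, NA), fus_upper = c(60, NA, NA)))
  R <- 4000
  cc <- count_curve(ch, "first_fusion", "penetration",
                    n_realizations = R, n_boot = 50, seed = 3)
  for (dt in c(10, 35, 60, 90, 150)) {
    p1 <- punif(60 + dt, 55, 95) - punif(60, 55, 95)
    p2 <- punif(60 + dt, 100, 140)
    se <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / R)
    expect_lt(abs(cc$mean[cc$grid == dt] - (p1 + p2)), 3 * se + 1e-12)
  }
})

test_that("degenerate single-oocyte curves collapse their confidence band", {
  ch <- chronogram(data.frame(
    oocyte_id = "o1", sperm_id = c("s1", "s2"),
    pen_lower = c(30, 80), pen_upper = c(30, 80),
    fus_lower = c(50, NA), fus_upper = c(50, NA)))
  cc <- count_curve(ch, "first_fusion", "penetration",
                    n_realizations = 10, n_boot = 200, seed = 4)
  expect_equal(cc$ci_low, cc$mean)
  expect_equal(cc$ci_high, cc$mean)
  # and the curve is the deterministic step: penetration at 80, fusion at 50
  expect_equal(cc$mean[cc$grid == 29], 0)
  expect_equal(cc$mean[cc$grid == 30], 1)
})

test_that("an oocyte with only its fertilizing sperm yields a zero curve", {
  ch <- chronogram(data.frame(oocyte_id = "o1", sperm_id = "s1",
                              pen_lower = 40, pen_upper = 50,
                              fus_lower = 55, fus_upper = 65))
  cc <- count_curve(ch, "first_fusion", "penetration",
                    n_realizations = 100, n_boot = 50, seed = 5)
  expect_true(all(cc$mean == 0))
  cf <- count_curve(ch, "first_fusion", "fusion",
                    n_realizations = 100, n_boot = 50, seed = 5)
  expect_true(all(cf$mean == 0))  # the first fusion itself is excluded
})

test_that("PVS occupancy equals cumulative penetrations minus fusions", {
  # degenerate windows make every realization identical, so the identity
  # can be checked across the returned curves directly
  ch <- chronogram(data.frame(
    oocyte_id = "o1", sperm_id = c("s1", "s2", "s3"),
    pen_lower = c(20, 40, 90), pen_upper = c(20, 40, 90),
    fus_lower = c(30, 70, NA), fus_upper = c(30, 70, NA)))
  args <- list(n_realizations = 3, n_boot = 5, seed = 6)
  cp <- do.call(count_curve, c(list(ch, "none", "penetration"), args))
  cf <- do.call(count_curve, c(list(ch, "none", "fusion"), args))
  cv <- do.call(count_curve, c(list(ch, "none", "pvs_occupancy"), args))
  expect_equal(cv$mean, cp$mean - cf$mean)
  # spot checks: at t=50 two penetrants, one fused
  expect_equal(cv$mean[cv$grid == 50], 1)
  expect_equal(cv$mean[cv$grid == 100], 1)
})

test_that("count_curve enforces its alignment preconditions", {
  ch <- fixture_three_fates()
  expect_error(count_curve(ch, "first_fusion", "penetration",
                           n_realizations = 10, n_boot = 5),
               "fertilized")
  expect_error(count_curve(subset_oocytes(ch, fate = "unpenetrated"),
                           "first_penetration", "penetration",
                           n_realizations = 10, n_boot = 5),
               "penetrated")
  expect_error(count_curve(chronogram(), "none", "penetration"), "empty")
})

test_that("fusion delay curve recovers degenerate and independent-window delays", {
  # directly observed: pen 0, fusion 10 -> step CDF, mean exactly 10
  ch <- chronogram(data.frame(oocyte_id = "o1", sperm_id = "s1",
                              pen_lower = 0, pen_upper = 0,
                              fus_lower = 10, fus_upper = 10))
  fd <- fusion_delay_curve(ch, n_realizations = 20, n_boot = 5, seed = 1)
  expect_equal(fd$mean_delay, 10)
  expect_equal(fd$prob[fd$grid == 9], 0)
  expect_equal(fd$prob[fd$grid == 10], 1)

  # pen U[0,10], fusion U[10,20]: constraint inactive, E[delay] = 15 - 5
  ch2 <- chronogram(data.frame(oocyte_id = "o1", sperm_id = "s1",
                               pen_lower = 0, pen_upper = 10,
                               fus_lower = 10, fus_upper = 20))
  R <- 4000
  fd2 <- fusion_delay_curve(ch2, n_realizations = R, n_boot = 5, seed = 2)
  se <- sqrt((100 / 12 + 100 / 12) / R)  # var of U[0,10] twice
  expect_lt(abs(fd2$mean_delay - 10), 3 * se)
  expect_error(fusion_delay_curve(fixture_three_fates() |>
                                    subset_oocytes(fate = "unpenetrated")),
               "fused")
})

test_that("the bootstrap band covers the known truth curve on synthetic cohorts", {
  # continuously observed synthetic cohorts (degenerate windows) isolate the
  # band construction from censoring loss: the analytic post-fertilization
  # penetration curve lambda0/60 * tau * (1 - exp(-t/tau)) should fall
  # inside the 95% band at >= 90% of grid points, pooled over replicates.
  # (Under sparse schedules the tail of the curve is additionally biased
  # down because events after the last round are unobservable.)
  p <- kinetic_params(n_oocytes = 40)
  dense <- observation_schedule(round_duration_range = c(240, 240),
                                gap_range = c(0, 0))
  covered <- vapply(1:15, function(k) {
    truth <- generate_truth(p, seed = 300 + k)
    cens <- censor_truth(truth, dense, seed = 600 + k)
    fert <- subset_oocytes(cens$chronogram, fate = "fertilized")
    cc <- count_curve(fert, "first_fusion", "penetration",
                      n_realizations = 100, n_boot = 300, seed = 900 + k,
                      t_max = 90)
    tc <- p$lambda0 / 60 * p$tau_PB * (1 - exp(-cc$grid / p$tau_PB))
    mean(cc$ci_low <= tc & tc <= cc$ci_high)
  }, numeric(1))
  expect_gte(mean(covered), 0.9)
})
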