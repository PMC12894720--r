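test_that("parameter validation and edge kinetics behave as specified", {
  expect_error(kinetic_params(lambda0 = -1), "lambda0")
  expect_error(kinetic_params(tau_FB = 0), "tau_FB")
  expect_error(kinetic_params(delay_mean = 0), "delay_mean")

  # an impermeable ZP admits nothing
  s0 <- simulate_cohort(kinetic_params(lambda0 = 0, n_oocytes = 20), seed = 1)
  expect_equal(s0$n_fertilized, 0L)
  expect_true(all(vapply(s0$oocytes, function(o) length(o$pen_times),
                         numeric(1)) == 0))
  expect_true(is.na(s0$mean_post_fert_penetrations))

  # an instantaneous fusion block admits exactly one fusion
  s1 <- simulate_cohort(kinetic_params(tau_FB = 1e-9, n_oocytes = 300),
                        seed = 2)
  nfus <- vapply(s1$oocytes, function(o) length(o$fus_times), numeric(1))
  t1 <- vapply(s1$oocytes, `[[`, numeric(1), "first_fusion")
  expect_true(all(nfus[!is.na(t1)] == 1))
  expect_equal(s1$polyspermy_fraction, 0)
})

test_that("cohorts are reproducible and per-oocyte results are order-independent", {
  p <- kinetic_params(n_oocytes = 25)
  a <- simulate_cohort(p, seed = 5)
  b <- simulate_cohort(p, seed = 5)
  expect_identical(a$oocytes, b$oocytes)
  expect_false(identical(a$oocytes, simulate_cohort(p, seed = 6)$oocytes))
  # oocyte i is a pure function of (seed, i): shrinking the cohort does not
  # change the retained oocytes
  p3 <- kinetic_params(n_oocytes = 3)
  small <- simulate_cohort(p3, seed = 5)
  expect_identical(a$oocytes[1:3], small$oocytes)
})

test_that("event logs conserve sperm and respect the horizon", {
  p <- kinetic_params(n_oocytes = 200, horizon = 240)
  s <- simulate_cohort(p, seed = 9)
  for (o in s$oocytes) {
    expect_equal(length(o$fus_of_pen), length(o$pen_times))
    expect_equal(sort(o$fus_of_pen[!is.na(o$fus_of_pen)]), o$fus_times)
    expect_lte(length(o$fus_times), length(o$pen_times))
    expect_true(all(o$pen_times <= p$horizon))
    expect_true(all(o$fus_times <= p$horizon))
    expect_true(all(is.na(o$fus_of_pen) | o$fus_of_pen >= o$pen_times))
  }
})

test_that("without blocks penetrations are homogeneous Poisson and all attempts fuse", {
  # fixed 10-min delay: every penetrant before horizon-10 must fuse
  p <- kinetic_params(tau_PB = Inf, tau_FB = Inf, delay_mean = 10,
                      delay_sd = 0, delay_family = "fixed",
                      n_oocytes = 5000, horizon = 240)
  s <- simulate_cohort(p, seed = 12)
  npen <- vapply(s$oocytes, function(o) length(o$pen_times), numeric(1))
  expected <- p$lambda0 * p$horizon / 60
  se <- sd(npen) / sqrt(length(npen))
  expect_lt(abs(mean(npen) - expected), 3 * se)
  fuse_all <- vapply(s$oocytes, function(o)
    all(!is.na(o$fus_of_pen[o$pen_times <= p$horizon - 10])), logical(1))
  expect_true(all(fuse_all))
})

test_that("post-fertilization penetrations converge to lambda0 * tau_PB", {
  p <- kinetic_params(horizon = 480, n_oocytes = 8000)
  s <- simulate_cohort(p, seed = 13)
  post <- vapply(seq_along(s$oocytes), function(i) {
    o <- s$oocytes[[i]]
    if (is.na(o$first_fusion)) NA_real_ else
      sum(o$pen_times > o$first_fusion)
  }, numeric(1))
  post <- post[!is.na(post)]
  expected <- p$lambda0 * p$tau_PB / 60  # 0.974
  se <- sd(post) / sqrt(length(post))
  expect_lt(abs(mean(post) - expected), 3 * se)
  expect_equal(mean(post), s$mean_post_fert_penetrations)
})

test_that("scenarios transform the kinetics as advertised", {
  p <- kinetic_params(n_oocytes = 400)
  expect_error(run_scenario(p, "frobnicate", seed = 1), "arg")

  base <- run_scenario(p, "baseline", seed = 21)
  expect_identical(base$oocytes, simulate_cohort(p, seed = 21)$oocytes)

  # removing the fusion block can only add fusions (coupled by shared seed)
  nofb <- run_scenario(p, "no_fusion_block", seed = 21)
  expect_true(all(nofb$extra_fusion_curve$mean >=
                    base$extra_fusion_curve$mean))
  expect_gte(nofb$polyspermy_fraction, base$polyspermy_fraction)

  # tripled permeability: post-T1 penetrations approach 3 lambda0 tau / 60
  p2 <- kinetic_params(horizon = 600, n_oocytes = 4000)
  x3 <- run_scenario(p2, "permeability_x3", seed = 22)
  post <- vapply(x3$oocytes, function(o)
    if (is.na(o$first_fusion)) NA_real_ else
      sum(o$pen_times > o$first_fusion), numeric(1))
  post <- post[!is.na(post)]
  expected <- 3 * p2$lambda0 * p2$tau_PB / 60
  expect_lt(abs(mean(post) - expected), 3 * sd(post) / sqrt(length(post)))

  # halved fusion time halves the mean delay parameter
  half <- run_scenario(p, "half_fusion_time", seed = 21)
  expect_equal(half$params$delay_mean, p$delay_mean / 2)
  expect_equal(half$params$delay_sd, p$delay_sd / 2)
  # no penetration block leaves the ZP permeable after fertilization
  nopb <- run_scenario(p, "no_penetration_block", seed = 21)
  expect_gt(nopb$mean_post_fert_penetrations,
            base$mean_post_fert_penetrations)
})

test_that("the simulator's extra-fusion curve is recovered by the fusion-block fit", {
  # cross-module self-consistency: the aggregated curve has the saturating
  # exponential shape with the simulator's own tau_FB
  p <- kinetic_params(n_oocytes = 10000)
  s <- simulate_cohort(p, seed = 31)
  cur <- s$extra_fusion_curve
  keep <- cur$dt_min <= 120
  f <- fit_fusion_block(make_curve(cur$dt_min[keep], cur$mean[keep],
                                   counted = "fusion"),
                        amplitude = s$mean_extra_fusions)
  expect_lt(abs(f$tau_FB - p$tau_FB) / p$tau_FB, 0.2)
})

test_that("delay families are moment-matched", {
  n <- 40000
  for (fam in c("gamma", "lognormal")) {
    p <- kinetic_params(delay_family = fam, n_oocytes = 1)
    d <- local({
      set.seed(77)
      fertkin:::draw_delays(n, p)
    })
    expect_lt(abs(mean(d) - 15.8), 3 * sd(d) / sqrt(n))
    expect_lt(abs(sd(d) - 5.7), 0.2)
    expect_true(all(d > 0))
  }
  p_fix <- kinetic_params(delay_family = "fixed", n_oocytes = 1)
  expect_true(all(fertkin:::draw_delays(10, p_fix) == 15.8))
})
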