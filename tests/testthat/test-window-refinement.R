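test_that("interval rules reproduce the landmark arithmetic", {
  lm <- landmark_set()
  h <- 240
  expect_equal(unclass(rule_window("unfused_motile", 100, lm, h)),
               c(lower = 100, upper = 240))
  expect_equal(unclass(rule_window("arrest_observed", 60, lm, h)),
               c(lower = 59, upper = 61))
  expect_equal(unclass(rule_window("head_visible_fused", 200, lm, h)),
               c(lower = 173, upper = 200))
  expect_equal(unclass(rule_window("flagellum_only", 200, lm, h)),
               c(lower = 0, upper = 179))
  expect_equal(unclass(rule_window("pb2_protrusion_angle_gt_90", 200, lm, h)),
               c(lower = 145, upper = 174))
  expect_equal(unclass(rule_window("pb2_extracting_angle_lt_90", 200, lm, h)),
               c(lower = 117, upper = 157))
  expect_equal(unclass(rule_window("pb2_complete", 200, lm, h)),
               c(lower = 0, upper = 137))
})

test_that("rule windows are clipped to the observation period and flag impossible states", {
  # early head-visible observation: lower bound clipped at insemination
  expect_equal(unclass(rule_window("head_visible_fused", 10)),
               c(lower = 0, upper = 10))
  # a completed PB2 extrusion 30 min after insemination is impossible
  expect_error(rule_window("pb2_complete", 30), "inconsistent")
  expect_error(rule_window("flagellum_only", 5), "inconsistent")
  expect_error(rule_window("head_visible_fused", 300, horizon = 240),
               "t_obs")
})

test_that("custom landmark sets propagate into the rule constants", {
  lm <- landmark_set(head_disappearance = c(20, 5), pb2_onset = c(30, 4),
                     pb2_angle_crossover = c(50, 5), pb2_complete = c(80, 8))
  expect_equal(unclass(rule_window("head_visible_fused", 200, lm)),
               c(lower = 175, upper = 200))
  expect_equal(unclass(rule_window("pb2_protrusion_angle_gt_90", 200, lm)),
               c(lower = 145, upper = 174))
  expect_error(landmark_set(pb2_onset = c(20, 2)), "strictly increasing")
  expect_error(landmark_set(head_disappearance = c(24, -1)), "positive")
})

test_that("penetration windows come from the inter-round gap", {
  expect_equal(unclass(penetration_window_from_rounds(30, 75)),
               c(lower = 30, upper = 75))
  expect_equal(unclass(penetration_window_from_rounds(30, 30)),
               c(lower = 30, upper = 30))
  expect_error(penetration_window_from_rounds(75, 30), "after")
})

test_that("refine_fusion_window intersects the per-round rules", {
  rounds <- data.frame(t_start = c(100, 140), t_end = c(100, 140),
                       state = c("unfused_motile", "head_visible_fused"))
  w <- refine_fusion_window(rounds, pen = time_window(0, 50))
  expect_equal(unclass(w), c(lower = 113, upper = 140))

  # live-observed arrest: +/- 1 min around the arrest time
  arr <- data.frame(t_start = 60, t_end = 60, state = "arrest_observed")
  expect_equal(unclass(refine_fusion_window(arr, pen = time_window(0, 50))),
               c(lower = 59, upper = 61))

  # disjoint rules are reported as an inconsistency naming the rounds
  bad <- data.frame(t_start = c(100, 100), t_end = c(100, 100),
                    state = c("pb2_complete", "head_visible_fused"))
  expect_error(refine_fusion_window(bad), "inconsistent.*pb2_complete")
  expect_error(refine_fusion_window(bad[0, ]), "at least one")

  # rules anchored at a round are evaluated at the round midpoint
  mid <- data.frame(t_start = 130, t_end = 150,
                    state = "head_visible_fused")
  expect_equal(unclass(refine_fusion_window(mid)),
               c(lower = 113, upper = 140))
})

test_that("refinement is order-independent and idempotent", {
  rounds <- data.frame(
    t_start = c(40, 90, 150), t_end = c(44, 96, 158),
    state = c("unfused_motile", "head_visible_fused", "flagellum_only"))
  w <- refine_fusion_window(rounds, pen = time_window(0, 30))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(refine_fusion_window(rounds[perm, ],
                                      pen = time_window(0, 30)), w)
  # duplicating the evidence does not change the intersection
  expect_equal(refine_fusion_window(rbind(rounds, rounds[2, ]),
                                    pen = time_window(0, 30)), w)
  # intersecting the result with itself is a no-op
  expect_equal(c(max(w[[1]], w[[1]]), min(w[[2]], w[[2]])),
               unname(unclass(w)))
})

test_that("rule windows never exceed their rule-implied width and stay in range", {
  lm <- landmark_set()
  max_width <- c(unfused_motile = Inf, arrest_observed = 2,
                 head_visible_fused = 27, flagellum_only = Inf,
                 pb2_protrusion_angle_gt_90 = 29,
                 pb2_extracting_angle_lt_90 = 40, pb2_complete = Inf)
  set.seed(42)
  for (k in 1:200) {
    st <- sample(observed_states, 1)
    t_obs <- runif(1, 0, 240)
    w <- tryCatch(rule_window(st, t_obs, lm, 240), error = function(e) NULL)
    if (is.null(w)) next  # inconsistent (too-early) observation
    expect_gte(w[[1]], 0)
    expect_lte(w[[2]], 240)
    expect_lte(w[[2]] - w[[1]], min(max_width[[st]], 240))
  }
})
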