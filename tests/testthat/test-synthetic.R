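# Synthetic gait generator: determinism, configured-vs-realized step
# statistics, force/stance consistency, perturbation truth structure.

test_that("identical seeds give bit-identical sessions", {
  p <- gait_params(seed = 11)
  a <- simulate_gait_trial(p, duration = 12)
  b <- simulate_gait_trial(p, duration = 12)
  expect_identical(a$markers, b$markers)
  expect_identical(a$forces, b$forces)
  expect_identical(a$truth$mos, b$truth$mos)
  r <- perturbation_response()
  pa <- simulate_perturbation_session(p, r, short_schedule(2), seed = 5)
  pb <- simulate_perturbation_session(p, r, short_schedule(2), seed = 5)
  expect_identical(pa$markers, pb$markers)
  expect_identical(pa$truth$pert_times, pb$truth$pert_times)
})

test_that("zero step-time variability yields equal realized step times", {
  p <- quiet_params(2, step_time_cv = 0)
  ses <- simulate_gait_trial(p, duration = 20)
  st <- diff(ses$truth$events$touchdowns$time)
  expect_lt(max(abs(st - 0.55)), 1e-9)
})

test_that("realized step parameters track the configured distributions", {
  p <- quiet_params(8, step_length_mean = 0.65, step_time_mean = 0.5,
                    step_length_cv = 0.04)
  ses <- simulate_gait_trial(p, speed = 1.3, duration = 40)
  steps <- step_parameters(ses, ses$truth$events)
  expect_gte(nrow(steps), 50)
  se <- sd(steps$step_length) / sqrt(nrow(steps))
  expect_lt(abs(mean(steps$step_length) - 0.65), 3 * se + 1e-3)

  # realized CV of step time within 30% of configured, over >= 100 steps
  for (cv in c(0, 0.02, 0.05)) {
    p2 <- quiet_params(3, step_time_cv = cv)
    s2 <- simulate_gait_trial(p2, duration = 70)
    st <- diff(s2$truth$events$touchdowns$time)
    expect_gte(length(st), 100)
    realized <- sd(st) / mean(st)
    if (cv == 0) {
      expect_lt(realized, 1e-9)
    } else {
      expect_lt(abs(realized - cv) / cv, 0.3)
    }
  }
})

test_that("belt force exceeds threshold exactly during stance", {
  p <- quiet_params(5)
  ses <- simulate_gait_trial(p, duration = 15)
  td <- ses$truth$events$touchdowns
  to <- ses$truth$events$toeoffs
  f <- ses$forces
  thr <- 0.5 * p$body_mass * 9.81
  # mid-stance samples must carry more than half body weight
  for (i in which(td$side == "L")[2:5]) {
    t_td <- td$time[i]
    t_to <- to$time[to$side == "L" & to$time > t_td][1]
    mid <- f$time > t_td + 0.15 & f$time < t_to - 0.15
    expect_true(all(f$left[mid] > thr))
    # swing: no force on that belt
    t_next <- td$time[td$side == "L" & td$time > t_td][1]
    sw <- f$time > t_to + 0.01 & f$time < t_next - 0.01
    expect_true(all(f$left[sw] == 0))
  }
})

test_that("mean truth MoS decreases strictly with speed", {
  p <- quiet_params(6)
  means <- vapply(seq(0.4, 1.8, by = 0.2), function(v) {
    mean(simulate_gait_trial(p, speed = v, duration = 12)$truth$mos$mos_ap)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("speed and duration preconditions are enforced", {
  p <- quiet_params(1)
  expect_error(simulate_gait_trial(p, speed = 0.1), "speed")
  expect_error(simulate_gait_trial(p, speed = 3.0), "speed")
  expect_error(simulate_gait_trial(p, duration = 5), "duration")
  expect_error(gait_params(double_support_fraction = 0.6),
               "double_support_fraction")
  expect_error(gait_params(mos_speed_coeffs = c(0.1, 0.05, 0)), "monotone")
  expect_error(perturbation_response(recovery_rate = 1.2), "recovery_rate")
})

test_that("perturbation truth follows the geometric response model", {
  p <- quiet_params(9)
  # closed-form decay: -0.12, -0.06, -0.03, -0.015 at Post1..Post4
  r <- perturbation_response(initial_mos_deviation = -0.12,
                             recovery_rate = 0.5, response_sd = 0,
                             delay_steps = 0)
  ses <- simulate_perturbation_session(p, r, short_schedule(3), seed = 21)
  base <- 0.22 - 0.12 * 1.3 + 0.005 * 1.3^2
  tr <- ses$truth$mos
  on <- ses$truth$pert_times[1]
  post <- tr$mos_ap[tr$touchdown_time >= on][1:4]
  expect_equal(post - base, c(-0.12, -0.06, -0.03, -0.015),
               tolerance = 1e-9)

  # full adaptation: perturbations 2..10 at baseline
  r1 <- perturbation_response(adaptation_rate = 1, response_sd = 0)
  s1 <- simulate_perturbation_session(p, r1, short_schedule(4), seed = 22)
  for (j in 2:10) {
    on_j <- s1$truth$pert_times[j]
    post_j <- s1$truth$mos$mos_ap[s1$truth$mos$touchdown_time >= on_j][1:8]
    expect_lt(max(abs(post_j - base)), 1e-9)
  }

  # no adaptation: Post1 deviation identical at every perturbation
  r0 <- perturbation_response(adaptation_rate = 0, response_sd = 0)
  s0 <- simulate_perturbation_session(p, r0, short_schedule(5), seed = 23)
  p1 <- vapply(s0$truth$pert_times, function(on) {
    s0$truth$mos$mos_ap[s0$truth$mos$touchdown_time >= on][1]
  }, numeric(1))
  expect_lt(diff(range(p1 - base)), 1e-9)

  # delay holds the full deviation before decay begins
  rd <- perturbation_response(initial_mos_deviation = -0.1,
                              recovery_rate = 0.5, response_sd = 0,
                              delay_steps = 2)
  sd_ <- simulate_perturbation_session(p, rd, short_schedule(6), seed = 24)
  on1 <- sd_$truth$pert_times[1]
  post1 <- sd_$truth$mos$mos_ap[sd_$truth$mos$touchdown_time >= on1][1:5]
  expect_equal(post1 - base, c(-0.1, -0.1, -0.1, -0.05, -0.025),
               tolerance = 1e-9)
})

test_that("perturbation schedule follows the protocol", {
  set.seed(13)
  sch <- perturbation_schedule()
  expect_equal(sch$side, c("R", rep("L", 8), "R"))
  expect_true(all(sch$gap[-1] >= 30 & sch$gap[-1] <= 90))
  expect_error(perturbation_schedule(sides = c("L", "R")), "mismatch")

  p <- quiet_params(10)
  ses <- simulate_perturbation_session(p, perturbation_response(),
                                       short_schedule(7), seed = 31)
  expect_length(ses$truth$pert_times, 10)
  expect_true(all(diff(ses$truth$pert_times) >= 30 &
                    diff(ses$truth$pert_times) <= 90))
  expect_equal(ses$truth$pert_table$side, c("R", rep("L", 8), "R"))
  # truth touchdown sides alternate throughout
  sides <- ses$truth$events$touchdowns$side
  expect_true(all(sides[-1] != sides[-length(sides)]))
})

test_that("perturbed belt ramps at the configured acceleration to the cap", {
  p <- quiet_params(12)
  ses <- simulate_perturbation_session(p, perturbation_response(),
                                       short_schedule(8), speed = 1.3,
                                       accel = 3, speed_factor = 1.8,
                                       seed = 41)
  expect_equal(max(ses$belt_left), 1.8 * 1.3, tolerance = 1e-6)
  expect_equal(max(ses$belt_right), 1.8 * 1.3, tolerance = 1e-6)
  # slope during the first ramp
  on <- ses$truth$pert_table$onset[2]  # a left perturbation
  sel <- ses$time > on + 0.02 & ses$time < on + 0.2
  slope <- diff(ses$belt_left[sel]) * 100
  expect_equal(median(slope), 3, tolerance = 0.01)
  # unperturbed belt stays at base speed during that window
  expect_true(all(abs(ses$belt_right[sel] - 1.3) < 1e-9))
})
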