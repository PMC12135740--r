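test_that("simulation config validates fields by name", {
  expect_error(simulation_config(cardiac_fraction = 1.4),
               "cardiac_fraction")
  expect_error(simulation_config(base_pc_rate = -1), "base_pc_rate")
  expect_error(simulation_config(type_weights = c(Flat = 1)),
               "type_weights")
  expect_error(simulation_config(sinus_cv = -0.1), "sinus_cv")
  expect_error(simulation_config(workouts_per_horse = c(5, 2)),
               "workouts_per_horse")
  expect_error(simulation_config(paf_prob = 2), "paf_prob")
})

test_that("cohort sampling applies the cardiac fraction as a fixed count", {
  cfg <- simulation_config(n_horses = 10, cardiac_fraction = 0.2, seed = 1,
                           workouts_per_horse = c(2, 2))
  co <- sample_cohort(cfg)
  expect_equal(nrow(co$horses), 10L)
  expect_equal(sum(co$horses$cardiac), 2L)
  # workouts_per_horse = [2,2]: every horse has exactly 2 plans
  expect_equal(length(co$plans), 20L)
  per_horse <- table(vapply(co$plans, `[[`, "", "horse_id"))
  expect_true(all(per_horse == 2))
  expect_true(all(co$horses$pc_propensity > 0))
  expect_true(all(co$horses$level %in% 1:5))
})

test_that("cohort sampling is deterministic under a fixed seed", {
  cfg <- simulation_config(n_horses = 5, seed = 77,
                           workouts_per_horse = c(2, 4))
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(a, b)
  sim_a <- simulate_workout(a$horses[a$horses$horse_id ==
                                       a$plans[[1]]$horse_id, ],
                            a$plans[[1]], cfg)
  sim_b <- simulate_workout(b$horses[b$horses$horse_id ==
                                       b$plans[[1]]$horse_id, ],
                            b$plans[[1]], cfg)
  expect_identical(sim_a, sim_b)
})

test_that("HR trajectories respect the +-5% peak contract and have no gaps", {
  plan_flat <- toy_plan(type = "Flat", duration_min = 30,
                        target_hr_peak = 140, seed = 3)
  f <- simulate_hr_trajectory(plan_flat)
  tt <- seq(0, attr(f, "duration_ms"), by = 1000)
  vals <- f(tt)
  expect_false(any(is.na(vals)))
  expect_gte(max(vals), 133); expect_lte(max(vals), 147)

  plan_comp <- toy_plan(type = "Competition", duration_min = 12,
                        target_hr_peak = 211, seed = 4)
  g <- simulate_hr_trajectory(plan_comp)
  mx <- max(g(seq(0, attr(g, "duration_ms"), by = 500)))
  expect_gte(mx, 200.45); expect_lte(mx, 221.55)

  # terminal deceleration is steep enough for the default segmenter
  expect_gte(attr(g, "decel_start_ms"), 0)
  d0 <- attr(g, "decel_start_ms")
  expect_gte(g(d0) - g(d0 + 60000), 30)

  expect_error(simulate_hr_trajectory(toy_plan(duration_min = 4)),
               "too short")
})

test_that("noise-free constant-HR tachograms are exact", {
  traj <- flat_trajectory(120, 5)
  cfg <- simulation_config(sinus_cv = 0, base_pc_rate = 0,
                           artifact_fraction_range = c(0, 0),
                           workouts_per_horse = c(1, 1))
  sim <- simulate_tachogram(traj, toy_horse(), toy_plan(injections = list()),
                            cfg, seed = 1)
  expect_true(all(sim$tachogram$rr_ms == 500))
  expect_equal(sum(sim$ground_truth$labels == "premature"), 0L)
})

test_that("event injection arithmetic matches the pause semantics exactly", {
  rr <- rep(500, 50)
  comp <- inject_event(rr, event_spec("single_pc", prematurity = 0.10,
                                      pause = "compensatory"), at = 20)
  expect_equal(comp$rr[20], 450)
  expect_equal(comp$rr[21], 550)
  expect_equal(comp$rr[20] + comp$rr[21], 2 * 500)   # exact
  non <- inject_event(rr, event_spec("single_pc", prematurity = 0.10,
                                     pause = "non_compensatory"), at = 20)
  expect_equal(non$rr[20], 450)
  expect_equal(non$rr[21], 500)
  expect_lt(non$rr[20] + non$rr[21], 2 * 500 * 0.96)

  trip <- inject_event(rr, event_spec("triplet", prematurity = 0.2), at = 10)
  expect_equal(trip$rr[10:12], rep(400, 3))
  expect_equal(trip$rr[13], 600)                     # one return cycle
  expect_equal(trip$span, c(10, 12))

  expect_error(event_spec("single_pc", prematurity = 1.2), "prematurity")
  expect_error(event_spec("run", run_length = 3), "run_length")
  expect_error(inject_event(rr, event_spec("run", run_length = 20), at = 45),
               "fit")

  set.seed(9)
  paf <- inject_event(rr, event_spec("paf", paf_beats = 30), at = 10)
  seg <- paf$rr[10:39]
  expect_true(all(seg >= 0.7 * 500 - 1 & seg <= 1.4 * 500 + 1))
  # uniform moments: cv = (0.7*500/sqrt(12)) / 525 = 0.1925 >> 0.10
  expect_gt(sd(seg) / mean(seg), 0.10)
})

test_that("ground-truth ledger conserves premature beat counts", {
  cfg <- simulation_config(n_horses = 3, workouts_per_horse = c(2, 2),
                           base_pc_rate = 2, complex_event_prob = 0.5,
                           couplet_prob = 0.5, paf_prob = 0.3,
                           duration_log_mean = log(8),
                           duration_log_sd = 0.1,
                           duration_bounds = c(6, 12), seed = 21)
  co <- sample_cohort(cfg)
  for (plan in co$plans) {
    horse <- co$horses[co$horses$horse_id == plan$horse_id, ]
    sim <- simulate_workout(horse, plan, cfg)
    led <- sim$ground_truth$ledger
    led <- led[led$realised, ]
    n_prem_led <- sum(led$run_length[led$kind != "paf"])
    expect_equal(sum(sim$ground_truth$labels == "premature"), n_prem_led)
    n_paf_led <- sum(led$run_length[led$kind == "paf"])
    expect_equal(sum(sim$ground_truth$labels == "paf"), n_paf_led)
    # ledger spans disjoint
    if (nrow(led) > 1) {
      led <- led[order(led$start_beat), ]
      expect_true(all(diff(led$start_beat) >
                        led$run_length[-nrow(led)]))
    }
  }
})

test_that("specificity anchor: clean simulations yield nPC = 0 downstream", {
  cfg <- simulation_config(n_horses = 2, workouts_per_horse = c(2, 2),
                           sinus_cv = 0, base_pc_rate = 0,
                           complex_event_prob = 0, couplet_prob = 0,
                           paf_prob = 0, artifact_fraction_range = c(0, 0),
                           duration_log_mean = log(7),
                           duration_log_sd = 0.1,
                           duration_bounds = c(5, 10), seed = 8)
  co <- sample_cohort(cfg)
  for (plan in co$plans) {
    horse <- co$horses[co$horses$horse_id == plan$horse_id, ]
    sim <- simulate_workout(horse, plan, cfg)
    an <- analyze_tachogram(sim$tachogram)
    expect_equal(an$profile$nPC, 0L)
    expect_false(an$profile$arrhythmia)
  }
})
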