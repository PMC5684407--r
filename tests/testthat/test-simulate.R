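test_that("trajectories respect the scheme and the no-exit case", {
  frozen <- kinetic_scheme(data.frame(from = "SS", to = "PK", rate = 0))
  traj <- simulate_trajectory(frozen, t_end = 100, seed = 1)
  expect_equal(traj, tibble::tibble(state = "SS", entry_time_s = 0))

  sch <- default_scheme()
  traj <- simulate_trajectory(sch, t_end = 30, seed = 7)
  expect_true(all(diff(traj$entry_time_s) > 0))
  expect_true(all(traj$state[-1] != traj$state[-nrow(traj)]))
  edges <- paste(traj$state[-nrow(traj)], traj$state[-1])
  ok <- with(sch$transitions[sch$transitions$rate > 0, ], paste(from, to))
  expect_true(all(edges %in% ok))
})

test_that("state_at_time uses inclusive entry times", {
  traj <- tibble::tibble(state = c("SS", "HP1"), entry_time_s = c(0, 0.5))
  expect_equal(state_at_time(traj, 0), "SS")
  expect_equal(state_at_time(traj, 0.4), "SS")
  expect_equal(state_at_time(traj, 0.5), "HP1")
  expect_equal(state_at_time(traj, 99), "HP1")
  expect_error(state_at_time(traj, -0.1), ">= 0")
})

test_that("Gillespie survival matches the analytic exponential", {
  sch <- irreversible_scheme(1)
  n <- 10000
  set.seed(11)
  still_ss <- vapply(seq_len(n), function(i) {
    state_at_time(simulate_trajectory(sch, t_end = 1.001), 1) == "SS"
  }, logical(1))
  p_hat <- mean(still_ss)
  p_true <- exp(-1)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("Gillespie occupancy agrees with the spectral solution", {
  sch <- default_scheme()
  n <- 10000
  want <- populations_wide(solve_populations(sch, c(1, 10)))
  set.seed(5)
  for (tt in c(1, 10)) {
    states <- vapply(seq_len(n), function(i) {
      state_at_time(simulate_trajectory(sch, t_end = tt + 1e-9), tt)
    }, character(1))
    for (s in sch$states) {
      p_true <- want[[s]][want$time_s == tt]
      se <- sqrt(max(p_true * (1 - p_true), 1e-12) / n)
      expect_lt(abs(mean(states == s) - p_true), 3 * se + 1e-9)
    }
  }
})

test_that("unfolding durations are exponential with the configured mean", {
  tau <- c(HP1 = 2.5, HP2 = 20, TS = 210, PK = 3500)
  expect_true(is.na(sample_unfolding_duration("SS", tau)))
  expect_error(sample_unfolding_duration("XX", tau), "no unfolding")

  set.seed(3)
  draws <- replicate(1e5, sample_unfolding_duration("PK", tau))
  expect_lt(abs(mean(draws) - 3500) / 3500, 0.01)

  set.seed(4)
  d <- replicate(5000, sample_unfolding_duration("TS", tau))
  ks <- stats::ks.test(d, "pexp", 1 / 210)
  expect_gt(ks$p.value, 0.01)
})

test_that("event tables are reproducible and structurally sound", {
  cfg <- generator_config(events_per_time = 40, folding_times = c(1, 10),
                          master_seed = 99L)
  e1 <- generate_event_table(cfg)
  e2 <- generate_event_table(cfg)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_equal(nrow(e1), 80)
  expect_true(all(is.na(e1$unfolding_duration_ms) ==
                    (e1$event_class == "no_block")))
  expect_true(all(e1$unfolding_duration_ms[!is.na(e1$unfolding_duration_ms)] > 0))
  expect_true(all(e1$censored[!is.na(e1$unfolding_duration_ms)] ==
                    (e1$unfolding_duration_ms[!is.na(e1$unfolding_duration_ms)] <
                       cfg$dead_time_ms)))
  # a different master seed produces different data
  cfg2 <- cfg; cfg2$master_seed <- 100L
  expect_false(identical(as.data.frame(generate_event_table(cfg2)),
                         as.data.frame(e1)))
})

test_that("degenerate generator configurations give all no-block events", {
  frozen <- kinetic_scheme(data.frame(from = "SS", to = "PK", rate = 0),
                           states = c("SS", "PK"))
  cfg <- generator_config(scheme = frozen, tau_map = c(PK = 10),
                          events_per_time = 30, folding_times = c(1, 5),
                          ss0_fraction = 0.3)
  ev <- generate_event_table(cfg)
  expect_true(all(ev$event_class == "no_block"))
  expect_equal(p0_from_events(ev, 1), 1.0)

  # near-total buffer fraction dominates regardless of kinetics
  cfg2 <- generator_config(events_per_time = 60, folding_times = 10,
                           ss0_fraction = 0.95, master_seed = 2L)
  ev2 <- generate_event_table(cfg2)
  expect_gt(mean(ev2$event_class == "no_block"), 0.85)
})

test_that("snapshot class counts match the master-equation populations", {
  cfg <- generator_config(events_per_time = 578, folding_times = 10,
                          ss0_fraction = 0, master_seed = 31L)
  ev <- generate_event_table(cfg)
  want <- populations_wide(solve_populations(cfg$scheme, 10))
  n <- nrow(ev)
  for (s in cfg$scheme$states) {
    p_true <- want[[s]][1]
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(mean(ev$true_state == s) - p_true), 3 * se + 1e-9)
  }
})

test_that("event tables round-trip through TSV", {
  cfg <- generator_config(events_per_time = 25, folding_times = c(1, 10),
                          master_seed = 8L)
  ev <- generate_event_table(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$unfolding_duration_ms, ev$unfolding_duration_ms)
  expect_equal(back$event_class, ev$event_class)
  expect_equal(back$t_fold_s, ev$t_fold_s)
})

test_that("mixture duration sampler censors at the dead time", {
  d <- sample_mixture_durations(5000, tau_ms = c(2, 100), weights = c(1, 1),
                                dead_time_ms = 0.5, seed = 2)
  expect_true(all(d$unfolding_duration_ms >= 0.5))
  expect_true(all(d$component %in% c(1, 2)))
  d2 <- sample_mixture_durations(5000, tau_ms = c(2, 100),
                                 weights = c(1, 1), seed = 2)
  expect_equal(nrow(d2), 5000)
})
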