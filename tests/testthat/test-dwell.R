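test_that("log histogram bins and normalises correctly", {
  h <- log_histogram(10)
  expect_equal(sum(h$count > 0), 1)
  hit <- h[h$count > 0, ]
  expect_true(hit$bin_lo_ms <= 10 && 10 <= hit$bin_hi_ms)
  expect_equal(hit$density, 1)

  set.seed(1)
  d <- rexp(578, 1 / 50)
  h <- log_histogram(d)
  expect_equal(sum(h$count), 578)
  expect_equal(attr(h, "total_events"), 578)
  expect_equal(sum(h$density), 1, tolerance = 1e-12)
  expect_true(all(diff(h$log10_mid) > 0))

  expect_error(log_histogram(numeric(0)), "no durations")
  expect_error(log_histogram(c(1, -2)), "> 0")
  # range widens to cover extreme data on whole bins
  h2 <- log_histogram(c(0.01, 2e5))
  expect_equal(sum(h2$count), 2)
})

test_that("log-time mixture density has the analytic peak and area", {
  # single component: f(tau) = c / e
  expect_equal(mixture_density(20, 20, 1), exp(-1))
  expect_equal(mixture_density(7, 7, 2.5), 2.5 * exp(-1))
  expect_error(mixture_density(-1, 20, 1), "> 0")

  # area per component over d(ln t) equals its amplitude
  for (tau in c(2.5, 210)) {
    q <- stats::integrate(function(x) mixture_density(exp(x), tau, 0.7),
                          -25, 25, rel.tol = 1e-10)
    expect_equal(q$value, 0.7, tolerance = 1e-6)
  }
  q2 <- stats::integrate(
    function(x) mixture_density(exp(x), c(2.5, 20, 210, 3500),
                                c(0.1, 0.2, 0.3, 0.4)), -25, 30,
    rel.tol = 1e-10)
  expect_equal(q2$value, 1, tolerance = 1e-6)

  # maximum sits at t = tau
  tgrid <- 10^seq(-2, 5, by = 0.001)
  for (tau in c(2.5, 3500)) {
    f <- mixture_density(tgrid, tau, 1)
    expect_equal(tgrid[which.max(f)], tau, tolerance = 0.005)
  }
})

test_that("noiseless single-component density is recovered within 1%", {
  h <- noiseless_histogram(18, 1)
  fit <- fit_mixture(h, 1, seed = 1)
  expect_lt(abs(fit$components$tau_ms - 18) / 18, 0.01)
  expect_lt(abs(fit$amplitudes$amplitude - 1), 0.01)
})

test_that("well-separated components are recovered from 5000 events", {
  tau <- c(2, 16, 128, 1024)
  d <- sample_mixture_durations(5000, tau, rep(1, 4), dead_time_ms = 0.5,
                                seed = 21)
  fit <- fit_mixture(log_histogram(d$unfolding_duration_ms), 4, seed = 21)
  expect_equal(fit$components$tau_ms, sort(fit$components$tau_ms))
  expect_true(all(abs(fit$components$tau_ms - tau) / tau < 0.10))
})

test_that("over-specified fits collapse the redundant component", {
  set.seed(42)
  d <- rexp(3000, 1 / 18)
  fit <- fit_mixture(log_histogram(d), 2, seed = 3)
  amp <- fit$amplitudes$amplitude
  expect_lt(min(amp) / sum(amp), 0.15)
  expect_lt(abs(fit$components$tau_ms[which.max(amp)] - 18) / 18, 0.10)
})

test_that("component count cannot exceed occupied bins", {
  expect_error(fit_mixture(log_histogram(c(10, 10.1, 98)), 4,
                           dead_time_ms = 0),
               "occupied bins")
})

test_that("global fits share time constants and lose to independent fits", {
  tau <- c(5, 200)
  d1 <- sample_mixture_durations(1500, tau, c(3, 1), seed = 1)
  d2 <- sample_mixture_durations(1500, tau, c(1, 3), seed = 2)
  h1 <- log_histogram(d1$unfolding_duration_ms, t_fold = 1)
  h2 <- log_histogram(d2$unfolding_duration_ms, t_fold = 30)
  g <- fit_mixture(list(h1, h2), 2, mode = "global", seed = 5)
  expect_equal(nrow(g$components), 2)
  expect_equal(unique(g$amplitudes$t_fold), c(1, 30))
  # shared taus recovered; per-time amplitudes reflect the weight flip
  expect_true(all(abs(g$components$tau_ms - tau) / tau < 0.15))
  a1 <- g$amplitudes$amplitude[g$amplitudes$t_fold == 1]
  a2 <- g$amplitudes$amplitude[g$amplitudes$t_fold == 30]
  expect_gt(a1[1] / a1[2], 1)
  expect_lt(a2[1] / a2[2], 1)
  # a global fit cannot beat the sum of independent fits
  ind <- fit_mixture(list(h1, h2), 2, mode = "single", seed = 5)
  expect_gte(g$objective + 1e-9,
             sum(vapply(ind, function(f) f$objective, numeric(1))))
})

test_that("maximum-likelihood mode agrees with the binned fit", {
  d <- sample_mixture_durations(4000, c(5, 500), c(1, 1),
                                dead_time_ms = 0.5, seed = 9)
  h <- log_histogram(d$unfolding_duration_ms)
  ls <- fit_mixture(h, 2, seed = 9)
  ml <- fit_mixture(h, 2, seed = 9, method = "mle",
                    durations = list(d$unfolding_duration_ms))
  expect_true(all(abs(ml$components$tau_ms - ls$components$tau_ms) /
                    ls$components$tau_ms < 0.10))
})

test_that("fractional populations follow the amplitude-share formula", {
  amp <- tibble::tibble(t_fold = 10, component = 1:2, tau_ms = c(5, 50),
                        amplitude = c(2, 2))
  p <- fractional_populations(amp, p0 = 0)
  expect_equal(p$population[p$state != "SS"], c(0.5, 0.5))

  amp$amplitude <- c(1, 3)
  p <- fractional_populations(amp, p0 = 0.2)
  expect_equal(p$population[match(c("SS", "component_1", "component_2"),
                                  p$state)], c(0.2, 0.2, 0.6))

  set.seed(6)
  for (i in 1:20) {
    a <- tibble::tibble(t_fold = 1, component = 1:3,
                        tau_ms = c(1, 10, 100), amplitude = runif(3))
    p0 <- runif(1)
    p <- fractional_populations(a, p0)
    expect_equal(sum(p$population), 1, tolerance = 1e-12)
    expect_true(all(p$population >= 0 & p$population <= 1))
  }

  amp$amplitude <- c(0, 0)
  expect_error(fractional_populations(amp, 0.1), "all-zero")
})

test_that("P0 is the no-block share of uncensored events", {
  ev <- tibble::tibble(
    t_fold_s = 10,
    event_class = rep(c("no_block", "single_level"), c(10, 90)),
    censored = FALSE
  )
  expect_equal(p0_from_events(ev, 10), 0.1)
  ev$event_class <- "no_block"
  expect_equal(p0_from_events(ev, 10), 1.0)
  expect_error(p0_from_events(ev, 60), "no events")
})
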