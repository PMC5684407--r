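quiet_model <- function(...) trace_model(noise_sd = 0, rc_time_ms = 0, ...)

test_that("noiseless plateaus segment and label exactly", {
  m <- quiet_model()
  # two-plateau pseudoknot signature: Level-3 then Level-4
  x <- c(rep(9.2, 400), rep(3.0, 120))
  segs <- segment_levels(x, m)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$label, c("Level-3", "Level-4"))
  expect_equal(segs$start_index, c(0, 400))
  expect_equal(segs$end_index, c(400, 520))
  expect_equal(classify_event(segs), "two_level")

  # constant open-pore trace
  open <- segment_levels(rep(100, 300), m)
  expect_equal(nrow(open), 1)
  expect_equal(open$label, "open")
  expect_equal(classify_event(open), "no_block")

  expect_error(segment_levels(numeric(1), m), "too short")
})

test_that("classification is order-sensitive and conservative", {
  seg <- function(labels, frac) {
    tibble::tibble(start_index = seq_along(labels) - 1,
                   end_index = seq_along(labels),
                   mean_fraction = frac, label = labels)
  }
  expect_equal(classify_event(seg(c("Level-4", "Level-3"), c(3, 9.2))),
               "unclassified")
  expect_equal(classify_event(seg("Level-1", 18.6)), "single_level")
  expect_equal(classify_event(seg("open", 100)), "no_block")
  expect_equal(classify_event(seg(c("Level-3", "Level-4", "Level-3"),
                                  c(9.2, 3, 9.2))), "unclassified")
})

test_that("unfolding duration is the switch-to-block-end interval", {
  segs <- tibble::tibble(start_index = c(0, 20000),
                         end_index = c(20000, 22000),
                         mean_fraction = c(9.2, 100),
                         label = c("Level-3", "open"))
  expect_equal(extract_unfolding_duration(segs, 20000), 1000)

  # two-level events include both dwells
  segs2 <- tibble::tibble(start_index = c(0, 16000, 20000),
                          end_index = c(16000, 20000, 22000),
                          mean_fraction = c(9.2, 3.0, 100),
                          label = c("Level-3", "Level-4", "open"))
  expect_equal(extract_unfolding_duration(segs2, 20000), 1000)

  open_only <- tibble::tibble(start_index = 0, end_index = 10,
                              mean_fraction = 100, label = "open")
  expect_error(extract_unfolding_duration(open_only, 20000), "no blocked")
})

test_that("synthesis round-trips at zero noise within one sample", {
  ev <- tibble::tibble(event_id = 1:2, true_state = c("PK", "HP2"),
                       event_class = c("two_level", "single_level"),
                       unfolding_duration_ms = c(12, 8))
  m <- quiet_model()
  syn <- synthesize_trace(ev, m, seed = 1)
  for (i in 1:2) {
    segs <- segment_levels(syn$traces[[i]], m)
    truth <- syn$truth[syn$truth$event_id == i, ]
    blocked_truth <- truth[truth$label != "open", ]
    blocked_got <- segs[!segs$label %in% "open", ]
    expect_equal(nrow(blocked_got), nrow(blocked_truth))
    expect_true(all(abs(blocked_got$end_index - blocked_truth$end_index) <= 1))
    dur <- extract_unfolding_duration(segs, m$sampling_rate_hz)
    expect_lt(abs(dur - ev$unfolding_duration_ms[i]),
              1.5 / m$sampling_rate_hz * 1000)
  }
  # zero noise, one two-level event: exactly two plateau values in the block
  pk <- syn$traces[[1]]
  blocked <- pk$samples[pk$samples < 50]
  expect_equal(sort(unique(round(blocked, 6))), c(3.0, 9.2))
})

test_that("noisy synthesized events recover boundaries within 5 samples", {
  ev <- tibble::tibble(event_id = 1, true_state = "PK",
                       event_class = "two_level",
                       unfolding_duration_ms = 20)
  m <- trace_model(noise_sd = 0.5, rc_time_ms = 1)
  syn <- synthesize_trace(ev, m, seed = 4)
  segs <- segment_levels(syn$traces[[1]], m)
  blocked <- segs[!segs$label %in% c("open", "unassigned"), ]
  truth <- syn$truth[syn$truth$label != "open", ]
  expect_equal(blocked$label, truth$label)
  # boundaries after the masked RC window line up with ground truth
  expect_true(all(abs(blocked$end_index - truth$end_index) <= 5))
})

test_that("segmentation + classification reproduce generator labels", {
  set.seed(77)
  n <- 500
  states <- sample(c("HP1", "HP2", "TS", "PK", "SS"), n, replace = TRUE,
                   prob = c(0.25, 0.25, 0.2, 0.2, 0.1))
  # durations floored above the resolvable-dwell limit (the real pipeline
  # censors events whose sub-dwells fall below the detector resolution)
  tau <- c(HP1 = 6, HP2 = 10, TS = 15, PK = 25)
  dur <- rep(NA_real_, n)
  folded <- states != "SS"
  dur[folded] <- pmax(stats::rexp(sum(folded), 1 / tau[states[folded]]), 4)
  ev <- tibble::tibble(
    event_id = seq_len(n), true_state = states,
    event_class = vapply(states, function(s) {
      if (s == "SS") "no_block"
      else if (s %in% c("HP1", "HP2")) "single_level" else "two_level"
    }, character(1)),
    unfolding_duration_ms = dur
  )
  m <- trace_model(noise_sd = 0.5, rc_time_ms = 0, sampling_rate_hz = 20000)
  syn <- synthesize_trace(ev, m, seed = 78)
  got <- purrr::map_chr(syn$traces, function(tr) {
    classify_event(segment_levels(tr, m))
  })
  expect_gte(mean(got == ev$event_class), 0.99)

  blocked <- which(ev$event_class != "no_block" & got == ev$event_class)
  err <- purrr::map_dbl(blocked, function(i) {
    segs <- segment_levels(syn$traces[[i]], m)
    extract_unfolding_duration(segs, m$sampling_rate_hz) -
      ev$unfolding_duration_ms[i]
  })
  expect_lt(abs(mean(err)), 0.5)
})
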