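#' Configuration for the synthetic event generator
#'
#' Bundles everything needed to emulate a snapshot experiment: the kinetic
#' scheme, the programmed folding-time grid, the number of captured
#' molecules per folding time, the mean unfolding duration of each captured
#' state, the non-participating buffer fraction SS0, and the dead-time
#' censoring threshold.
#'
#' @param scheme A [kinetic_scheme()]. Default [default_scheme()].
#' @param folding_times Folding times in seconds. Default
#'   `c(1, 2, 5, 10, 30, 60)`, the experimental grid.
#' @param events_per_time Captured molecules per folding time. Default 578,
#'   the event count of the 10-s wild-type snapshot.
#' @param tau_map Named numeric vector: mean unfolding duration (ms) per
#'   captured state. The initial (single-stranded) state gives no block and
#'   needs no entry. Default `c(HP1 = 2.5, HP2 = 20, TS = 210, PK = 3500)`.
#' @param ss0_fraction Fraction of molecules that never participate in
#'   folding (buffer state SS0), in `[0, 1)`. Default 0.042.
#' @param dead_time_ms Durations below this are flagged censored and dropped
#'   downstream. Default 0.5 ms.
#' @param master_seed Integer master seed; all per-event randomness derives
#'   from it. Default 1.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(scheme = default_scheme(),
                             folding_times = c(1, 2, 5, 10, 30, 60),
                             events_per_time = 578,
                             tau_map = c(HP1 = 2.5, HP2 = 20, TS = 210, PK = 3500),
                             ss0_fraction = 0.042,
                             dead_time_ms = 0.5,
                             master_seed = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(folding_times <= 0)) stop("folding_times must be > 0", call. = FALSE)
  if (events_per_time < 1) stop("events_per_time must be >= 1", call. = FALSE)
  if (any(tau_map <= 0)) stop("all tau values must be > 0", call. = FALSE)
  if (ss0_fraction < 0 || ss0_fraction >= 1) {
    stop("ss0_fraction must be in [0, 1)", call. = FALSE)
  }
  if (dead_time_ms < 0) stop("dead_time_ms must be >= 0", call. = FALSE)
  missing_tau <- setdiff(setdiff(scheme$states, scheme$initial_state),
                         names(tau_map))
  if (length(missing_tau) > 0) {
    stop("tau_map missing captured state(s): ",
         paste(missing_tau, collapse = ", "), call. = FALSE)
  }
  structure(
    list(scheme = scheme, folding_times = folding_times,
         events_per_time = as.integer(events_per_time), tau_map = tau_map,
         ss0_fraction = ss0_fraction, dead_time_ms = dead_time_ms,
         master_seed = as.integer(master_seed)),
    class = "generator_config"
  )
}

# deterministic per-event sub-seed from (master seed, counter); < 2^31
.sub_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) * 48271 + as.double(counter) * 69621) %%
               2147483587)
}

#' Simulate one exact stochastic trajectory
#'
#' Gillespie realisation of the scheme's continuous-time Markov chain: the
#' waiting time in state j is exponential with the total exit rate
#' \eqn{\sum_i k_{j \to i}}, and the next state is chosen with probability
#' proportional to its rate. States with no positive exit rate persist.
#'
#' @param scheme A [kinetic_scheme()].
#' @param t_end End of the simulated interval (seconds, > 0).
#' @param seed Optional integer seed for this trajectory.
#' @return A tibble with columns `state`, `entry_time_s`, starting at
#'   `(initial_state, 0)` with strictly increasing entry times.
#' @export
simulate_trajectory <- function(scheme, t_end, seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- scheme$transitions[scheme$transitions$rate > 0, ]
  out_by_state <- split(tr, tr$from)
  state <- scheme$initial_state
  t <- 0
  states <- character(0)
  times <- numeric(0)
  states[1] <- state
  times[1] <- 0
  k <- 1L
  repeat {
    edges <- out_by_state[[state]]
    if (is.null(edges) || nrow(edges) == 0) break
    total <- sum(edges$rate)
    t <- t + stats::rexp(1, total)
    if (t >= t_end) break
    state <- if (nrow(edges) == 1) edges$to else
      sample(edges$to, 1, prob = edges$rate)
    k <- k + 1L
    states[k] <- state
    times[k] <- t
  }
  tibble::tibble(state = states, entry_time_s = times)
}

#' State occupied at a given time
#'
#' @param traj A trajectory from [simulate_trajectory()].
#' @param t Time in seconds (>= 0). Entry times are inclusive: at the exact
#'   moment of a jump the new state is returned.
#' @return The state label occupied at `t` (the last state beyond the final
#'   jump).
#' @export
state_at_time <- function(traj, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  traj$state[findInterval(t, traj$entry_time_s)]
}

#' Draw an unfolding duration for a captured state
#'
#' The single-stranded initial state produces an open pore (no block); every
#' other state emits an exponentially distributed unfolding duration with
#' its state-specific mean.
#'
#' @param state State label.
#' @param tau_map Named vector of mean durations (ms) for captured states.
#' @param seed Optional integer seed.
#' @param ss_state Label of the no-block state. Default `"SS"`.
#' @return Duration in ms, or `NA_real_` for the no-block state.
#' @export
sample_unfolding_duration <- function(state, tau_map, seed = NULL,
                                      ss_state = "SS") {
  if (!is.null(seed)) set.seed(seed)
  if (state == ss_state) return(NA_real_)
  if (!state %in% names(tau_map)) {
    stop("no unfolding time constant configured for state ", state,
         call. = FALSE)
  }
  stats::rexp(1, 1 / tau_map[[state]])
}

.class_of_state <- function(state, ss_state = "SS") {
  if (state == ss_state) "no_block"
  else if (state %in% c("TS", "PK")) "two_level"
  else "single_level"
}

#' Generate a synthetic snapshot event table
#'
#' For each programmed folding time, simulates `events_per_time` captured
#' molecules: a Bernoulli `ss0_fraction` of molecules belong to the
#' non-participating buffer state and always read out as no-block; the rest
#' follow a Gillespie trajectory of the scheme, are sampled at the folding
#' time, and (if folded) emit an exponential unfolding duration. Durations
#' below the dead time are flagged `censored`. The table is byte-identical
#' for identical `master_seed`.
#'
#' @param cfg A [generator_config()].
#' @return A tibble with columns `event_id`, `t_fold_s`, `true_state`,
#'   `event_class` (`no_block` / `single_level` / `two_level`),
#'   `unfolding_duration_ms` (`NA` for no-block events) and `censored`.
#' @export
generate_event_table <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  ss <- cfg$scheme$initial_state
  counter <- 0L
  rows <- purrr::map(cfg$folding_times, function(tf) {
    purrr::map(seq_len(cfg$events_per_time), function(i) {
      counter <<- counter + 1L
      set.seed(.sub_seed(cfg$master_seed, counter))
      buffered <- stats::runif(1) < cfg$ss0_fraction
      state <- if (buffered) ss else {
        traj <- simulate_trajectory(cfg$scheme, tf)
        state_at_time(traj, tf)
      }
      dur <- if (state == ss) NA_real_ else
        sample_unfolding_duration(state, cfg$tau_map, ss_state = ss)
      tibble::tibble(
        event_id = counter,
        t_fold_s = tf,
        true_state = state,
        event_class = .class_of_state(state, ss),
        unfolding_duration_ms = dur,
        censored = !is.na(dur) && dur < cfg$dead_time_ms
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "generator") <- list(master_seed = cfg$master_seed,
                                 ss0_fraction = cfg$ss0_fraction,
                                 dead_time_ms = cfg$dead_time_ms)
  out
}

#' Draw unfolding durations directly from an exponential mixture
#'
#' Bypasses the trajectory stage: samples each event's state from fixed
#' mixture weights and its duration from that state's exponential. Used for
#' recovery studies at a single snapshot (fixed folding time).
#'
#' @param n Number of events.
#' @param tau_ms Component mean durations (ms).
#' @param weights Mixture weights (normalised internally).
#' @param dead_time_ms Durations below this are dropped (censored).
#' @param seed Optional integer seed.
#' @return A tibble with columns `component`, `unfolding_duration_ms`,
#'   censored draws already removed.
#' @export
sample_mixture_durations <- function(n, tau_ms, weights = NULL,
                                     dead_time_ms = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weights)) weights <- rep(1, length(tau_ms))
  stopifnot(length(weights) == length(tau_ms), all(tau_ms > 0),
            all(weights >= 0), sum(weights) > 0)
  comp <- sample.int(length(tau_ms), n, replace = TRUE, prob = weights)
  dur <- stats::rexp(n, 1 / tau_ms[comp])
  keep <- dur >= dead_time_ms
  tibble::tibble(component = comp[keep], unfolding_duration_ms = dur[keep])
}

#' Read / write a snapshot event table as TSV
#'
#' @param events An event tibble from [generate_event_table()].
#' @param path Output file path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns the event tibble (the generator-only `true_state` column is
#'   optional in user files).
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- tibble::as_tibble(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  )
  need <- c("t_fold_s", "event_class", "unfolding_duration_ms")
  if (!all(need %in% names(out))) {
    stop("event table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"censored" %in% names(out)) out$censored <- FALSE
  out
}
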