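# small fixture builders shared across test files

two_state_scheme <- function(k_fwd = 2, k_rev = 3) {
  kinetic_scheme(
    data.frame(from = c("SS", "PK"), to = c("PK", "SS"),
               rate = c(k_fwd, k_rev))
  )
}

irreversible_scheme <- function(k = 1) {
  kinetic_scheme(data.frame(from = "SS", to = "PK", rate = k))
}

# random connected scheme on n states: a random spanning chain plus extra
# random directed edges, all rates positive
random_scheme <- function(n_states, seed) {
  set.seed(seed)
  states <- c("SS", paste0("X", seq_len(n_states - 1)))
  chain <- data.frame(from = states[-n_states], to = states[-1],
                      rate = stats::runif(n_states - 1, 0.05, 5))
  back <- data.frame(from = states[-1], to = states[-n_states],
                     rate = stats::runif(n_states - 1, 0.05, 5))
  tr <- rbind(chain, back)
  extra <- max(0, stats::rpois(1, n_states - 2))
  for (i in seq_len(extra)) {
    pair <- sample(states, 2)
    if (!any(tr$from == pair[1] & tr$to == pair[2])) {
      tr <- rbind(tr, data.frame(from = pair[1], to = pair[2],
                                 rate = stats::runif(1, 0.05, 5)))
    }
  }
  kinetic_scheme(tr, states = states)
}

# independent oracle: populations via Matrix scaling-and-squaring expm
expm_populations <- function(scheme, times, initial = NULL) {
  m <- rate_matrix(scheme)
  if (is.null(initial)) initial <- as.numeric(scheme$states == scheme$initial_state)
  vapply(times, function(t) as.numeric(Matrix::expm(m * t) %*% initial),
         numeric(length(scheme$states)))
}

# noiseless log-binned histogram whose per-bin masses equal the exact
# mixture bin integrals (scaled to a nominal event count)
noiseless_histogram <- function(tau_ms, amplitude, n_nominal = 1e5,
                                t_fold = NA_real_) {
  h <- log_histogram(tau_ms, t_fold = t_fold)  # bin grid only
  mass <- rowSums(vapply(seq_along(tau_ms), function(i) {
    amplitude[i] * (exp(-h$bin_lo_ms / tau_ms[i]) -
                      exp(-h$bin_hi_ms / tau_ms[i]))
  }, numeric(nrow(h))))
  h$density <- mass
  h$count <- round(mass * n_nominal)
  attr(h, "total_events") <- n_nominal
  h
}
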