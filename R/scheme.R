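#' Define a folding kinetic scheme
#'
#' A kinetic scheme is a continuous-time Markov chain over a small set of
#' discrete folding states (for the wild-type pseudoknot: `SS`, `HP1`, `HP2`,
#' `TS`, `PK`) with first-order rate constants on directed edges.
#'
#' @param transitions A data frame with columns `from`, `to` and `rate`
#'   (per second, finite and >= 0). Each row is one directed transition.
#' @param states Ordered character vector of state labels. Defaults to the
#'   states appearing in `transitions` (in order of first appearance).
#' @param initial_state Label of the state every molecule starts in.
#'   Default `"SS"` if present, otherwise the first state.
#'
#' @return An object of class `kinetic_scheme`: a list with elements
#'   `states`, `transitions` (tibble `from`, `to`, `rate`) and
#'   `initial_state`.
#' @seealso [default_scheme()], [rate_matrix()], [solve_populations()]
#' @export
#' @examples
#' kinetic_scheme(data.frame(from = c("SS", "PK"), to = c("PK", "SS"),
#'                           rate = c(2, 3)))
kinetic_scheme <- function(transitions, states = NULL, initial_state = NULL) {
  stopifnot(is.data.frame(transitions))
  need <- c("from", "to", "rate")
  if (!all(need %in% names(transitions))) {
    stop("`transitions` must have columns from, to, rate", call. = FALSE)
  }
  tr <- tibble::as_tibble(transitions[need])
  tr$from <- as.character(tr$from)
  tr$to <- as.character(tr$to)
  tr$rate <- as.numeric(tr$rate)
  if (is.null(states)) {
    states <- unique(c(rbind(tr$from, tr$to)))
  }
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state labels", call. = FALSE)
  unknown <- setdiff(unique(c(tr$from, tr$to)), states)
  if (length(unknown) > 0) {
    stop("transition references unknown state(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(tr$from == tr$to)) stop("self-transitions are not allowed", call. = FALSE)
  if (any(!is.finite(tr$rate)) || any(tr$rate < 0)) {
    stop("rate constants must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(paste(tr$from, tr$to))) {
    stop("duplicate (from, to) transition", call. = FALSE)
  }
  if (is.null(initial_state)) {
    initial_state <- if ("SS" %in% states) "SS" else states[[1]]
  }
  if (!initial_state %in% states) stop("unknown initial_state", call. = FALSE)
  structure(
    list(states = states, transitions = tr, initial_state = initial_state),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", length(x$states), " states: ",
      paste(x$states, collapse = ", "),
      " (initial: ", x$initial_state, ")\n", sep = "")
  print(x$transitions, n = nrow(x$transitions))
  invisible(x)
}

#' Default five-state pseudoknot folding scheme
#'
#' The wild-type topology: `SS <-> HP1`, `SS <-> HP2`, `HP1 <-> TS`,
#' `HP1 <-> PK`. HP2 exchanges only with SS (its fold shares no helix with
#' HP1/TS/PK, so direct transitions between HP2 and the other folded states
#' are excluded), and TS reaches the native PK only via HP1.
#'
#' The default rate constants reproduce the reported branching fractions
#' (SS: 84.7% to HP1 / 15.3% to HP2; HP1: 6.3% to PK, 18.1% to TS, 75.6%
#' back to SS) on a time scale where all states approach equilibrium near a
#' 60 s folding time.
#'
#' @param pk_reversible If `FALSE`, the PK -> HP1 back-rate is clamped to 0
#'   (irreversible native-state formation). Default `TRUE`.
#' @return A [kinetic_scheme()].
#' @export
#' @examples
#' default_scheme()
default_scheme <- function(pk_reversible = TRUE) {
  tr <- tibble::tribble(
    ~from,  ~to,   ~rate,
    "SS",   "HP1", 0.559,
    "SS",   "HP2", 0.101,
    "HP1",  "SS",  0.756,
    "HP1",  "TS",  0.181,
    "HP1",  "PK",  0.063,
    "HP2",  "SS",  0.050,
    "TS",   "HP1", 0.050,
    "PK",   "HP1", 0.010
  )
  if (!pk_reversible) tr$rate[tr$from == "PK"] <- 0
  kinetic_scheme(tr, states = c("SS", "HP1", "HP2", "TS", "PK"),
                 initial_state = "SS")
}

#' Build the master-equation rate matrix
#'
#' For a scheme over \eqn{\omega} states the population vector obeys
#' \eqn{dP/dt = M P} with off-diagonal \eqn{M_{ij} = k_{j \to i}} (column =
#' source state, row = destination) and diagonal
#' \eqn{M_{ii} = -\sum_{j \ne i} k_{i \to j}}. Columns therefore sum to
#' zero: total population is conserved.
#'
#' @param scheme A [kinetic_scheme()].
#' @return A square numeric matrix with state labels on both dimnames.
#' @export
#' @examples
#' rate_matrix(kinetic_scheme(data.frame(from = c("SS", "PK"),
#'                                       to = c("PK", "SS"), rate = c(2, 3))))
rate_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  s <- scheme$states
  m <- matrix(0, length(s), length(s), dimnames = list(s, s))
  tr <- scheme$transitions
  for (r in seq_len(nrow(tr))) {
    m[tr$to[r], tr$from[r]] <- m[tr$to[r], tr$from[r]] + tr$rate[r]
  }
  diag(m) <- diag(m) - colSums(m)
  m
}

#' Solve time-dependent state populations
#'
#' Solves \eqn{dP/dt = M P} spectrally: with eigenpairs
#' \eqn{(\lambda_\mu, n_\mu)} of the rate matrix and coefficients
#' \eqn{c_\mu} fixed by the initial populations,
#' \eqn{P(t) = \sum_\mu c_\mu n_\mu e^{\lambda_\mu t}}. If the
#' eigendecomposition is ill-conditioned (defective or near-defective
#' matrix) the solver falls back to a scaling-and-squaring matrix
#' exponential and flags this in the `"diagnostics"` attribute.
#'
#' @param scheme A [kinetic_scheme()] or a rate matrix from [rate_matrix()].
#' @param times Numeric vector of folding times in seconds (>= 0).
#' @param initial Named or unnamed numeric vector of initial populations
#'   (non-negative, summing to 1). Defaults to all mass in the scheme's
#'   initial state (or the first state for a bare matrix).
#' @return A tibble with columns `time_s`, `state`, `population`
#'   (long format; `population` in `[0, 1]`, summing to 1 at each time).
#'   The attribute `"diagnostics"` records whether the expm fallback ran.
#' @export
#' @examples
#' solve_populations(default_scheme(), times = c(0, 1, 10, 60))
solve_populations <- function(scheme, times, initial = NULL) {
  m <- if (inherits(scheme, "kinetic_scheme")) rate_matrix(scheme) else as.matrix(scheme)
  s <- rownames(m)
  if (is.null(s)) s <- paste0("S", seq_len(nrow(m)))
  if (is.null(initial)) {
    init_state <- if (inherits(scheme, "kinetic_scheme")) scheme$initial_state else s[[1]]
    initial <- as.numeric(s == init_state)
  }
  if (!is.null(names(initial))) initial <- initial[s]
  initial <- as.numeric(initial)
  if (length(initial) != nrow(m) || any(is.na(initial)) || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-8) {
    stop("`initial` must be a non-negative vector over the states summing to 1",
         call. = FALSE)
  }
  times <- as.numeric(times)
  if (any(times < 0)) stop("negative times are not allowed", call. = FALSE)

  sol <- .pop_matrix(m, initial, times)
  p_t <- sol$p
  fallback <- sol$fallback

  out <- tibble::tibble(
    time_s = rep(times, each = length(s)),
    state = factor(rep(s, length(times)), levels = s),
    population = as.numeric(p_t)
  )
  attr(out, "diagnostics") <- list(expm_fallback = fallback)
  class(out) <- c("population_kinetics", class(out))
  out
}

# matrix-only solver core: states x times population matrix with spectral
# path and expm fallback; kept free of data-frame overhead so optimisation
# loops can call it directly
.pop_matrix <- function(m, initial, times) {
  fallback <- FALSE
  p_t <- tryCatch({
    eg <- eigen(m)
    v <- eg$vectors
    # solve() errors on a singular (defective) eigenbasis -> expm fallback
    cmu <- solve(v, initial)
    out <- vapply(times, function(t) {
      p <- (v %*% (cmu * exp(eg$values * t)))[, 1]
      if (is.complex(p) && max(abs(Im(p))) > 1e-8) {
        stop("large imaginary residue")
      }
      Re(p)
    }, numeric(nrow(m)))
    out
  }, error = function(e) {
    fallback <<- TRUE
    vapply(times, function(t) {
      as.numeric(Matrix::expm(m * t) %*% initial)
    }, numeric(nrow(m)))
  })
  p_t <- matrix(p_t, nrow = nrow(m))
  p_t[p_t < 0 & p_t > -1e-9] <- 0
  if (any(p_t < -1e-9) || any(abs(colSums(p_t) - 1) > 1e-6)) {
    # spectral path numerically unacceptable: use the matrix exponential
    fallback <- TRUE
    p_t <- vapply(times, function(t) {
      as.numeric(Matrix::expm(m * t) %*% initial)
    }, numeric(nrow(m)))
    p_t <- matrix(p_t, nrow = nrow(m))
    p_t[p_t < 0 & p_t > -1e-9] <- 0
  }
  p_t <- sweep(p_t, 2, colSums(p_t), "/")
  list(p = p_t, fallback = fallback)
}

#' Pivot population kinetics to wide form
#'
#' @param populations A long tibble from [solve_populations()] (columns
#'   `time_s`, `state`, `population`).
#' @return A tibble with `time_s` and one column per state.
#' @export
populations_wide <- function(populations) {
  tidyr::pivot_wider(
    tibble::as_tibble(populations)[c("time_s", "state", "population")],
    names_from = "state", values_from = "population"
  )
}

#' Equilibrium state distribution
#'
#' The normalised null eigenvector of the rate matrix: the limit of
#' [solve_populations()] as folding time grows without bound.
#'
#' @inheritParams solve_populations
#' @return A named numeric vector of equilibrium populations (sums to 1).
#' @export
#' @examples
#' equilibrium_distribution(default_scheme())
equilibrium_distribution <- function(scheme) {
  m <- if (inherits(scheme, "kinetic_scheme")) rate_matrix(scheme) else as.matrix(scheme)
  s <- rownames(m)
  if (is.null(s)) s <- paste0("S", seq_len(nrow(m)))
  unreachable <- .unreachable_states(m)
  if (length(unreachable) > 0) {
    stop("scheme is not connected; unreachable state(s): ",
         paste(s[unreachable], collapse = ", "), call. = FALSE)
  }
  eg <- eigen(m)
  i0 <- which.min(abs(Re(eg$values)))
  if (abs(Re(eg$values[i0])) > 1e-9 * max(1, max(abs(m)))) {
    stop("no zero eigenvalue found; invalid rate matrix", call. = FALSE)
  }
  v <- Re(eg$vectors[, i0])
  v <- v / sum(v)
  if (any(v < -1e-9)) stop("negative equilibrium population; invalid scheme",
                           call. = FALSE)
  v[v < 0] <- 0
  stats::setNames(v / sum(v), s)
}

# states not reachable (in the undirected sense, via nonzero rates) from state 1
.unreachable_states <- function(m) {
  adj <- (m != 0) | (t(m) != 0)
  diag(adj) <- TRUE
  seen <- rep(FALSE, nrow(m))
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(!seen)
}

#' Branching fractions out of a state
#'
#' The probability that the next transition out of `from_state` goes to each
#' neighbour: \eqn{k_{from \to to} / \sum k_{from \to \cdot}}.
#'
#' @param scheme A [kinetic_scheme()].
#' @param from_state State label with at least one positive outgoing rate.
#' @return A tibble with columns `from`, `to`, `rate`, `fraction`
#'   (fractions sum to 1).
#' @export
#' @examples
#' branching_fractions(default_scheme(), "HP1")
branching_fractions <- function(scheme, from_state) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  out <- dplyr::filter(scheme$transitions, .data$from == from_state)
  if (nrow(out) == 0 || sum(out$rate) <= 0) {
    stop("state ", from_state, " has no positive outgoing transitions",
         call. = FALSE)
  }
  dplyr::mutate(out, fraction = .data$rate / sum(.data$rate))
}

#' Read / write a kinetic scheme as YAML or JSON
#'
#' The on-disk format lists `states`, `initial_state` and `transitions`
#' (each with `from`, `to`, `rate_per_s`).
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param scheme A [kinetic_scheme()].
#' @return `read_scheme()` returns a [kinetic_scheme()];
#'   `write_scheme()` returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tr <- if (is.data.frame(x$transitions)) {
    tibble::tibble(from = as.character(x$transitions$from),
                   to = as.character(x$transitions$to),
                   rate = as.numeric(x$transitions$rate_per_s))
  } else {
    tibble::tibble(
      from = vapply(x$transitions, function(e) as.character(e$from),
                    character(1)),
      to = vapply(x$transitions, function(e) as.character(e$to), character(1)),
      rate = vapply(x$transitions, function(e) as.numeric(e$rate_per_s),
                    numeric(1))
    )
  }
  kinetic_scheme(tr, states = x$states, initial_state = x$initial_state)
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  tr <- scheme$transitions
  x <- list(
    states = scheme$states,
    initial_state = scheme$initial_state,
    transitions = lapply(seq_len(nrow(tr)), function(i) {
      list(from = tr$from[i], to = tr$to[i], rate_per_s = tr$rate[i])
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
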