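#' Configuration for the master-equation rate fit
#'
#' @param scheme A [kinetic_scheme()] giving the topology whose rates are to
#'   be estimated (the `rate` column supplies optional initial values; edges
#'   with `free = FALSE` in `fixed_edges` are held at their value).
#' @param fixed_edges Optional data frame `from`, `to` of edges to hold
#'   fixed at the scheme's rate (e.g. clamping a back-rate to 0).
#' @param rate_bounds Two-element bounds (per second) for free rates.
#'   Default `c(1e-4, 1e3)`; the search runs on a log scale.
#' @param ss0_bounds Bounds for the buffer fraction SS0. Default
#'   `c(0, 0.25)`.
#' @param ss0_init Initial SS0. Default 0.05. Set `ss0_fixed = TRUE` to
#'   freeze it.
#' @param ss0_fixed Treat SS0 as fixed rather than fitted. Default `FALSE`.
#' @param n_starts Number of multi-start local optimisations. Default 50.
#' @param seed Integer seed for start generation (and the GA stage).
#' @param use_ga Also run a seeded genetic-algorithm stage and keep the
#'   better optimum (cross-check of the multi-start result). Default
#'   `FALSE`.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(scheme = default_scheme(), fixed_edges = NULL,
                       rate_bounds = c(1e-4, 1e3), ss0_bounds = c(0, 0.25),
                       ss0_init = 0.05, ss0_fixed = FALSE,
                       n_starts = 50L, seed = 1L, use_ga = FALSE) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            length(rate_bounds) == 2, rate_bounds[1] > 0,
            rate_bounds[1] < rate_bounds[2],
            ss0_bounds[1] >= 0, ss0_bounds[1] <= ss0_bounds[2],
            n_starts >= 1)
  structure(
    list(scheme = scheme, fixed_edges = fixed_edges,
         rate_bounds = rate_bounds, ss0_bounds = ss0_bounds,
         ss0_init = ss0_init, ss0_fixed = ss0_fixed,
         n_starts = as.integer(n_starts), seed = as.integer(seed),
         use_ga = use_ga),
    class = "fit_config"
  )
}

#' Effective single-stranded population after buffer correction
#'
#' A fraction SS0 of molecules never participates in folding and inflates
#' the apparent no-block population; the effective SS population is the
#' apparent value minus SS0 (clipped at zero). Downstream comparison
#' renormalises the participating ensemble to `1 - ss0`.
#'
#' @param apparent_ss Apparent (measured) SS population(s) in `[0, 1]`.
#' @param ss0 Buffer fraction in `[0, 1]`.
#' @return `pmax(apparent_ss - ss0, 0)`; warns if the subtraction clips.
#' @export
effective_ss_population <- function(apparent_ss, ss0) {
  stopifnot(all(apparent_ss >= 0 & apparent_ss <= 1), ss0 >= 0, ss0 <= 1)
  if (any(apparent_ss < ss0)) {
    warning("apparent SS population below ss0; clipping to 0 ",
            "(model inconsistency)", call. = FALSE)
  }
  pmax(apparent_ss - ss0, 0)
}

# apparent (measured) populations -> participating-ensemble populations
.correct_populations <- function(p_wide, ss0, ss_label) {
  w <- p_wide
  if (ss0 >= 1) stop("ss0 must be < 1", call. = FALSE)
  w[[ss_label]] <- pmax(w[[ss_label]] - ss0, 0)
  states <- setdiff(names(w), "time_s")
  tot <- rowSums(w[states])
  for (s in states) w[[s]] <- w[[s]] / tot
  w
}

#' RMSD fitness between measured and predicted population kinetics
#'
#' \deqn{F = \sqrt{\sum_i \sum_t (P_E^{(i)}(t) - P_T^{(i)}(t))^2 / N}}
#' where the sums run over states and folding times and N is the total
#' number of (state, time) data points.
#'
#' @param p_e,p_t Population tibbles (long, columns `time_s`, `state`,
#'   `population`) on identical (state, time) grids.
#' @return The scalar fitness F (>= 0; 0 iff the inputs agree exactly).
#' @export
fitness <- function(p_e, p_t) {
  e <- tibble::as_tibble(p_e)[c("time_s", "state", "population")]
  t <- tibble::as_tibble(p_t)[c("time_s", "state", "population")]
  j <- dplyr::full_join(e, t, by = c("time_s", "state"),
                        suffix = c("_e", "_t"))
  miss <- j[is.na(j$population_e) | is.na(j$population_t), ]
  if (nrow(miss) > 0) {
    stop("population grids do not match; missing (state, time) pairs: ",
         paste(paste0(miss$state, "@", miss$time_s), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(j) == 0) stop("empty population grids", call. = FALSE)
  sqrt(sum((j$population_e - j$population_t)^2) / nrow(j))
}

#' Fit transition rate constants to population kinetics
#'
#' Estimates the scheme's rate constants (and, by default, the buffer
#' fraction SS0) by minimising the RMSD fitness between the measured
#' populations (buffer-corrected and renormalised) and master-equation
#' predictions started from the pure single-stranded state. Rates are
#' parameterised on a log scale within bounds; optimisation is multi-start
#' bounded quasi-Newton ([stats::nlminb()]) with log-uniform random starts,
#' optionally cross-checked by a compact seeded genetic algorithm.
#' Diagnostics include the per-start trace and the condition number of the
#' numerical Hessian at the optimum (large values signal poor
#' identifiability).
#'
#' @param p_e Measured population kinetics: long tibble `time_s`, `state`,
#'   `population` covering >= 2 folding times and all scheme states.
#' @param cfg A [fit_config()].
#' @return Object of class `rate_fit`: fitted `scheme` (rates replaced by
#'   estimates), `rates` tibble (`from`, `to`, `rate`, `free`),
#'   `ss0`, `fitness`, `predicted` populations on the data grid,
#'   `branching` tibble for every source state, `starts` per-start tibble,
#'   `hessian_condition`, `convergence` flag.
#' @export
fit_rates <- function(p_e, cfg = fit_config()) {
  stopifnot(inherits(cfg, "fit_config"))
  scheme <- cfg$scheme
  ss_label <- scheme$initial_state
  wide <- populations_wide(p_e)
  if (nrow(wide) < 2) stop("need >= 2 folding times", call. = FALSE)
  missing_states <- setdiff(scheme$states, names(wide))
  if (length(missing_states) > 0) {
    stop("populations missing state(s): ",
         paste(missing_states, collapse = ", "), call. = FALSE)
  }
  wide <- wide[c("time_s", scheme$states)]
  times <- wide$time_s

  tr <- scheme$transitions
  tr$free <- TRUE
  if (!is.null(cfg$fixed_edges)) {
    fx <- paste(cfg$fixed_edges$from, cfg$fixed_edges$to)
    tr$free[paste(tr$from, tr$to) %in% fx] <- FALSE
  }
  free_idx <- which(tr$free)
  nfree <- length(free_idx)
  lb_r <- log(cfg$rate_bounds[1]); ub_r <- log(cfg$rate_bounds[2])
  fit_ss0 <- !cfg$ss0_fixed
  npar <- nfree + as.integer(fit_ss0)

  # matrix-level objective: avoids data-frame plumbing inside the optimiser
  ns <- length(scheme$states)
  to_i <- match(tr$to, scheme$states)
  from_i <- match(tr$from, scheme$states)
  p_meas <- t(as.matrix(wide[scheme$states]))  # states x times (apparent)
  ss_i <- match(ss_label, scheme$states)
  p0_vec <- as.numeric(scheme$states == ss_label)
  build_m <- function(k) {
    m <- matrix(0, ns, ns)
    m[cbind(to_i, from_i)] <- k
    diag(m) <- diag(m) - colSums(m)
    m
  }
  obj <- function(theta) {
    k <- tr$rate
    k[free_idx] <- exp(theta[seq_len(nfree)])
    ss0 <- if (fit_ss0) theta[npar] else cfg$ss0_init
    pc <- p_meas
    pc[ss_i, ] <- pmax(pc[ss_i, ] - ss0, 0)
    pc <- sweep(pc, 2, colSums(pc), "/")
    pred <- .pop_matrix(build_m(k), p0_vec, times)$p
    sum((pc - pred)^2)
  }

  lower <- c(rep(lb_r, nfree), if (fit_ss0) cfg$ss0_bounds[1])
  upper <- c(rep(ub_r, nfree), if (fit_ss0) cfg$ss0_bounds[2])

  set.seed(cfg$seed)
  starts <- vector("list", cfg$n_starts)
  # first start: the scheme's own rates (if positive) and ss0_init
  th0 <- c(pmin(pmax(log(pmax(tr$rate[free_idx], cfg$rate_bounds[1])), lb_r),
                ub_r),
           if (fit_ss0) min(max(cfg$ss0_init, cfg$ss0_bounds[1]),
                            cfg$ss0_bounds[2]))
  starts[[1]] <- th0
  for (s in seq_len(cfg$n_starts)[-1]) {
    starts[[s]] <- c(stats::runif(nfree, log(1e-3), log(1e2)),
                     if (fit_ss0) stats::runif(1, cfg$ss0_bounds[1],
                                               cfg$ss0_bounds[2]))
  }

  run_start <- function(theta0) {
    tryCatch({
      f <- stats::nlminb(theta0, obj, lower = lower, upper = upper,
                         control = list(iter.max = 500, eval.max = 2000,
                                        rel.tol = 1e-12))
      # codes 7/8 ("singular"/"false" convergence) signal a stall on a flat
      # region of the objective -- the norm for weakly identified rate sets,
      # reported separately through the Hessian condition number; accept
      # them alongside clean codes
      ok <- f$convergence == 0 ||
        grepl("singular convergence|false convergence", f$message)
      list(par = f$par, value = f$objective, ok = ok)
    }, error = function(e) list(par = theta0, value = Inf, ok = FALSE))
  }
  results <- lapply(starts, run_start)

  if (isTRUE(cfg$use_ga)) {
    ga <- .ga_minimise(obj, lower, upper, seed = cfg$seed + 7L)
    polished <- run_start(ga$par)
    results <- c(results, list(polished))
  }

  values <- vapply(results, `[[`, numeric(1), "value")
  best <- results[[which.min(values)]]
  if (!any(vapply(results, `[[`, logical(1), "ok"))) {
    warning("no start reported clean convergence; returning best found",
            call. = FALSE)
  }

  k <- tr$rate
  k[free_idx] <- exp(best$par[seq_len(nfree)])
  ss0 <- if (fit_ss0) best$par[npar] else cfg$ss0_init
  fitted_scheme <- scheme
  fitted_scheme$transitions$rate <- k

  corrected <- .correct_populations(wide, ss0, ss_label)
  corrected_long <- tidyr::pivot_longer(corrected, -"time_s",
                                        names_to = "state",
                                        values_to = "population")
  pred <- solve_populations(fitted_scheme, times)
  f_val <- fitness(corrected_long, pred)

  hess_cond <- tryCatch({
    h <- stats::optimHess(best$par, obj)
    kappa(h, exact = TRUE)
  }, error = function(e) NA_real_)
  if (is.finite(hess_cond) && hess_cond > 1e10) {
    warning("ill-conditioned Hessian (condition number ",
            format(hess_cond, digits = 3),
            "); some parameters may be non-identifiable", call. = FALSE)
  }

  branching <- dplyr::bind_rows(lapply(
    unique(fitted_scheme$transitions$from[fitted_scheme$transitions$rate > 0]),
    function(s) branching_fractions(fitted_scheme, s)))

  structure(
    list(
      scheme = fitted_scheme,
      rates = dplyr::mutate(fitted_scheme$transitions, free = tr$free),
      ss0 = ss0,
      fitness = f_val,
      predicted = pred,
      measured_corrected = corrected_long,
      branching = branching,
      starts = tibble::tibble(start = seq_along(results),
                              objective = values,
                              converged = vapply(results, `[[`, logical(1),
                                                 "ok")),
      hessian_condition = hess_cond,
      convergence = best$ok,
      config = cfg
    ),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> fitness F = ", format(x$fitness, digits = 4),
      ", ss0 = ", format(x$ss0, digits = 3),
      ", Hessian condition = ", format(x$hessian_condition, digits = 3),
      "\n", sep = "")
  print(x$rates, n = nrow(x$rates))
  invisible(x)
}

#' Tidy a rate fit
#'
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return One row per transition: `from`, `to`, `rate`, `free`, plus the
#'   source-state branching `fraction` where defined.
#' @export
tidy.rate_fit <- function(x, ...) {
  dplyr::left_join(x$rates,
                   x$branching[c("from", "to", "fraction")],
                   by = c("from", "to"))
}

#' @rdname tidy.rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(
    fitness = x$fitness, ss0 = x$ss0,
    hessian_condition = x$hessian_condition,
    n_starts = nrow(x$starts),
    n_starts_converged = sum(x$starts$converged),
    convergence = x$convergence
  )
}

# compact real-coded genetic algorithm (tournament selection, blend
# crossover, Gaussian mutation); used as a seeded cross-check stage
.ga_minimise <- function(fn, lower, upper, seed = 1L, pop_size = 40L,
                         generations = 60L, p_mutate = 0.2) {
  set.seed(seed)
  np <- length(lower)
  pop <- t(replicate(pop_size, stats::runif(np, lower, upper)))
  fit <- apply(pop, 1, fn)
  for (g in seq_len(generations)) {
    newpop <- matrix(0, pop_size, np)
    elite <- which.min(fit)
    newpop[1, ] <- pop[elite, ]
    for (i in 2:pop_size) {
      pick <- function() {
        c2 <- sample.int(pop_size, 2)
        c2[which.min(fit[c2])]
      }
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      w <- stats::runif(np, -0.25, 1.25)
      child <- w * pa + (1 - w) * pb
      mut <- stats::runif(np) < p_mutate
      child[mut] <- child[mut] +
        stats::rnorm(sum(mut), 0, (upper[mut] - lower[mut]) / 10)
      newpop[i, ] <- pmin(pmax(child, lower), upper)
    }
    pop <- newpop
    fit <- apply(pop, 1, fn)
  }
  i <- which.min(fit)
  list(par = pop[i, ], value = fit[i])
}

#' Summarise a fitted scheme as a pathway report
#'
#' Collects the per-edge rates, per-source-state branching tables, the
#' equilibrium distribution, and every simple route from the initial state
#' to a target state ranked by path flux (the product of branching
#' fractions along the route).
#'
#' @param result A `rate_fit` (or a bare [kinetic_scheme()]).
#' @param target Destination state for route ranking. Default `"PK"` if
#'   present, else the last state.
#' @return A list of class `pathway_report`: `rates`, `branching`,
#'   `equilibrium`, `routes` (tibble `route`, `flux`, `flux_share`),
#'   `ss0`, `fitness`.
#' @export
pathway_report <- function(result, target = NULL) {
  scheme <- if (inherits(result, "rate_fit")) result$scheme else result
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (is.null(target)) {
    target <- if ("PK" %in% scheme$states) "PK" else
      scheme$states[length(scheme$states)]
  }
  sources <- unique(scheme$transitions$from[scheme$transitions$rate > 0])
  branching <- dplyr::bind_rows(lapply(sources, branching_fractions,
                                       scheme = scheme))
  frac <- stats::setNames(branching$fraction,
                          paste(branching$from, branching$to))
  # depth-first enumeration of simple paths initial -> target
  paths <- list()
  walk <- function(node, visited, acc) {
    if (node == target) {
      paths[[length(paths) + 1]] <<- acc
      return(invisible())
    }
    nxt <- branching$to[branching$from == node]
    for (v in setdiff(nxt, visited)) walk(v, c(visited, v), c(acc, v))
  }
  walk(scheme$initial_state, scheme$initial_state, scheme$initial_state)
  routes <- if (length(paths) == 0) {
    tibble::tibble(route = character(0), flux = numeric(0),
                   flux_share = numeric(0))
  } else {
    flux <- vapply(paths, function(p) {
      prod(frac[paste(p[-length(p)], p[-1])])
    }, numeric(1))
    tibble::tibble(route = vapply(paths, paste, character(1),
                                  collapse = " -> "),
                   flux = flux) |>
      dplyr::arrange(dplyr::desc(.data$flux)) |>
      dplyr::mutate(flux_share = .data$flux / sum(.data$flux))
  }
  structure(
    list(rates = scheme$transitions, branching = branching,
         equilibrium = equilibrium_distribution(scheme), routes = routes,
         ss0 = if (inherits(result, "rate_fit")) result$ss0 else NA_real_,
         fitness = if (inherits(result, "rate_fit")) result$fitness
                   else NA_real_),
    class = "pathway_report"
  )
}

#' @export
print.pathway_report <- function(x, ...) {
  cat("<pathway_report>\n")
  cat("Branching fractions:\n")
  print(x$branching, n = nrow(x$branching))
  cat("Routes to the native state (by flux share):\n")
  print(x$routes, n = nrow(x$routes))
  cat("Equilibrium populations:\n")
  print(round(x$equilibrium, 4))
  invisible(x)
}

#' Read / write population kinetics as TSV
#'
#' Wide format: `time_s` plus one column per state (optionally `sd_<state>`
#' columns, ignored on read into the long form).
#'
#' @param populations Long population tibble (`time_s`, `state`,
#'   `population`).
#' @param path File path.
#' @return `write_populations()` returns `path` invisibly;
#'   `read_populations()` returns a long tibble.
#' @export
write_populations <- function(populations, path) {
  utils::write.table(populations_wide(populations), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_populations
#' @export
read_populations <- function(path) {
  w <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  states <- setdiff(names(w), c("time_s", grep("^sd_", names(w), value = TRUE)))
  out <- tidyr::pivot_longer(tibble::as_tibble(w[c("time_s", states)]),
                             -"time_s", names_to = "state",
                             values_to = "population")
  out$state <- factor(out$state, levels = states)
  out
}
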