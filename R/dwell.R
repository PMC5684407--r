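#' Log-binned unfolding-duration histogram
#'
#' Bins durations on a log10(time) axis and normalises per-bin counts by the
#' total event count, so the per-bin masses N/N0 sum to 1 (the convention of
#' single-molecule lifetime histograms: the area of the histogram is the
#' total fractional population).
#'
#' @param durations_ms Positive, uncensored unfolding durations in ms.
#' @param bins_per_decade Bins per factor of 10 in time. Default 10.
#' @param range Two-element range in ms covered by the bin grid. Default
#'   `c(0.1, 1e5)`; widened automatically (on whole bins) if data fall
#'   outside it.
#' @param t_fold Optional folding-time label (seconds) carried along.
#' @return An object of class `log_histogram`: a tibble with columns
#'   `bin_lo_ms`, `bin_hi_ms`, `log10_mid`, `count`, `density` (= N/N0),
#'   with attributes `total_events` and `t_fold`.
#' @export
#' @examples
#' log_histogram(rexp(500, 1 / 20))
log_histogram <- function(durations_ms, bins_per_decade = 10,
                          range = c(0.1, 1e5), t_fold = NA_real_) {
  durations_ms <- as.numeric(durations_ms)
  if (length(durations_ms) == 0) stop("no durations supplied", call. = FALSE)
  if (any(!is.finite(durations_ms)) || any(durations_ms <= 0)) {
    stop("durations must be finite and > 0", call. = FALSE)
  }
  w <- 1 / bins_per_decade
  lo <- min(log10(range[1]), floor(log10(min(durations_ms)) / w) * w)
  hi <- max(log10(range[2]), ceiling(log10(max(durations_ms)) / w) * w)
  edges <- seq(lo, hi + w / 2, by = w)
  idx <- findInterval(log10(durations_ms), edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  n0 <- length(durations_ms)
  out <- tibble::tibble(
    bin_lo_ms = 10^edges[-length(edges)],
    bin_hi_ms = 10^edges[-1],
    log10_mid = (edges[-length(edges)] + edges[-1]) / 2,
    count = counts,
    density = counts / n0
  )
  attr(out, "total_events") <- n0
  attr(out, "t_fold") <- t_fold
  class(out) <- c("log_histogram", class(out))
  out
}

#' Log-time exponential mixture density
#'
#' On a log-time axis a single exponential lifetime with time constant
#' \eqn{\tau} has density (per unit \eqn{\ln t})
#' \deqn{f(t) = c\, e^{(\ln t - \ln\tau) - e^{(\ln t - \ln\tau)}},}
#' peaking at \eqn{t = \tau} with value \eqn{c/e}; the amplitude \eqn{c}
#' equals the area under the component. A mixture sums such terms.
#'
#' @param t_ms Evaluation times (ms, > 0).
#' @param tau_ms Component time constants (ms).
#' @param amplitude Component amplitudes (areas), same length as `tau_ms`.
#' @return Density values (per unit natural-log time) at `t_ms`.
#' @export
#' @examples
#' mixture_density(20, tau_ms = 20, amplitude = 1)  # 1/e
mixture_density <- function(t_ms, tau_ms, amplitude = rep(1, length(tau_ms))) {
  if (any(t_ms <= 0)) stop("t must be > 0", call. = FALSE)
  stopifnot(length(tau_ms) == length(amplitude))
  rowSums(matrix(vapply(seq_along(tau_ms), function(i) {
    x <- log(t_ms) - log(tau_ms[i])
    amplitude[i] * exp(x - exp(x))
  }, numeric(length(t_ms))), nrow = length(t_ms)))
}

# expected mixture mass in a time bin [lo, hi]: the integral of the log-time
# density over ln t has the closed form c * (exp(-lo/tau) - exp(-hi/tau))
.bin_mass <- function(lo_ms, hi_ms, tau_ms, amplitude) {
  rowSums(matrix(vapply(seq_along(tau_ms), function(i) {
    amplitude[i] * (exp(-lo_ms / tau_ms[i]) - exp(-hi_ms / tau_ms[i]))
  }, numeric(length(lo_ms))), nrow = length(lo_ms)))
}

#' Fit an exponential mixture to log-binned histograms
#'
#' Minimises weighted least squares between each histogram's per-bin mass
#' N/N0 and the mixture's exact per-bin integral (not the midpoint density),
#' using Levenberg-Marquardt on log-scale parameters with multiple starts
#' from log-spaced time-constant grids. In `"global"` mode the time
#' constants are shared across all histograms while amplitudes are fitted
#' per histogram (the global fit across folding times); `"single"` fits each
#' histogram independently. Per-bin weights use the Poisson variance of the
#' model-predicted bin count (Pearson weighting), which keeps sparse tail
#' bins from dominating. Bins below `dead_time_ms` are excluded so the fit
#' is consistent with dead-time censored data.
#'
#' An optional `method = "mle"` maximises the raw-duration likelihood of the
#' same mixture (dead-time truncated) as a cross-check; it requires raw
#' `durations` and ignores bin weights.
#'
#' @param histograms A [log_histogram()] or a list of them (one per folding
#'   time for a global fit).
#' @param n_components Number of exponential components (>= 1).
#' @param mode `"global"` (shared tau, per-histogram amplitudes) or
#'   `"single"`. With one histogram the two coincide.
#' @param seed Integer seed controlling multi-start jitter.
#' @param n_starts Number of optimisation starts. Default 8.
#' @param dead_time_ms Dead time below which bins are ignored. Default 0.5.
#' @param method `"ls"` (binned weighted least squares, default) or
#'   `"mle"`.
#' @param durations For `method = "mle"`: list of raw duration vectors
#'   matching `histograms`.
#' @return An object of class `mixture_fit` with elements `components`
#'   (tibble `component`, `tau_ms`), `amplitudes` (tibble `t_fold`,
#'   `component`, `tau_ms`, `amplitude`), `objective`, `converged`,
#'   `n_starts_converged`, `mode`, `method`.
#' @export
fit_mixture <- function(histograms, n_components, mode = c("global", "single"),
                        seed = 1L, n_starts = 8L, dead_time_ms = 0.5,
                        method = c("ls", "mle"), durations = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (inherits(histograms, "log_histogram")) histograms <- list(histograms)
  stopifnot(n_components >= 1, length(histograms) >= 1)
  if (mode == "single" && length(histograms) > 1) {
    fits <- lapply(seq_along(histograms), function(i) {
      fit_mixture(histograms[[i]], n_components, mode = "single",
                  seed = seed + i - 1L, n_starts = n_starts,
                  dead_time_ms = dead_time_ms, method = method,
                  durations = durations[i])
    })
    return(fits)
  }

  hs <- lapply(histograms, function(h) {
    # a bin straddling the dead time is partially censored and not modelled;
    # keep only bins entirely above it
    keep <- h$bin_lo_ms >= dead_time_ms * (1 - 1e-9)
    d <- h[keep, ]
    list(lo = d$bin_lo_ms, hi = d$bin_hi_ms, mass = d$density,
         count = d$count, t_fold = attr(h, "t_fold"),
         total = attr(h, "total_events"))
  })
  occupied <- min(vapply(hs, function(h) sum(h$count > 0), integer(1)))
  if (n_components > occupied) {
    stop("n_components (", n_components,
         ") exceeds occupied bins (", occupied, ")", call. = FALSE)
  }

  all_d <- unlist(lapply(hs, function(h) rep(sqrt(h$lo * h$hi), h$count)))
  tau_lo <- max(dead_time_ms, min(all_d) / 10, 1e-3)
  tau_hi <- 10 * max(all_d)
  nh <- length(hs)
  np <- n_components

  # theta = (log tau [np], log amplitude [np x nh]); weights carry the
  # Poisson variance proxy per histogram (expected counts, fixed per stage)
  weights <- lapply(hs, function(h) pmax(h$count, 1))
  resid_fun <- function(theta) {
    tau <- exp(theta[seq_len(np)])
    unlist(lapply(seq_len(nh), function(j) {
      a <- exp(theta[np + (j - 1) * np + seq_len(np)])
      mu <- .bin_mass(hs[[j]]$lo, hs[[j]]$hi, tau, a)
      (hs[[j]]$mass - mu) * hs[[j]]$total / sqrt(weights[[j]])
    }))
  }

  nll_fun <- function(theta) {
    tau <- exp(theta[seq_len(np)])
    sum(vapply(seq_len(nh), function(j) {
      a <- exp(theta[np + (j - 1) * np + seq_len(np)])
      w <- a / sum(a)
      x <- durations[[j]]
      x <- x[x >= dead_time_ms]
      dens <- vapply(seq_len(np), function(i) {
        w[i] * stats::dexp(x, 1 / tau[i]) /
          stats::pexp(dead_time_ms, 1 / tau[i], lower.tail = FALSE)
      }, numeric(length(x)))
      -sum(log(pmax(rowSums(dens), 1e-300)))
    }, numeric(1)))
  }

  set.seed(seed)
  lower <- c(rep(log(tau_lo), np), rep(log(1e-8), np * nh))
  upper <- c(rep(log(tau_hi), np), rep(log(10), np * nh))
  base_grid <- seq(log(tau_lo * 2), log(tau_hi / 10), length.out = np + 2)[2:(np + 1)]
  best <- NULL
  n_conv <- 0L
  for (s in seq_len(n_starts)) {
    tau0 <- base_grid + stats::rnorm(np, 0, if (s == 1) 0 else 0.6)
    tau0 <- pmin(pmax(sort(tau0), log(tau_lo)), log(tau_hi))
    a0 <- rep(log(pmax(mean(vapply(hs, function(h) sum(h$mass), numeric(1))) / np,
                       1e-4)), np * nh)
    theta0 <- c(tau0, a0)
    fit <- tryCatch({
      if (method == "ls") {
        f <- minpack.lm::nls.lm(theta0, lower = lower, upper = upper,
                                fn = resid_fun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200, ptol = 1e-12, ftol = 1e-12))
        list(par = f$par, value = sum(f$fvec^2),
             ok = f$info %in% c(1, 2, 3, 4))
      } else {
        if (is.null(durations)) {
          stop("method = 'mle' requires raw `durations`", call. = FALSE)
        }
        f <- stats::nlminb(theta0, nll_fun, lower = lower, upper = upper)
        list(par = f$par, value = f$objective, ok = f$convergence == 0)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$ok) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("mixture fit failed to converge from any start",
                          call. = FALSE)

  if (method == "ls") {
    # second stage: freeze the variance proxy at the stage-1 model's
    # expected counts and re-solve from the stage-1 optimum. Observed-count
    # weights bias tau low (empty tail bins carry full weight), parameter-
    # coupled expected-count weights bias it high; fixed expected-count
    # weights avoid both.
    tau1 <- exp(best$par[seq_len(np)])
    weights <- lapply(seq_len(nh), function(j) {
      a <- exp(best$par[np + (j - 1) * np + seq_len(np)])
      pmax(.bin_mass(hs[[j]]$lo, hs[[j]]$hi, tau1, a) * hs[[j]]$total, 1)
    })
    f2 <- tryCatch(
      minpack.lm::nls.lm(best$par, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(f2)) {
      best <- list(par = f2$par, value = sum(f2$fvec^2),
                   ok = best$ok || f2$info %in% c(1, 2, 3, 4))
    }
  }

  tau <- exp(best$par[seq_len(np)])
  ord <- order(tau)
  tau <- tau[ord]
  amp <- lapply(seq_len(nh), function(j) {
    exp(best$par[np + (j - 1) * np + seq_len(np)])[ord]
  })
  t_folds <- vapply(hs, function(h) {
    if (is.null(h$t_fold)) NA_real_ else as.numeric(h$t_fold)
  }, numeric(1))
  amplitudes <- dplyr::bind_rows(lapply(seq_len(nh), function(j) {
    tibble::tibble(t_fold = t_folds[j], component = seq_len(np),
                   tau_ms = tau, amplitude = amp[[j]])
  }))
  structure(
    list(
      components = tibble::tibble(component = seq_len(np), tau_ms = tau),
      amplitudes = amplitudes,
      objective = best$value,
      converged = best$ok,
      n_starts_converged = n_conv,
      mode = mode, method = method,
      n_histograms = nh, dead_time_ms = dead_time_ms
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> ", nrow(x$components), " component(s), ",
      x$n_histograms, " histogram(s), mode = ", x$mode,
      ", objective = ", format(x$objective, digits = 4), "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return One row per (histogram, component): `t_fold`, `component`,
#'   `tau_ms`, `amplitude`.
#' @export
tidy.mixture_fit <- function(x, ...) x$amplitudes

#' @rdname tidy.mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$components), n_histograms = x$n_histograms,
    objective = x$objective, converged = x$converged,
    n_starts_converged = x$n_starts_converged, mode = x$mode,
    method = x$method
  )
}

#' No-block (single-stranded) fraction from an event table
#'
#' P0 is the number of open-pore (no-block) events divided by the total
#' number of (uncensored) events collected at one folding time.
#'
#' @param events Event tibble with columns `t_fold_s`, `event_class` and
#'   optionally `censored`.
#' @param t_fold Folding time (seconds) to select.
#' @return P0 as a single number in `[0, 1]`.
#' @export
p0_from_events <- function(events, t_fold) {
  e <- dplyr::filter(events, .data$t_fold_s == t_fold)
  if ("censored" %in% names(e)) e <- dplyr::filter(e, !.data$censored)
  if (nrow(e) == 0) stop("no events at t_fold = ", t_fold, call. = FALSE)
  mean(e$event_class == "no_block")
}

#' Convert mixture amplitudes to fractional state populations
#'
#' Each component's fractional population is its share of the total fitted
#' amplitude scaled by the folded fraction:
#' \eqn{P_i = (1 - P_0)\, c_i / \sum_i c_i}, with the single-stranded
#' population equal to \eqn{P_0}.
#'
#' @param fit A `mixture_fit` (or a tibble like its `amplitudes` element).
#' @param p0 No-block fraction(s): a single value, or a data frame with
#'   columns `t_fold` and `p0` matched to the fit's histograms.
#' @param state_labels Optional labels for the components in ascending-tau
#'   order (e.g. `c("HP1", "HP2", "TS", "PK")`); default `component_<i>`.
#' @param ss_label Label for the no-block state. Default `"SS"`.
#' @return A tibble `t_fold`, `state`, `population`; populations at each
#'   folding time sum to 1 (the SS row carries P0).
#' @export
fractional_populations <- function(fit, p0, state_labels = NULL,
                                   ss_label = "SS") {
  amp <- if (inherits(fit, "mixture_fit")) fit$amplitudes else
    tibble::as_tibble(fit)
  if (is.data.frame(p0)) {
    amp <- dplyr::left_join(amp, p0, by = "t_fold")
  } else {
    if (any(p0 < 0 | p0 > 1)) stop("p0 must be in [0, 1]", call. = FALSE)
    amp$p0 <- p0
  }
  if (any(is.na(amp$p0))) stop("missing p0 for some folding time", call. = FALSE)
  ncomp <- max(amp$component)
  labels <- state_labels %||% paste0("component_", seq_len(ncomp))
  if (length(labels) != ncomp) {
    stop("state_labels must have one label per component", call. = FALSE)
  }
  pops <- amp |>
    dplyr::group_by(.data$t_fold) |>
    dplyr::group_modify(function(d, key) {
      if (sum(d$amplitude) <= 0) {
        stop("all-zero amplitudes; populations undefined", call. = FALSE)
      }
      tibble::tibble(
        state = c(ss_label, labels[d$component]),
        population = c(d$p0[1],
                       (1 - d$p0[1]) * d$amplitude / sum(d$amplitude))
      )
    }) |>
    dplyr::ungroup()
  pops$state <- factor(pops$state, levels = c(ss_label, labels))
  pops
}
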