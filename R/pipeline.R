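#' Operating-point presets
#'
#' Returns the generator/fit settings for the experimentally characterised
#' systems: the wild-type pseudoknot with Mg2+ (four components at
#' 2.5 / 20 / 210 / 3500 ms), the wild type without Mg2+ (the two
#' pseudoknot-like states destabilised: 2.5 / 20 / 80 / 1900 ms), the polyU
#' loop mutant with Mg2+ (three components at 2.0 / 22 / 1000 ms) and the
#' 12-bp reference hairpin (single 18 ms component).
#'
#' @param name One of `"wild_type_mg"`, `"wild_type_nomg"`, `"polyU_mg"`,
#'   `"ref_hp"`.
#' @return A list with `tau_map` (ms), `n_components`, `state_labels`,
#'   `default_n` (events per snapshot), and for the wild type a `scheme`.
#'   The polyU preset carries default mixture `weights` for its 10-s
#'   snapshot (folded final state dominant).
#' @export
preset <- function(name = c("wild_type_mg", "wild_type_nomg", "polyU_mg",
                            "ref_hp")) {
  name <- match.arg(name)
  switch(
    name,
    wild_type_mg = list(
      tau_map = c(HP1 = 2.5, HP2 = 20, TS = 210, PK = 3500),
      n_components = 4L,
      state_labels = c("HP1", "HP2", "TS", "PK"),
      scheme = default_scheme(),
      default_n = 578L
    ),
    wild_type_nomg = list(
      tau_map = c(HP1 = 2.5, HP2 = 20, TS = 80, PK = 1900),
      n_components = 4L,
      state_labels = c("HP1", "HP2", "TS", "PK"),
      scheme = default_scheme(),
      default_n = 578L
    ),
    polyU_mg = list(
      tau_map = c(HP3 = 2.0, prePK_star = 22, PK_star = 1000),
      n_components = 3L,
      state_labels = c("HP3", "prePK_star", "PK_star"),
      weights = c(HP3 = 0.30, prePK_star = 0.25, PK_star = 0.45),
      default_n = 232L
    ),
    ref_hp = list(
      tau_map = c(ref_HP = 18),
      n_components = 1L,
      state_labels = "ref_HP",
      default_n = 500L
    )
  )
}

#' Captured-state mixture weights at one folding time
#'
#' Solves the scheme's master equation at `t_fold` and returns the
#' populations of the captured (non-initial) states, renormalised to sum
#' to 1 — the mixture weights of a single-snapshot duration sample.
#'
#' @param scheme A [kinetic_scheme()].
#' @param t_fold Folding time in seconds.
#' @return Named weights over the captured states.
#' @export
snapshot_weights <- function(scheme, t_fold) {
  p <- populations_wide(solve_populations(scheme, t_fold))
  captured <- setdiff(scheme$states, scheme$initial_state)
  w <- unlist(p[1, captured])
  w / sum(w)
}

#' Simulate a snapshot experiment to disk
#'
#' Runs [generate_event_table()] and persists the event table (TSV) plus a
#' JSON metadata sidecar recording the seed and configuration.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return The event tibble, invisibly; files `events.tsv` and
#'   `events_meta.json` under `out_dir`.
#' @export
run_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- generate_event_table(cfg)
  write_events(events, file.path(out_dir, "events.tsv"))
  meta <- list(
    master_seed = cfg$master_seed,
    folding_times = cfg$folding_times,
    events_per_time = cfg$events_per_time,
    tau_map = as.list(cfg$tau_map),
    ss0_fraction = cfg$ss0_fraction,
    dead_time_ms = cfg$dead_time_ms,
    states = cfg$scheme$states
  )
  jsonlite::write_json(meta, file.path(out_dir, "events_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(events)
}

#' Run the full snapshot analysis
#'
#' Executes the analysis chain on an event table: per-folding-time no-block
#' fraction P0 and log-binned histogram, a global mixture fit with shared
#' time constants, amplitude-to-population conversion, master-equation rate
#' fitting, and the pathway report.
#'
#' @param events Event tibble ([generate_event_table()] / [read_events()]),
#'   covering >= 2 folding times.
#' @param n_components Mixture components. Default 4.
#' @param state_labels Component labels in ascending-tau order. Default
#'   `c("HP1", "HP2", "TS", "PK")` for 4 components.
#' @param fit_cfg A [fit_config()] for the rate stage (its scheme defines
#'   the topology).
#' @param dead_time_ms Dead time shared with the generator. Default 0.5.
#' @param seed Seed for the fitting stages.
#' @param out_dir Optional directory; when given, all intermediates
#'   (histograms, fit JSON, populations TSV, report JSON) are persisted.
#' @return A list of class `snapshot_report`: `p0` (tibble `t_fold`, `p0`),
#'   `histograms`, `mixture` (`mixture_fit`), `populations` (long tibble),
#'   `rate_fit`, `pathway`, `seed`.
#' @export
run_analyze <- function(events, n_components = 4L,
                        state_labels = NULL, fit_cfg = fit_config(),
                        dead_time_ms = 0.5, seed = 1L, out_dir = NULL) {
  t_folds <- sort(unique(events$t_fold_s))
  if (length(t_folds) < 2) stop("events must cover >= 2 folding times",
                                call. = FALSE)
  state_labels <- state_labels %||%
    if (n_components == 4) c("HP1", "HP2", "TS", "PK") else
      paste0("component_", seq_len(n_components))

  ok <- events
  if ("censored" %in% names(ok)) ok <- dplyr::filter(ok, !.data$censored)

  p0_tbl <- tibble::tibble(
    t_fold = t_folds,
    p0 = vapply(t_folds, function(tf) p0_from_events(events, tf), numeric(1))
  )
  histograms <- lapply(t_folds, function(tf) {
    d <- ok$unfolding_duration_ms[ok$t_fold_s == tf &
                                    ok$event_class != "no_block"]
    log_histogram(d, t_fold = tf)
  })
  mixture <- fit_mixture(histograms, n_components, mode = "global",
                         seed = seed, dead_time_ms = dead_time_ms)
  populations <- fractional_populations(
    mixture, p0_tbl, state_labels = state_labels,
    ss_label = fit_cfg$scheme$initial_state
  )
  populations <- dplyr::rename(populations, time_s = "t_fold")
  rate_fit <- fit_rates(populations, fit_cfg)
  pathway <- pathway_report(rate_fit)

  report <- structure(
    list(p0 = p0_tbl, histograms = histograms, mixture = mixture,
         populations = populations, rate_fit = rate_fit, pathway = pathway,
         seed = seed),
    class = "snapshot_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_populations(populations, file.path(out_dir, "populations.tsv"))
    for (h in histograms) {
      utils::write.table(
        h, file.path(out_dir, sprintf("histogram_t%s.tsv", attr(h, "t_fold"))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = seed,
           p0 = p0_tbl,
           components = mixture$components,
           amplitudes = mixture$amplitudes,
           rates = rate_fit$rates,
           ss0 = rate_fit$ss0,
           fitness = rate_fit$fitness,
           branching = rate_fit$branching,
           routes = pathway$routes),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @export
print.snapshot_report <- function(x, ...) {
  cat("<snapshot_report> ", nrow(x$p0), " folding times, ",
      nrow(x$mixture$components), " mixture components\n", sep = "")
  cat("Time constants (ms): ",
      paste(signif(x$mixture$components$tau_ms, 3), collapse = ", "), "\n",
      sep = "")
  cat("Rate-fit fitness F = ", format(x$rate_fit$fitness, digits = 4),
      ", ss0 = ", format(x$rate_fit$ss0, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Ground-truth recovery experiment
#'
#' Simulates snapshot data from a known scheme, runs the full analysis, and
#' compares recovered time constants, populations and branching fractions
#' against the ground truth, replicated over seeds.
#'
#' @param cfg A [generator_config()] holding the ground-truth scheme.
#' @param seeds Integer vector of replicate master seeds.
#' @param fit_cfg [fit_config()] for the rate stage; defaults to the
#'   ground-truth topology with a reduced start count (the per-replicate
#'   fits start near plausible scales).
#' @param n_components Mixture components; defaults to the number of
#'   captured states.
#' @return A list of class `recovery_summary`: `per_replicate` tibble
#'   (seed, component taus, branching fractions, ss0), `truth`, and
#'   `summary` (median absolute errors).
#' @export
run_recover <- function(cfg, seeds = 1:5,
                        fit_cfg = NULL, n_components = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  captured <- setdiff(cfg$scheme$states, cfg$scheme$initial_state)
  n_components <- n_components %||% length(captured)
  fit_cfg <- fit_cfg %||% fit_config(scheme = cfg$scheme, n_starts = 10L)

  truth_tau <- sort(cfg$tau_map[captured])
  truth_br <- dplyr::bind_rows(lapply(
    unique(cfg$scheme$transitions$from[cfg$scheme$transitions$rate > 0]),
    branching_fractions, scheme = cfg$scheme))

  per_rep <- dplyr::bind_rows(lapply(seeds, function(s) {
    cfg_s <- cfg
    cfg_s$master_seed <- as.integer(s)
    events <- generate_event_table(cfg_s)
    rep <- run_analyze(events, n_components = n_components,
                       state_labels = names(truth_tau),
                       fit_cfg = fit_cfg,
                       dead_time_ms = cfg$dead_time_ms, seed = s)
    br <- rep$rate_fit$branching
    tibble::tibble(
      seed = s,
      component = seq_len(n_components),
      state = names(truth_tau),
      tau_ms = rep$mixture$components$tau_ms,
      tau_true_ms = as.numeric(truth_tau),
      ss0 = rep$rate_fit$ss0,
      fitness = rep$rate_fit$fitness,
      branching = list(br)
    )
  }))

  tau_err <- per_rep |>
    dplyr::group_by(.data$component, .data$state) |>
    dplyr::summarise(
      tau_true_ms = .data$tau_true_ms[1],
      tau_median_ms = stats::median(.data$tau_ms),
      tau_mad_ms = stats::median(abs(.data$tau_ms - .data$tau_true_ms[1])),
      .groups = "drop")

  structure(
    list(per_replicate = per_rep, truth = list(tau = truth_tau,
                                               branching = truth_br),
         summary = tau_err),
    class = "recovery_summary"
  )
}
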