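#' Nanopore trace model
#'
#' Nominal blockade levels and acquisition parameters for synthesising and
#' segmenting multi-level current traces. Levels are expressed as residual
#' current fractions I/I0 in percent of the open-pore current: Level-1
#' (18.6%) and Level-2 (12.6%) are the single-level hairpin blocks, Level-3
#' (9.2%) and Level-4 (3.0%) form the stepwise two-level pseudoknot
#' signature.
#'
#' @param open_current Open-pore current in arbitrary units. Default 100
#'   (so samples read directly in percent).
#' @param level_fractions Named I/I0 percentages per level.
#' @param noise_sd Gaussian noise SD, percent of I0. Default 0.5.
#' @param sampling_rate_hz Samples per second. Default 20000.
#' @param rc_time_ms RC settling time constant after a voltage switch (ms);
#'   samples within the settling window are masked during segmentation.
#'   Default 1.
#' @return A list of class `trace_model`.
#' @export
trace_model <- function(open_current = 100,
                        level_fractions = c("Level-1" = 18.6,
                                            "Level-2" = 12.6,
                                            "Level-3" = 9.2,
                                            "Level-4" = 3.0),
                        noise_sd = 0.5, sampling_rate_hz = 20000,
                        rc_time_ms = 1.0) {
  stopifnot(all(level_fractions > 0), all(level_fractions < 100),
            sampling_rate_hz > 0, noise_sd >= 0, rc_time_ms >= 0)
  structure(
    list(open_current = open_current, level_fractions = level_fractions,
         noise_sd = noise_sd, sampling_rate_hz = sampling_rate_hz,
         rc_time_ms = rc_time_ms),
    class = "trace_model"
  )
}

.state_levels <- function(state) {
  switch(state,
         HP1 = "Level-1", HP2 = "Level-2",
         TS = c("Level-3", "Level-4"), PK = c("Level-3", "Level-4"),
         character(0))
}

#' Synthesise multi-level current traces for events
#'
#' Forward model for the segmentation stage: each event becomes a
#' piecewise-constant trace at its nominal level fractions with additive
#' Gaussian noise and an optional exponential RC-settling transient at the
#' voltage switch (sample 1). Single-level events block at their state's
#' level for the whole unfolding duration; two-level events spend 80% of
#' the duration at Level-3 and 20% at Level-4. After the block ends the
#' pore returns to the open current for a short tail.
#'
#' @param events Event tibble (needs `event_id`, `true_state`,
#'   `event_class`, `unfolding_duration_ms`).
#' @param model A [trace_model()].
#' @param seed Integer seed for the noise.
#' @param tail_ms Open-pore tail after the block (and total length of a
#'   no-block trace). Default 5 ms.
#' @param level3_share Fraction of a two-level duration spent at Level-3.
#'   Default 0.8.
#' @return A list with `traces` (list of `current_trace` objects: `samples`,
#'   `sampling_rate_hz`, `switch_index`, `event_id`) and `truth` (tibble of
#'   per-segment ground-truth boundaries, 0-based half-open sample windows).
#' @export
synthesize_trace <- function(events, model = trace_model(), seed = 1L,
                             tail_ms = 5, level3_share = 0.8) {
  stopifnot(inherits(model, "trace_model"))
  if (model$sampling_rate_hz <= 0) stop("sampling rate must be > 0",
                                        call. = FALSE)
  set.seed(seed)
  sp_ms <- model$sampling_rate_hz / 1000  # samples per ms
  lev <- model$level_fractions / 100 * model$open_current
  truth <- list()
  traces <- purrr::map(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    segs <- if (ev$event_class == "no_block" || is.na(ev$unfolding_duration_ms)) {
      tibble::tibble(label = "open", level = model$open_current,
                     n = round(tail_ms * sp_ms))
    } else {
      labels <- .state_levels(ev$true_state)
      shares <- if (length(labels) == 2) c(level3_share, 1 - level3_share) else 1
      dplyr::bind_rows(
        tibble::tibble(label = labels, level = as.numeric(lev[labels]),
                       n = round(ev$unfolding_duration_ms * shares * sp_ms)),
        tibble::tibble(label = "open", level = model$open_current,
                       n = round(tail_ms * sp_ms))
      )
    }
    segs <- segs[segs$n > 0, ]
    samples <- rep(segs$level, segs$n)
    if (model$rc_time_ms > 0) {
      k <- seq_along(samples)
      settle <- exp(-(k - 1) / (model$rc_time_ms * sp_ms))
      samples <- samples + (model$open_current * 1.5 - samples) * settle
    }
    if (model$noise_sd > 0) {
      samples <- samples + stats::rnorm(length(samples),
                                        0, model$noise_sd / 100 *
                                          model$open_current)
    }
    ends <- cumsum(segs$n)
    truth[[length(truth) + 1]] <<- tibble::tibble(
      event_id = ev$event_id, label = segs$label,
      start_index = c(0, ends[-length(ends)]), end_index = ends
    )
    structure(list(samples = samples,
                   sampling_rate_hz = model$sampling_rate_hz,
                   switch_index = 0L, event_id = ev$event_id),
              class = "current_trace")
  })
  list(traces = traces, truth = dplyr::bind_rows(truth))
}

#' Segment a current trace into blockade levels
#'
#' Walks the trace with a running median and opens a new segment where the
#' level shifts by more than `3 * noise_sd` (percent of I0, with a small
#' floor) for at least `min_dwell` samples. Samples inside the RC-settling
#' window after the voltage switch are masked before segmentation. Each
#' segment's mean is assigned to the nearest nominal level within
#' `tolerance` percentage points of I/I0, to `"open"` if within tolerance
#' of the open current, otherwise `"unassigned"`.
#'
#' @param trace A `current_trace` (list with `samples`, `sampling_rate_hz`,
#'   `switch_index`) or a bare numeric vector.
#' @param model A [trace_model()].
#' @param min_dwell Minimum sustained samples for a level change. Default
#'   10.
#' @param tolerance Level-assignment tolerance in percentage points of
#'   I/I0. Default 2.
#' @return A tibble of segments: `start_index`, `end_index` (0-based,
#'   half-open), `mean_fraction` (percent of I0), `label`.
#' @export
segment_levels <- function(trace, model = trace_model(), min_dwell = 10,
                           tolerance = 2) {
  samples <- if (is.numeric(trace)) trace else trace$samples
  if (length(samples) < 2) stop("trace too short to segment", call. = FALSE)
  rate <- if (is.numeric(trace)) model$sampling_rate_hz else trace$sampling_rate_hz
  mask <- 0L
  if (model$rc_time_ms > 0) {
    mask <- min(length(samples) - 1L,
                as.integer(ceiling(5 * model$rc_time_ms / 1000 * rate)))
  }
  x <- samples[(mask + 1L):length(samples)]
  med <- stats::runmed(x, k = min(2L * (min_dwell %/% 2L) + 1L,
                                  2L * (length(x) %/% 2L) - 1L))
  thresh <- max(3 * model$noise_sd, 0.05) / 100 * model$open_current
  breaks <- integer(0)
  seg_start <- 1L
  level <- med[1]
  i <- 2L
  n <- length(x)
  while (i <= n) {
    if (abs(med[i] - level) > thresh) {
      run_end <- min(n, i + min_dwell - 1L)
      if (all(abs(med[i:run_end] - med[run_end]) <= thresh) &&
          (run_end - i + 1L >= min_dwell || run_end == n)) {
        breaks <- c(breaks, i - 1L)
        seg_start <- i
        level <- med[run_end]
        i <- run_end + 1L
        next
      }
    }
    # slow drift tracking within a segment
    level <- level + 0.02 * (med[i] - level)
    i <- i + 1L
  }
  bounds <- c(0L, breaks, n)
  segs <- purrr::map(seq_len(length(bounds) - 1L), function(j) {
    a <- bounds[j] + 1L
    b <- bounds[j + 1L]
    m <- mean(x[a:b])
    frac <- m / model$open_current * 100
    label <- "unassigned"
    if (abs(frac - 100) <= max(tolerance, 3 * model$noise_sd)) {
      label <- "open"
    } else {
      d <- abs(model$level_fractions - frac)
      if (min(d) <= tolerance) label <- names(model$level_fractions)[which.min(d)]
    }
    tibble::tibble(start_index = mask + a - 1L, end_index = mask + b,
                   mean_fraction = frac, label = label)
  })
  dplyr::bind_rows(segs)
}

#' Classify an unfolding signature from its segments
#'
#' The three signature classes: no sub-open-pore segment means the molecule
#' was still single-stranded (`no_block`); exactly one blocked level is a
#' hairpin-type block (`single_level`); a Level-3 segment followed by a
#' Level-4 segment is the stepwise pseudoknot-type signature
#' (`two_level`). Anything else is `"unclassified"`.
#'
#' @param segments Segment tibble from [segment_levels()] for one unfold
#'   window.
#' @return One of `"no_block"`, `"single_level"`, `"two_level"`,
#'   `"unclassified"`.
#' @export
classify_event <- function(segments) {
  blocked <- segments[!segments$label %in% "open", ]
  blocked <- blocked[blocked$label != "unassigned" |
                       blocked$mean_fraction < 50, ]
  if (nrow(blocked) == 0) return("no_block")
  labs <- blocked$label
  if (nrow(blocked) == 1 && labs != "unassigned") return("single_level")
  if (nrow(blocked) == 2 && identical(labs, c("Level-3", "Level-4"))) {
    return("two_level")
  }
  "unclassified"
}

#' Extract the unfolding duration from segments
#'
#' The unfolding duration runs from the voltage switch (start of the unfold
#' window) to the end of the last blocked segment; for two-level events it
#' therefore includes both the Level-3 and the Level-4 dwell.
#'
#' @param segments Segment tibble from [segment_levels()].
#' @param sampling_rate_hz Samples per second.
#' @param switch_index 0-based sample index of the voltage switch. Default
#'   0.
#' @return Duration in ms.
#' @export
extract_unfolding_duration <- function(segments, sampling_rate_hz,
                                       switch_index = 0L) {
  blocked <- segments[!segments$label %in% c("open") &
                        segments$mean_fraction < 50, ]
  if (nrow(blocked) == 0) {
    stop("no blocked segment; unfolding duration undefined for an SS event",
         call. = FALSE)
  }
  (max(blocked$end_index) - switch_index) / sampling_rate_hz * 1000
}
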