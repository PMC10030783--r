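#' Detect spikes by topographic prominence
#'
#' Finds local maxima and keeps those whose topographic prominence -- the
#' peak height above the higher of the two minima flanking it, searching
#' outwards to the nearest higher samples or the trace ends -- reaches the
#' threshold. This is the standard (window-unbounded) prominence
#' definition; plateaus report their middle sample. Experimental
#' recordings use a prominence threshold of 0.03 mV; simulation traces use
#' whatever threshold suits their units.
#'
#' @param x numeric trace (length >= 3), or a data frame of traces.
#' @param prominence minimum prominence (> 0) for a peak to count as a spike.
#' @param times optional vector of time stamps, same length as `x`
#'   (default: sample indices `1..n`).
#' @param min_separation optional minimum time between reported spikes;
#'   when two spikes fall closer, the less prominent one is dropped.
#' @param amplitude_cap optional upper bound: spikes with prominence
#'   `>= amplitude_cap` are discarded (e.g. 0.1 mV to keep only small
#'   spikes).
#' @param ... passed between methods.
#' @return tibble of class `spike_train` with columns `time`, `index`,
#'   `height` (trace value at the apex), `prominence`; times strictly
#'   increasing.
#' @export
detect_spikes <- function(x, ...) UseMethod("detect_spikes")

#' @rdname detect_spikes
#' @export
detect_spikes.numeric <- function(x, prominence, times = NULL,
                                  min_separation = NULL,
                                  amplitude_cap = NULL, ...) {
  if (length(x) < 3) abort("trace must have at least 3 samples")
  if (!is.numeric(prominence) || prominence <= 0)
    abort("`prominence` must be > 0")
  if (is.null(times)) times <- seq_along(x)
  if (length(times) != length(x)) abort("`times` must match the trace length")
  pk <- local_maxima(x)
  prom <- vapply(pk, function(p) peak_prominence(x, p), numeric(1))
  keep <- prom >= prominence
  if (!is.null(amplitude_cap)) keep <- keep & prom < amplitude_cap
  pk <- pk[keep]; prom <- prom[keep]
  if (!is.null(min_separation) && length(pk) > 1) {
    ord <- order(prom, decreasing = TRUE)
    taken <- logical(0); sel <- integer(0)
    tt <- times[pk]
    for (k in ord) {
      if (all(abs(tt[k] - tt[sel]) >= min_separation) || !length(sel))
        sel <- c(sel, k)
    }
    sel <- sort(sel)
    pk <- pk[sel]; prom <- prom[sel]
  }
  out <- tibble(time = times[pk], index = pk, height = x[pk],
                prominence = prom)
  out <- out[order(out$time), ]
  class(out) <- c("spike_train", class(out))
  out
}

#' @rdname detect_spikes
#' @param value,time,channel column names (strings) holding the trace
#'   values, time stamps and channel/electrode labels; detection runs per
#'   channel.
#' @export
detect_spikes.data.frame <- function(x, prominence, value = "potential",
                                     time = "iteration",
                                     channel = "electrode", ...) {
  stopifnot(value %in% names(x), time %in% names(x))
  if (!is.null(channel) && channel %in% names(x)) {
    out <- x |>
      dplyr::group_by(.data[[channel]]) |>
      dplyr::group_modify(function(d, g) {
        detect_spikes(d[[value]], prominence = prominence,
                      times = d[[time]], ...)
      }) |>
      dplyr::ungroup()
  } else {
    out <- detect_spikes(x[[value]], prominence = prominence,
                         times = x[[time]], ...)
  }
  class(out) <- unique(c("spike_train", class(out)))
  out
}

# local maxima with scipy-style plateau handling (midpoint reported)
local_maxima <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i - 1L] < x[i]) {
      ahead <- i + 1L
      while (ahead <= n - 1L && x[ahead] == x[i]) ahead <- ahead + 1L
      if (x[ahead] < x[i]) {
        peaks <- c(peaks, (i + ahead - 1L) %/% 2L)
        i <- ahead
        next
      }
      i <- ahead
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# topographic prominence of the peak at index p (window-unbounded)
peak_prominence <- function(x, p) {
  h <- x[p]
  lmin <- h
  i <- p - 1L
  while (i >= 1L && x[i] <= h) {
    if (x[i] < lmin) lmin <- x[i]
    i <- i - 1L
  }
  rmin <- h
  i <- p + 1L
  while (i <= length(x) && x[i] <= h) {
    if (x[i] < rmin) rmin <- x[i]
    i <- i + 1L
  }
  h - max(lmin, rmin)
}

#' Inter-spike intervals
#'
#' Successive differences of the spike times of a train; empty for trains
#' with fewer than two spikes.
#'
#' @param train a `spike_train` (or numeric vector of spike times).
#' @return numeric vector of intervals (all positive).
#' @export
interspike_intervals <- function(train) {
  times <- if (is.numeric(train)) train else train$time
  if (length(times) < 2) return(numeric(0))
  diff(sort(times))
}

#' Timing constants for gate extraction
#'
#' Spikes from different stimulation scenarios occurring within
#' `simultaneity` iterations are treated as one logical event; pooled
#' spikes further apart than `separation` iterations belong to different
#' events. Defaults follow the simulation read-out convention
#' (simultaneity 2e2, separation 1e3 iterations).
#'
#' @param simultaneity simultaneity window (iterations).
#' @param separation event-separation gap (iterations); must exceed the
#'   simultaneity window.
#' @return list of class `gate_timing_params`.
#' @export
gate_timing_params <- function(simultaneity = 200, separation = 1000) {
  if (!(separation > simultaneity && simultaneity > 0))
    abort("need separation > simultaneity > 0")
  structure(list(simultaneity = simultaneity, separation = separation),
            class = "gate_timing_params")
}

#' Align cross-scenario spike trains into logical events
#'
#' Pools the spike times of the three stimulation scenarios
#' `(x, y) = (0,1), (1,0), (1,1)` (x = stimulation at E1, y = at E2),
#' partitions the pooled train into events by single-linkage chaining --
#' a new event starts wherever the gap to the previous spike exceeds the
#' separation threshold -- and marks, per event, which scenarios
#' contributed a spike. The chaining makes membership unambiguous: every
#' spike belongs to exactly one event.
#'
#' @param trains named list with elements `"01"`, `"10"`, `"11"`: each a
#'   `spike_train` or numeric vector of spike times (apex times).
#' @param timing a [gate_timing_params()].
#' @return tibble with one row per event: `event`, `t_start`, `t_end`,
#'   `n_spikes`, presence flags `s01`, `s10`, `s11`, `simultaneous`
#'   (whether the event's span fits the simultaneity window), and the
#'   classified `gate` (see [classify_gate()]).
#' @export
align_events <- function(trains, timing = gate_timing_params()) {
  if (!all(c("01", "10", "11") %in% names(trains)))
    abort('`trains` must have elements "01", "10", "11"')
  tt <- purrr::map(trains[c("01", "10", "11")],
                   \(x) if (is.numeric(x)) x else x$time)
  pooled <- tibble(
    time = unlist(tt, use.names = FALSE),
    scenario = rep(c("01", "10", "11"), lengths(tt)))
  if (nrow(pooled) == 0)
    return(tibble(event = integer(0), t_start = numeric(0),
                  t_end = numeric(0), n_spikes = integer(0),
                  s01 = logical(0), s10 = logical(0), s11 = logical(0),
                  simultaneous = logical(0), gate = character(0)))
  pooled <- pooled[order(pooled$time), ]
  gap <- c(Inf, diff(pooled$time))
  pooled$event <- cumsum(gap > timing$separation)
  pooled |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(
      t_start = min(.data$time), t_end = max(.data$time),
      n_spikes = dplyr::n(),
      s01 = any(.data$scenario == "01"),
      s10 = any(.data$scenario == "10"),
      s11 = any(.data$scenario == "11"),
      simultaneous = (max(.data$time) - min(.data$time)) <= timing$simultaneity,
      .groups = "drop") |>
    dplyr::mutate(gate = classify_gate(.data$s01, .data$s10, .data$s11))
}

#' Classify a spike-presence pattern as a Boolean gate
#'
#' The presence triple `(s01, s10, s11)` records whether a spike occurred
#' under inputs `(x, y) = (0,1), (1,0), (1,1)` (x = excitation around E1,
#' y = around E2). Reading each spike as logical TRUE, the triple is the
#' truth table of a Boolean function of `(x, y)` restricted to the three
#' tested input pairs, giving the exhaustive 8-way lookup:
#'
#' | (s01, s10, s11) | gate |
#' |---|---|
#' | (0,0,0) | `CONST-FALSE` (no gate) |
#' | (0,0,1) | `AND` |
#' | (0,1,0) | `x-AND-NOT-y` |
#' | (0,1,1) | `SELECT-x` (output = x) |
#' | (1,0,0) | `NOT-x-AND-y` |
#' | (1,0,1) | `SELECT-y` (output = y) |
#' | (1,1,0) | `XOR` |
#' | (1,1,1) | `OR` |
#'
#' @param s01,s10,s11 logical vectors (recycled together).
#' @return character vector of gate labels.
#' @export
classify_gate <- function(s01, s10, s11) {
  key <- paste0(as.integer(s01), as.integer(s10), as.integer(s11))
  unname(gate_lookup_table()[key])
}

gate_lookup_table <- function() {
  c("000" = "CONST-FALSE", "001" = "AND", "010" = "x-AND-NOT-y",
    "011" = "SELECT-x", "100" = "NOT-x-AND-y", "101" = "SELECT-y",
    "110" = "XOR", "111" = "OR")
}

#' Gate labels
#'
#' @return character vector of the 8 gate labels in presence-pattern order
#'   `000 ... 111`.
#' @export
gate_labels <- function() unname(gate_lookup_table())

#' Census of Boolean gates across electrodes
#'
#' For each electrode, detects spikes in the potential trace of each of the
#' three stimulation scenarios, aligns them into events
#' ([align_events()]) and classifies every event as a gate
#' ([classify_gate()]). Events classified `CONST-FALSE` cannot occur
#' (an event contains at least one spike).
#'
#' @param scenarios named list with elements `"01"`, `"10"`, `"11"`: each an
#'   `fhn_sim` result or a long trace tibble (`iteration`, `electrode`,
#'   `potential`) as produced by [potential_traces()]. All three must share
#'   the same electrodes and recording iterations.
#' @param prominence spike-detection prominence threshold, in trace units.
#' @param timing a [gate_timing_params()].
#' @param amplitude_cap optional prominence cap (see [detect_spikes()]).
#' @return object of class `gate_census`: list with `events` (electrode x
#'   event table with presence flags and gate labels) and `counts`
#'   (aggregate events per gate type). `tidy()` returns the events,
#'   `glance()` a one-row summary.
#' @export
census_gates <- function(scenarios, prominence,
                         timing = gate_timing_params(),
                         amplitude_cap = NULL) {
  if (!all(c("01", "10", "11") %in% names(scenarios)))
    abort('`scenarios` must have elements "01", "10", "11"')
  traces <- purrr::map(scenarios[c("01", "10", "11")], function(s) {
    if (inherits(s, "fhn_sim")) potential_traces(s) else as_tibble(s)
  })
  iters <- purrr::map(traces, \(d) sort(unique(d$iteration)))
  elecs <- purrr::map(traces, \(d) sort(unique(d$electrode)))
  if (!all(purrr::map_lgl(iters[-1], identical, iters[[1]])))
    abort("scenario recordings have mismatched horizons")
  if (!all(purrr::map_lgl(elecs[-1], identical, elecs[[1]])))
    abort("scenario recordings have mismatched electrodes")
  events <- purrr::map_dfr(elecs[[1]], function(e) {
    trains <- purrr::map(traces, function(d) {
      d <- d[d$electrode == e, ]
      detect_spikes(d$potential, prominence = prominence,
                    times = d$iteration, amplitude_cap = amplitude_cap)
    })
    ev <- align_events(trains, timing)
    if (nrow(ev)) dplyr::mutate(ev, electrode = e, .before = 1) else ev
  })
  counts <- if (nrow(events)) {
    dplyr::count(events, .data$gate, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n))
  } else {
    tibble(gate = character(0), n = integer(0))
  }
  structure(list(events = events, counts = counts,
                 electrodes = elecs[[1]], timing = timing,
                 prominence = prominence),
            class = "gate_census")
}

#' @export
print.gate_census <- function(x, ...) {
  cat(sprintf("<gate_census> %d events on %d electrodes\n",
              nrow(x$events), length(x$electrodes)))
  if (nrow(x$counts)) print(x$counts)
  invisible(x)
}

#' @export
tidy.gate_census <- function(x, ...) x$events

#' @export
glance.gate_census <- function(x, ...) {
  tibble(n_events = nrow(x$events),
         n_electrodes = length(x$electrodes),
         n_gate_types = nrow(x$counts),
         top_gate = if (nrow(x$counts)) x$counts$gate[1] else NA_character_)
}
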