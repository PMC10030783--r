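#' Load schedules for insole recordings
#'
#' Describes when each loading condition was applied, in sample indices
#' (1-based, half-open `[start, end)`: a spike at a boundary belongs to the
#' earlier window). Conditions follow the bench protocol vocabulary:
#' `no-load`, `even` (35 kg evenly distributed), `heel-bias`, `toe-bias`.
#'
#' @param condition character vector of conditions.
#' @param start,end integer sample indices; intervals must be increasing and
#'   non-overlapping.
#' @return tibble of class `load_schedule` with columns `interval`,
#'   `condition`, `start`, `end`.
#' @export
load_schedule <- function(condition, start, end) {
  known <- c("no-load", "even", "heel-bias", "toe-bias")
  if (!all(condition %in% known))
    abort(paste0("conditions must be among: ", paste(known, collapse = ", ")))
  start <- as.integer(start); end <- as.integer(end)
  if (length(condition) != length(start) || length(start) != length(end))
    abort("condition, start and end must have equal lengths")
  if (any(end <= start)) abort("each interval needs end > start")
  if (is.unsorted(start, strictly = TRUE) || any(start[-1] < end[-length(end)]))
    abort("intervals must be increasing and non-overlapping")
  out <- tibble(interval = seq_along(condition), condition = condition,
                start = start, end = end)
  class(out) <- c("load_schedule", class(out))
  out
}

#' Multi-channel differential voltage recordings
#'
#' A recording set is a wide tibble -- `time` (seconds) plus one column per
#' differential channel (mV) -- with the logger's characteristics attached:
#' sample period (default 1 s) and acquisition range (default +/-156 mV).
#' Channel labels follow the electrode-pair convention `"Ch 1-2"` ...
#' `"Ch 15-16"`.
#'
#' @param data wide data frame with a `time` column and channel columns.
#' @param sample_period sampling period in seconds.
#' @param range acquisition voltage range in mV; values are clipped to
#'   `[-range, range]` (with a warning) on construction.
#' @return tibble of class `recording_set`.
#' @export
recording_set <- function(data, sample_period = 1, range = 156) {
  data <- as_tibble(data)
  if (!"time" %in% names(data)) abort("`data` needs a `time` column")
  chans <- setdiff(names(data), "time")
  if (!length(chans)) abort("`data` needs at least one channel column")
  n_clip <- 0L
  for (ch in chans) {
    v <- data[[ch]]
    if (!is.numeric(v)) abort(sprintf("channel `%s` is not numeric", ch))
    out_of_range <- !is.na(v) & abs(v) > range
    n_clip <- n_clip + sum(out_of_range)
    data[[ch]] <- pmin(pmax(v, -range), range)
  }
  if (n_clip > 0)
    warn(sprintf("%d sample(s) exceeded the %g mV acquisition range and were clipped",
                 n_clip, range))
  structure(data, sample_period = sample_period, range = range,
            channels = chans, clipped = n_clip,
            class = c("recording_set", class(data)))
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set> %d samples x %d channels @ %g s, range +/-%g mV\n",
              nrow(x), length(attr(x, "channels")),
              attr(x, "sample_period"), attr(x, "range")))
  NextMethod()
}

default_channel_labels <- function(n) {
  paste0("Ch ", seq(1, 2 * n, by = 2), "-", seq(2, 2 * n, by = 2))
}

#' Read a delimited logger export
#'
#' Reads a delimited text export (header row; first column time in seconds,
#' remaining columns channel voltages in mV) into a [recording_set()].
#' Non-uniform time stamps are resampled to the nearest whole sample
#' period; missing seconds are filled with `NA` and flagged in the `gaps`
#' attribute. Values outside the acquisition range are clipped (with a
#' warning).
#'
#' @param path file path (CSV or TSV; delimiter sniffed from the header).
#' @param sample_period,range logger characteristics, see [recording_set()].
#' @return a [recording_set()].
#' @export
read_logger_export <- function(path, sample_period = 1, range = 156) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort("logger export is empty or has no data rows")
  delim <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else " "
  hdr <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
  if (suppressWarnings(!any(is.na(as.numeric(hdr)))))
    abort("logger export is missing a header row")
  rows <- strsplit(lines[-1], delim, fixed = TRUE)
  ncol <- length(hdr)
  for (r in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[r]]))
    if (length(vals) != ncol || anyNA(vals))
      abort(sprintf("non-numeric or malformed record at line %d", r + 1L))
    rows[[r]] <- vals
  }
  m <- do.call(rbind, rows)
  colnames(m) <- hdr
  d <- as_tibble(as.data.frame(m, check.names = FALSE))
  names(d)[1] <- "time"
  # resample to a uniform grid at the sample period
  snapped <- round(d$time / sample_period) * sample_period
  full <- seq(min(snapped), max(snapped), by = sample_period)
  idx <- match(full, snapped)
  gaps <- full[is.na(idx)]
  out <- d[idx, , drop = FALSE]
  out$time <- full
  rs <- recording_set(out, sample_period = sample_period, range = range)
  attr(rs, "gaps") <- gaps
  rs
}

#' Synthesize an insole recording with planted ground truth
#'
#' Generates a multi-channel differential recording emulating the logger
#' output: a slow sinusoidal baseline drift, AR(1) Gaussian measurement
#' noise (correlation time `noise_corr` seconds -- at 1 Hz the logger
#' averages many measurements per stored sample, so the residual noise is
#' slow, not white), and planted biphasic spikes at Poisson times whose
#' rate and amplitude depend on the load condition. Planted spikes closer
#' than `min_spacing` are re-drawn so each remains individually
#' resolvable. The exact planted times and amplitudes are returned, making
#' the generator usable as ground truth for detector validation.
#'
#' @param schedule a [load_schedule()]; the recording spans sample 1 to the
#'   last interval's end.
#' @param n_channels number of differential channels (default 8).
#' @param rates named numeric: spikes per 30-minute (1800-sample) window for
#'   each condition. Defaults reflect denser spiking under load.
#' @param amplitude named list (or single `c(mean, sd)`) giving the spike
#'   prominence distribution in mV per condition; default mean 0.06 mV,
#'   sd 0.01 mV (spikes below 0.1 mV).
#' @param spike_width spike width in samples.
#' @param min_spacing minimum spacing between planted spikes (samples);
#'   default ten spike widths.
#' @param noise_sd marginal standard deviation of the measurement noise, mV.
#' @param noise_corr AR(1) correlation time of the noise, seconds.
#' @param drift_amplitude,drift_period baseline drift sine amplitude (mV)
#'   and period (s).
#' @param sample_period,range logger characteristics.
#' @param seed integer seed; fixes the output exactly.
#' @return list with `recording` (a [recording_set()]) and `truth` (tibble
#'   `channel`, `interval`, `condition`, `time`, `amplitude`).
#' @export
synthesize_recording <- function(schedule,
                                 n_channels = 8,
                                 rates = c("no-load" = 2, "even" = 8,
                                           "heel-bias" = 6, "toe-bias" = 6),
                                 amplitude = c(mean = 0.06, sd = 0.01),
                                 spike_width = 10,
                                 min_spacing = 10 * spike_width,
                                 noise_sd = 0.005,
                                 noise_corr = 60,
                                 drift_amplitude = 0.01,
                                 drift_period = 3600,
                                 sample_period = 1,
                                 range = 156,
                                 seed = 1L) {
  if (any(rates < 0)) abort("rates must be >= 0")
  amp_for <- function(cond) {
    a <- if (is.list(amplitude)) amplitude[[cond]] else amplitude
    if (is.null(a)) abort(sprintf("no amplitude given for condition `%s`", cond))
    if (a[[1]] <= 0 || a[[2]] < 0) abort("amplitude mean must be > 0 and sd >= 0")
    a
  }
  n <- max(schedule$end) - 1L
  tt <- (seq_len(n) - 1) * sample_period
  withr::with_seed(as.integer(seed), {
    chans <- default_channel_labels(n_channels)
    rho <- exp(-sample_period / noise_corr)
    sig <- matrix(0, n, n_channels)
    truth <- list()
    for (c_i in seq_len(n_channels)) {
      eps <- rnorm(n, 0, noise_sd)
      noise <- as.numeric(stats::filter(eps * sqrt(1 - rho^2), rho,
                                        method = "recursive",
                                        init = rnorm(1, 0, noise_sd)))
      drift <- drift_amplitude * sin(2 * pi * tt / drift_period + runif(1, 0, 2 * pi))
      v <- drift + noise
      for (r in seq_len(nrow(schedule))) {
        cond <- schedule$condition[r]
        s0 <- schedule$start[r]; s1 <- schedule$end[r] - 1L
        len <- s1 - s0 + 1L
        rate <- rates[[cond]]
        if (is.null(rate)) abort(sprintf("no rate given for condition `%s`", cond))
        n_sp <- rpois(1, rate * len / 1800)
        if (n_sp == 0) next
        margin <- 2L * spike_width
        lo <- s0 + margin; hi <- s1 - margin
        if (hi <= lo) next
        times <- sort(round(runif(n_sp, lo, hi)))
        tries <- 0L
        while (n_sp > 1 && any(diff(times) < min_spacing) && tries < 200L) {
          times <- sort(round(runif(n_sp, lo, hi)))   # re-draw overlapping sets
          tries <- tries + 1L
        }
        if (n_sp > 1 && any(diff(times) < min_spacing)) {
          keep <- c(TRUE, diff(times) >= min_spacing)
          times <- times[keep]
          warn(sprintf("dropped %d planted spike(s) that could not be spaced",
                       n_sp - length(times)))
        }
        ap <- amp_for(cond)
        amps <- pmax(rnorm(length(times), ap[[1]], ap[[2]]), ap[[1]] / 4)
        for (k in seq_along(times)) {
          v <- v + amps[k] * biphasic_shape(n, times[k], spike_width)
        }
        truth[[length(truth) + 1L]] <- tibble(
          channel = chans[c_i], interval = schedule$interval[r],
          condition = cond, time = tt[times], amplitude = amps)
      }
      sig[, c_i] <- v
    }
    colnames(sig) <- chans
    rec <- recording_set(dplyr::bind_cols(tibble(time = tt), as_tibble(sig)),
                         sample_period = sample_period, range = range)
    truth <- if (length(truth)) {
      dplyr::arrange(dplyr::bind_rows(truth), .data$channel, .data$time)
    } else {
      tibble(channel = character(0), interval = integer(0),
             condition = character(0), time = numeric(0),
             amplitude = numeric(0))
    }
    list(recording = rec, truth = truth)
  })
}

# biphasic spike: unit-height positive Gaussian lobe at `at` followed by a
# smaller negative lobe (depolarisation then recovery undershoot)
biphasic_shape <- function(n, at, width) {
  x <- seq_len(n)
  s <- width / 4
  exp(-((x - at)^2) / (2 * s^2)) - 0.3 * exp(-((x - at - width / 2)^2) / (2 * (1.5 * s)^2))
}

# detect spikes on one channel restricted to one half-open interval
detect_in_interval <- function(rec, channel, start, end, prominence,
                               amplitude_cap, min_separation = NULL) {
  seg <- start:(end - 1L)
  x <- rec[[channel]][seg]
  x[is.na(x)] <- 0
  tt <- rec$time[seg]
  detect_spikes(x, prominence = prominence, times = tt,
                amplitude_cap = amplitude_cap,
                min_separation = min_separation)
}

#' Windowed spike census of a recording
#'
#' Counts detected spikes per channel and schedule interval, applying the
#' prominence threshold (default 0.03 mV) and the small-spike amplitude cap
#' (default: keep spikes below 0.1 mV) to each channel restricted to each
#' half-open interval.
#'
#' @param recording a [recording_set()].
#' @param schedule a [load_schedule()]; must lie within the recording.
#' @param prominence prominence threshold, mV.
#' @param amplitude_cap upper prominence bound, mV (`NULL` for no cap).
#' @param min_separation optional minimum spike separation, seconds.
#' @return tibble with columns `channel`, `interval`, `condition`, `n`.
#' @export
spike_census <- function(recording, schedule, prominence = 0.03,
                         amplitude_cap = 0.1, min_separation = NULL) {
  check_schedule_range(recording, schedule)
  chans <- attr(recording, "channels")
  grid <- tidyr::expand_grid(channel = chans, interval = schedule$interval)
  purrr::pmap_dfr(grid, function(channel, interval) {
    r <- schedule[schedule$interval == interval, ]
    sp <- detect_in_interval(recording, channel, r$start, r$end,
                             prominence, amplitude_cap, min_separation)
    tibble(channel = channel, interval = interval,
           condition = r$condition, n = nrow(sp))
  })
}

check_schedule_range <- function(recording, schedule) {
  if (any(schedule$start < 1L) || any(schedule$end > nrow(recording) + 1L))
    abort("schedule interval outside the recording")
  invisible(TRUE)
}

#' Inter-spike-interval histogram by load condition
#'
#' Detects spikes per channel within each schedule interval, computes
#' inter-spike intervals within each channel-interval, pools them per
#' condition and bins them on a common axis so conditions can be overlaid.
#'
#' @inheritParams spike_census
#' @param bin_width histogram bin width, seconds.
#' @return object of class `isi_histogram`: tibble `condition`, `bin_lo`,
#'   `bin_hi`, `bin_mid`, `n`; conditions with fewer than two spikes in
#'   every channel-interval contribute no rows.
#' @export
isi_histogram <- function(recording, schedule, prominence = 0.03,
                          amplitude_cap = 0.1, bin_width = 60) {
  check_schedule_range(recording, schedule)
  chans <- attr(recording, "channels")
  isis <- purrr::pmap_dfr(
    tidyr::expand_grid(channel = chans, interval = schedule$interval),
    function(channel, interval) {
      r <- schedule[schedule$interval == interval, ]
      sp <- detect_in_interval(recording, channel, r$start, r$end,
                               prominence, amplitude_cap)
      iv <- interspike_intervals(sp)
      if (!length(iv)) return(NULL)
      tibble(condition = r$condition, isi = iv)
    })
  if (nrow(isis) == 0) {
    out <- tibble(condition = character(0), bin_lo = numeric(0),
                  bin_hi = numeric(0), bin_mid = numeric(0), n = integer(0))
  } else {
    breaks <- seq(0, (max(isis$isi) %/% bin_width + 1) * bin_width,
                  by = bin_width)
    out <- isis |>
      dplyr::mutate(bin = cut(.data$isi, breaks, right = FALSE)) |>
      dplyr::count(.data$condition, .data$bin, name = "n") |>
      dplyr::mutate(
        bin_lo = breaks[as.integer(.data$bin)],
        bin_hi = breaks[as.integer(.data$bin) + 1L],
        bin_mid = (.data$bin_lo + .data$bin_hi) / 2) |>
      dplyr::select("condition", "bin_lo", "bin_hi", "bin_mid", "n")
  }
  class(out) <- c("isi_histogram", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

#' Spike amplitudes summarised by load condition
#'
#' Summarises detected spike amplitudes (topographic prominences -- robust
#' to baseline drift, unlike absolute voltage) per channel and condition,
#' and reports pairwise differences of condition means within each channel,
#' in particular the signed `even` minus `no-load` difference used to
#' assess the load effect.
#'
#' @inheritParams spike_census
#' @return object of class `amplitude_by_condition`: list with `summary`
#'   (`channel`, `condition`, `mean`, `sd`, `n`) and `differences`
#'   (`channel`, `cond_a`, `cond_b`, `diff` = mean_a - mean_b).
#' @export
amplitude_by_condition <- function(recording, schedule, prominence = 0.03,
                                   amplitude_cap = NULL) {
  check_schedule_range(recording, schedule)
  chans <- attr(recording, "channels")
  amp <- purrr::pmap_dfr(
    tidyr::expand_grid(channel = chans, interval = schedule$interval),
    function(channel, interval) {
      r <- schedule[schedule$interval == interval, ]
      sp <- detect_in_interval(recording, channel, r$start, r$end,
                               prominence, amplitude_cap)
      if (!nrow(sp)) return(NULL)
      tibble(channel = channel, condition = r$condition,
             amplitude = sp$prominence)
    })
  summary <- amp |>
    dplyr::group_by(.data$channel, .data$condition) |>
    dplyr::summarise(mean = mean(.data$amplitude),
                     sd = stats::sd(.data$amplitude),
                     n = dplyr::n(), .groups = "drop")
  conds <- unique(schedule$condition)
  pairs <- if (length(conds) > 1) {
    cmb <- utils::combn(conds, 2)
    purrr::map_dfr(seq_len(ncol(cmb)), function(k) {
      a <- cmb[1, k]; b <- cmb[2, k]
      summary |>
        dplyr::select("channel", "condition", "mean") |>
        tidyr::pivot_wider(names_from = "condition", values_from = "mean") |>
        dplyr::transmute(channel = .data$channel, cond_a = a, cond_b = b,
                         diff = .data[[a]] - .data[[b]])
    })
  } else {
    tibble(channel = character(0), cond_a = character(0),
           cond_b = character(0), diff = numeric(0))
  }
  structure(list(summary = summary, differences = pairs),
            class = "amplitude_by_condition")
}

#' @export
print.amplitude_by_condition <- function(x, ...) {
  cat("<amplitude_by_condition>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.amplitude_by_condition <- function(x, ...) x$summary

#' @export
glance.amplitude_by_condition <- function(x, ...) {
  ev <- x$differences[x$differences$cond_a == "even" &
                        x$differences$cond_b == "no-load", ]
  if (!nrow(ev)) {
    ev2 <- x$differences[x$differences$cond_a == "no-load" &
                           x$differences$cond_b == "even", ]
    ev <- dplyr::mutate(ev2, diff = -.data$diff)
  }
  tibble(n_channels = length(unique(x$summary$channel)),
         n_conditions = length(unique(x$summary$condition)),
         mean_even_minus_noload = if (nrow(ev)) mean(ev$diff) else NA_real_)
}

#' Write a recording set as delimited text
#'
#' @param recording a [recording_set()].
#' @param path output path (tab-separated; `time` column first).
#' @export
write_recording <- function(recording, path) {
  readr::write_tsv(as_tibble(recording), path)
  invisible(path)
}
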