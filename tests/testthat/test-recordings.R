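test_that("load schedules validate their intervals and vocabulary", {
  s <- bench_schedule()
  expect_equal(s$condition, c("no-load", "even", "no-load"))
  expect_error(load_schedule("walking", 1, 10), "conditions")
  expect_error(load_schedule(c("even", "even"), c(1, 5), c(10, 20)),
               "non-overlapping")
  expect_error(load_schedule("even", 10, 10), "end > start")
})

test_that("the recording generator is seed-exact and honest about its plants", {
  sched <- bench_schedule()
  a <- suppressWarnings(synthesize_recording(sched, seed = 3))
  b <- suppressWarnings(synthesize_recording(sched, seed = 3))
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$recording), 5400)
  expect_equal(length(attr(a$recording, "channels")), 8)

  # all-zero rates leave a spike-free trace
  quiet <- synthesize_recording(sched,
                                rates = c("no-load" = 0, "even" = 0),
                                seed = 4)
  expect_equal(nrow(quiet$truth), 0)
  cen <- spike_census(quiet$recording, sched)
  expect_true(all(cen$n <= 2))   # at most stray noise excursions
})

test_that("the census recovers well-separated planted spikes exactly", {
  sched <- bench_schedule()
  syn <- suppressWarnings(synthesize_recording(sched,
                              rates = c("no-load" = 2, "even" = 8),
                              amplitude = c(mean = 0.06, sd = 0.002),
                              noise_sd = 0.002, drift_amplitude = 0.005,
                              seed = 1))
  cen <- spike_census(syn$recording, sched)
  planted <- dplyr::count(syn$truth, channel, interval, name = "n_true")
  cmp <- dplyr::left_join(cen, planted, by = c("channel", "interval"))
  cmp$n_true[is.na(cmp$n_true)] <- 0L
  expect_equal(cmp$n, cmp$n_true)
  # the during-weight window spikes more on every channel, by construction
  wide <- tidyr::pivot_wider(cen, id_cols = "channel",
                             names_from = "interval", values_from = "n")
  expect_true(all(wide$`2` > wide$`1`))
  expect_true(all(wide$`2` > wide$`3`))
})

test_that("sub-threshold planted spikes are rejected at the 0.03 mV threshold", {
  sched <- bench_schedule()
  syn <- synthesize_recording(sched,
                              rates = c("no-load" = 3, "even" = 3),
                              amplitude = c(mean = 0.02, sd = 0.0005),
                              noise_sd = 5e-4, drift_amplitude = 0.001,
                              seed = 7)
  expect_gt(nrow(syn$truth), 0)
  cen <- spike_census(syn$recording, sched)
  expect_true(all(cen$n == 0))
})

test_that("interval restriction is half-open in samples", {
  sched <- load_schedule(c("no-load", "even"), c(1, 101), c(101, 201))
  tt <- 0:199
  mk <- function(at) triangle_trace(200, at, 0.08)
  # sample index k (1-based) belongs to the interval with start <= k < end
  rec <- recording_set(tibble::tibble(time = tt,
                                      `Ch 1-2` = mk(97),
                                      `Ch 3-4` = mk(104)))
  cen <- spike_census(rec, sched, amplitude_cap = NULL)
  w <- tidyr::pivot_wider(cen, id_cols = "channel",
                          names_from = "interval", values_from = "n")
  expect_equal(w$`1`[w$channel == "Ch 1-2"], 1)
  expect_equal(w$`2`[w$channel == "Ch 1-2"], 0)
  expect_equal(w$`1`[w$channel == "Ch 3-4"], 0)
  expect_equal(w$`2`[w$channel == "Ch 3-4"], 1)
  expect_error(spike_census(rec, load_schedule("even", 150, 500)), "outside")
})

test_that("ISI histograms bin pooled intervals per condition on a common axis", {
  sched <- load_schedule(c("no-load", "even"), c(1, 1001), c(1001, 2001))
  tt <- 0:1999
  x <- numeric(2000)
  for (at in seq(100, 900, by = 120)) x <- x + triangle_trace(2000, at, 0.08)
  rec <- recording_set(tibble::tibble(time = tt, `Ch 1-2` = x))
  h <- isi_histogram(rec, sched, bin_width = 60, amplitude_cap = NULL)
  h_no <- h[h$condition == "no-load", ]
  expect_equal(nrow(h_no), 1)                      # one occupied bin
  expect_true(h_no$bin_lo <= 120 & 120 < h_no$bin_hi)
  expect_equal(h_no$n, 6)                          # 7 spikes -> 6 intervals
  expect_false("even" %in% h$condition)            # < 2 spikes there
})

test_that("amplitude summaries recover planted condition effects", {
  sched <- load_schedule(c("no-load", "even"), c(1, 1801), c(1801, 3601))

  # identical planted amplitude distributions: no systematic difference
  # (prominences carry a small undershoot/baseline inflation that is common
  # to both conditions, so only the contrast is expected to vanish)
  same <- suppressWarnings(
    synthesize_recording(sched, rates = c("no-load" = 10, "even" = 10),
                         amplitude = c(mean = 0.06, sd = 0.005), seed = 11))
  res <- amplitude_by_condition(same$recording, sched)
  expect_equal(nrow(res$differences), 8)
  expect_true(all(abs(res$differences$diff) < 0.01))
  expect_lt(abs(mean(res$differences$diff)), 0.005)

  # a planted reduction under load comes out negative on every channel
  eff <- suppressWarnings(
    synthesize_recording(sched, rates = c("no-load" = 10, "even" = 10),
                         amplitude = list("no-load" = c(0.08, 0.01),
                                          "even" = c(0.056, 0.01)),
                         seed = 12))
  res2 <- amplitude_by_condition(eff$recording, sched)
  d <- res2$differences
  sgn <- ifelse(d$cond_a == "even", 1, -1)
  expect_equal(nrow(d), 8)
  expect_true(all(sgn * d$diff < 0))
  expect_lt(glance(res2)$mean_even_minus_noload, 0)

  # spike counts in the summary agree with the census under matched filters
  cen <- spike_census(eff$recording, sched, amplitude_cap = NULL)
  res3 <- amplitude_by_condition(eff$recording, sched, amplitude_cap = NULL)
  joined <- dplyr::inner_join(
    dplyr::count(res3$summary, channel, condition, wt = n, name = "n_amp"),
    dplyr::count(cen, channel, condition, wt = n, name = "n_cen"),
    by = c("channel", "condition"))
  expect_equal(joined$n_amp, joined$n_cen)
})

test_that("logger exports round-trip, clip and flag gaps", {
  sched <- load_schedule("even", 1, 61)
  syn <- synthesize_recording(sched, rates = c("even" = 2), seed = 5,
                              n_channels = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recording(syn$recording, f)
  back <- read_logger_export(f)
  expect_equal(as.data.frame(back), as.data.frame(syn$recording),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_length(attr(back, "gaps"), 0)

  # clipping to the acquisition range, with a warning
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,Ch 1-2", "0,0", "1,200", "2,0", "3,-1"), f2)
  expect_warning(clipped <- read_logger_export(f2), "clipped")
  expect_equal(max(clipped$`Ch 1-2`), 156)

  # a missing second is flagged as a gap
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,Ch 1-2", "0,0", "1,0.1", "3,0.2"), f3)
  gapped <- read_logger_export(f3)
  expect_equal(attr(gapped, "gaps"), 2)
  expect_true(is.na(gapped$`Ch 1-2`[3]))

  # malformed inputs fail loudly, with a line number where sensible
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,Ch 1-2", "0,0", "1,oops"), f4)
  expect_error(read_logger_export(f4), "line 3")
  f5 <- withr::local_tempfile(fileext = ".csv")
  writeLines("", f5)
  expect_error(read_logger_export(f5), "empty")
  f6 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0", "1,1"), f6)
  expect_error(read_logger_export(f6), "header")
})
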