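test_that("spike detection honours the topographic prominence threshold", {
  expect_equal(nrow(detect_spikes(rep(1, 50), prominence = 0.03)), 0)

  tr <- triangle_trace(60, at = 30, height = 0.05)
  sp <- detect_spikes(tr, prominence = 0.03)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$time, 30)
  expect_equal(sp$prominence, 0.05)

  low <- triangle_trace(60, at = 30, height = 0.02)
  expect_equal(nrow(detect_spikes(low, prominence = 0.03)), 0)

  # plateau peaks report their middle sample
  pl <- c(0, 0, 1, 1, 1, 0, 0)
  expect_equal(detect_spikes(pl, prominence = 0.5)$index, 4)

  # prominence is measured against the higher flanking minimum
  x <- c(0, 1, 0.6, 0.9, 0, 2, 0)
  sp2 <- detect_spikes(x, prominence = 0.01)
  expect_equal(sp2$index, c(2, 4, 6))
  expect_equal(sp2$prominence[2], 0.3)   # 0.9 - max(0.6, 0)

  expect_error(detect_spikes(c(1, 2), prominence = 1), "3 samples")
  expect_error(detect_spikes(rep(0, 10), prominence = 0), "> 0")
})

test_that("detection is shift-invariant and scale-equivariant", {
  set.seed(41)
  for (k in 1:5) {
    x <- cumsum(rnorm(300, sd = 0.3))
    base <- detect_spikes(x, prominence = 0.5)
    shifted <- detect_spikes(x + 17.3, prominence = 0.5)
    expect_identical(base$index, shifted$index)
    expect_equal(base$prominence, shifted$prominence, tolerance = 1e-9)
    scaled <- detect_spikes(3 * x, prominence = 3 * 0.5)
    expect_identical(base$index, scaled$index)
    expect_equal(scaled$prominence, 3 * base$prominence, tolerance = 1e-9)
  }
})

test_that("detection agrees with an independent peak-prominence implementation", {
  set.seed(42)
  x <- cumsum(rnorm(400, sd = 0.2)) + 0.5 * sin(seq_len(400) / 15)
  for (thr in c(0.2, 0.5, 1)) {
    ref <- scipy_find_peaks(x, thr)
    expect_false(is.null(ref))
    got <- detect_spikes(x, prominence = thr)
    expect_identical(got$index, ref$index)
    expect_equal(got$prominence, ref$prominence, tolerance = 1e-9)
  }
})

test_that("amplitude caps and minimum separation filter the train", {
  x <- triangle_trace(100, 20, 0.05) + triangle_trace(100, 60, 0.2)
  sp <- detect_spikes(x, prominence = 0.03, amplitude_cap = 0.1)
  expect_equal(sp$time, 20)            # the large spike is capped away
  close_pair <- triangle_trace(100, 40, 0.6, half_width = 2) +
    triangle_trace(100, 44, 0.4, half_width = 2)
  kept <- detect_spikes(close_pair, prominence = 0.1, min_separation = 10)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$time, 40)          # the more prominent of the pair
})

test_that("inter-spike intervals are successive time differences", {
  expect_equal(interspike_intervals(c(10, 30, 70)), c(20, 40))
  expect_equal(interspike_intervals(c(42)), numeric(0))
  expect_equal(interspike_intervals(numeric(0)), numeric(0))
  sp <- detect_spikes(triangle_trace(50, 10, 1) + triangle_trace(50, 35, 1),
                      prominence = 0.5)
  expect_equal(interspike_intervals(sp), 25)
  set.seed(6)
  tt <- sort(sample(1000, 20))
  expect_true(all(interspike_intervals(tt) > 0))
})

test_that("event alignment chains pooled spikes by the separation gap", {
  timing <- gate_timing_params(simultaneity = 200, separation = 1000)

  # single-scenario event
  ev <- align_events(list("01" = numeric(0), "10" = numeric(0), "11" = 5000),
                     timing)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gate, "AND")
  expect_identical(c(ev$s01, ev$s10, ev$s11), c(FALSE, FALSE, TRUE))

  # chained simultaneity: all three scenarios in one event
  ev2 <- align_events(list("01" = 5000, "10" = 5100, "11" = 5150), timing)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$gate, "OR")
  expect_true(ev2$simultaneous)

  # separation beyond the gap splits events
  ev3 <- align_events(list("01" = 1000, "10" = 9000, "11" = numeric(0)),
                      timing)
  expect_equal(nrow(ev3), 2)
  expect_equal(ev3$gate, c("NOT-x-AND-y", "x-AND-NOT-y"))

  # every spike lands in exactly one event
  set.seed(77)
  for (k in 1:5) {
    trains <- list("01" = sort(sample(50000, 8)),
                   "10" = sort(sample(50000, 8)),
                   "11" = sort(sample(50000, 8)))
    ev <- align_events(trains, timing)
    expect_equal(sum(ev$n_spikes), 24)
    expect_true(all(ev$t_start[-1] - ev$t_end[-nrow(ev)] > timing$separation))
  }

  expect_error(gate_timing_params(simultaneity = 2000, separation = 1000),
               "separation")
})

test_that("the 8 presence patterns map onto the Boolean-function lookup", {
  ref <- boolean_function_patterns()
  for (r in seq_len(nrow(ref))) {
    expect_equal(classify_gate(ref$s01[r], ref$s10[r], ref$s11[r]),
                 ref$gate[r])
  }
  expect_equal(classify_gate(TRUE, TRUE, TRUE), "OR")
  expect_equal(classify_gate(FALSE, TRUE, TRUE), "SELECT-x")
  expect_equal(classify_gate(FALSE, FALSE, FALSE), "CONST-FALSE")
  expect_setequal(gate_labels(), ref$gate)   # bijection onto 8 labels
})

test_that("the gate census composes detection, alignment and classification", {
  iters <- seq(0, 20000, by = 50)
  flat <- function(e) bump_trace(iters, e, numeric(0))
  mk <- function(tA, tB) dplyr::bind_rows(tA, tB)

  # electrode A: one OR event; electrode B: two single-input events
  sc <- list(
    "01" = mk(bump_trace(iters, "EA", 5000), bump_trace(iters, "EB", 1000)),
    "10" = mk(bump_trace(iters, "EA", 5100), bump_trace(iters, "EB", 9000)),
    "11" = mk(bump_trace(iters, "EA", 5150), flat("EB")))
  cen <- census_gates(sc, prominence = 0.5)
  ev <- tidy(cen)
  expect_equal(ev$gate[ev$electrode == "EA"], "OR")
  expect_setequal(ev$gate[ev$electrode == "EB"],
                  c("NOT-x-AND-y", "x-AND-NOT-y"))
  expect_equal(sum(cen$counts$n), nrow(ev))
  expect_equal(glance(cen)$n_events, 3L)

  # deterministic on identical inputs
  cen2 <- census_gates(sc, prominence = 0.5)
  expect_identical(cen$events, cen2$events)

  # all-flat traces give an empty census
  empty <- census_gates(list("01" = flat("EA"), "10" = flat("EA"),
                             "11" = flat("EA")), prominence = 0.5)
  expect_equal(nrow(empty$events), 0)

  # mismatched horizons are rejected
  bad <- sc
  bad$`11` <- bump_trace(seq(0, 10000, by = 50), "EA", 5150)
  expect_error(census_gates(bad, prominence = 0.5), "horizon")
})
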