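test_that("electrode potentials sum u - v over the conductive Moore neighbourhood", {
  lay <- electrode_layout(tibble::tibble(electrode = "E1", i = 5, j = 5))
  full <- conductive_template(matrix(1L, 9, 9))

  expect_equal(sample_potential(rest_state(full), lay, "E1", full), 0)

  # only the centre node conductive: a one-term sum
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  tm <- conductive_template(m)
  u <- matrix(0, 9, 9); u[5, 5] <- 0.5
  v <- matrix(0, 9, 9); v[5, 5] <- 0.1
  expect_equal(sample_potential(field_state(u, v), lay, "E1", tm), 0.4)

  # fully conductive neighbourhood at u = 1, v = 0: nine offsets qualify
  u1 <- matrix(1, 9, 9)
  expect_equal(sample_potential(field_state(u1), lay, "E1", full), 9)

  # linear in (u, v)
  set.seed(5)
  ur <- matrix(runif(81), 9); vr <- matrix(runif(81), 9)
  p1 <- sample_potential(field_state(ur, vr), lay, "E1", full)
  p2 <- sample_potential(field_state(2 * ur, 2 * vr), lay, "E1", full)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)

  # centre-summand variant multiplies the centre reading by the count
  expect_equal(sample_potential(field_state(ur, vr), lay, "E1", full,
                                summand = "centre"),
               (ur[5, 5] - vr[5, 5]) * 9, tolerance = 1e-12)

  expect_error(sample_potential(rest_state(full),
                                electrode_layout(tibble::tibble(
                                  electrode = "EX", i = 99, j = 1)),
                                "EX", full),
               "outside")
})

test_that("activity counts use a strict threshold over conductive nodes", {
  m <- matrix(1L, 6, 6)
  u <- matrix(0, 6, 6); u[1, 1:5] <- 0.2
  expect_equal(total_activity(field_state(u), m), 5)
  u[2, 1] <- 0.1                      # exactly at threshold: not counted
  expect_equal(total_activity(field_state(u), m), 5)
  expect_equal(total_activity(rest_state(m), m), 0)
  # non-conductive nodes never count
  m2 <- m; m2[1, ] <- 0L
  expect_equal(total_activity(field_state(u), m2), 0)
})

test_that("coverage accumulates strictly and normalizes by the maximum", {
  m <- matrix(1L, 3, 3)
  cov <- new_coverage_map(m)
  above <- field_state(matrix(0.2, 3, 3))
  at <- field_state(matrix(0.1, 3, 3))
  for (k in 1:7) cov <- accumulate_coverage(cov, above)
  for (k in 1:3) cov <- accumulate_coverage(cov, at)   # u = 0.1 not counted
  expect_true(all(unclass(cov) == 7L))

  raw <- new_coverage_map(m)
  raw[] <- c(0L, 3L, 6L, 0L, 0L, 0L, 0L, 0L, 0L)
  nm <- normalize_coverage(raw)
  expect_equal(sort(unique(as.vector(nm))), c(0, 0.5, 1))
  expect_equal(max(nm), 1)

  zero <- normalize_coverage(new_coverage_map(m))
  expect_true(all(unclass(zero) == 0))
})

test_that("snapshots show conductive nodes above the display threshold", {
  m <- matrix(1L, 4, 4); m[1, ] <- 0L
  u <- matrix(0, 4, 4); u[1, 2] <- 0.9; u[3, 3] <- 0.05; u[4, 4] <- 0.03
  fr <- render_snapshot(field_state(u), m)
  expect_identical(dim(fr), c(4L, 4L))
  expect_false(fr[1, 2])      # non-conductive, even though u is high
  expect_true(fr[3, 3])       # wave-front level u = 0.05 > 0.04
  expect_false(fr[4, 4])      # below display threshold
  expect_equal(sum(render_snapshot(rest_state(m), m)), 0)
})

test_that("the default layout places 16 electrodes toe-to-heel on the network", {
  tm <- generate_mycelium(insole_mask(96, 240), seed = 2)
  lay <- default_electrode_layout(tm)
  expect_equal(nrow(lay), 16)
  expect_false(anyDuplicated(lay$electrode) > 0)
  g <- unclass_mat(tm)
  expect_true(all(g[cbind(lay$i, lay$j)] == 1L))
  e <- function(id) lay[lay$electrode == id, ]
  expect_lt(e("E1")$j, e("E2")$j)              # E1 toe lobe, E2 heel lobe
  mid <- lay[!lay$electrode %in% c("E1", "E2"), ]
  expect_true(all(diff(mid$j) > 0))            # E3..E16 run toe to heel
  expect_true(all(mid$j > e("E1")$j & mid$j < e("E2")$j))
})

test_that("in-loop recorders match the module operations applied to saved fields", {
  set.seed(18)
  m <- random_template(12, 12, p = 0.7)
  tm <- conductive_template(m)
  lay <- electrode_layout(tibble::tibble(electrode = c("E1", "E2"),
                                         i = c(4, 9), j = c(4, 9)))
  sim <- fhn_simulate(tm, fhn_params(c2 = 0.015),
                      stimulus_spec(c(4, 4), radius = 3),
                      n_iter = 60, layout = lay, record_every = 1,
                      record_fields = TRUE, track_max_u = TRUE)
  cov <- new_coverage_map(m)
  for (k in seq_along(sim$fields)) {
    st <- field_state(sim$fields[[k]], sim$fields_v[[k]])
    expect_equal(sim$activity[k], total_activity(st, tm))
    expect_equal(unname(sim$potentials[k, "E1"]),
                 sample_potential(st, lay, "E1", tm), tolerance = 1e-12)
    expect_equal(unname(sim$potentials[k, "E2"]),
                 sample_potential(st, lay, "E2", tm), tolerance = 1e-12)
    if (k > 1) cov <- accumulate_coverage(cov, st)   # engine skips iteration 0
  }
  expect_identical(unclass(sim$coverage_raw), matrix(as.integer(cov), 12, 12))
  expect_equal(length(sim$max_u), 61)
  expect_equal(sim$max_u[1], 1)       # stimulus value at iteration 0
})

test_that("trace accessors and exports are tidy and faithful", {
  tm <- conductive_template(matrix(1L, 10, 10))
  lay <- electrode_layout(tibble::tibble(electrode = c("E1", "E2"),
                                         i = c(3, 8), j = c(3, 8)))
  sim <- fhn_simulate(tm, fhn_params(c2 = 0.015), stimulus_spec(c(3, 3)),
                      n_iter = 40, layout = lay, record_every = 10)
  tr <- potential_traces(sim)
  expect_identical(names(tr), c("iteration", "electrode", "potential"))
  expect_equal(nrow(tr), 2 * 5)       # 2 electrodes x (4 records + initial)
  expect_identical(tidy(sim), tr)

  g <- glance(sim)
  expect_equal(g$n_iter, 40L)
  expect_equal(g$n_electrodes, 2L)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_traces(sim, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$E1, sim$potentials[, "E1"], tolerance = 1e-12)

  fc <- withr::local_tempfile(fileext = ".txt")
  write_coverage(coverage_map(sim, normalized = FALSE), fc)
  m2 <- as.matrix(read.table(fc))
  expect_equal(unname(m2), unclass(sim$coverage_raw), ignore_attr = TRUE)
})
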