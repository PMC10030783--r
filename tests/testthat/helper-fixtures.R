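# small programmatic fixtures shared across test files

# trace with a triangular bump of the given height at `at`
triangle_trace <- function(n, at, height, half_width = 3) {
  x <- numeric(n)
  for (d in -half_width:half_width)
    if (at + d >= 1 && at + d <= n)
      x[at + d] <- height * (1 - abs(d) / (half_width + 1))
  x
}

# long-form potential-trace tibble for one electrode with bumps at `times`
bump_trace <- function(iterations, electrode, times, height = 1) {
  x <- numeric(length(iterations))
  for (t in times) x <- x + triangle_trace(length(iterations), match(t, iterations), height)
  tibble::tibble(iteration = iterations, electrode = electrode, potential = x)
}

# a 3-interval before/during/after bench schedule at 30-minute windows
bench_schedule <- function() {
  load_schedule(c("no-load", "even", "no-load"),
                start = c(1, 1801, 3601), end = c(1801, 3601, 5401))
}

# strip template class/attributes down to the bare integer matrix
unclass_mat <- function(x) {
  attr(x, "mask") <- NULL
  class(x) <- NULL
  matrix(as.integer(x), nrow(x), ncol(x))
}
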