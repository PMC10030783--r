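#' Virtual electrode layouts
#'
#' An electrode layout is a tibble with columns `electrode` (unique id),
#' `i`, `j` (1-based node coordinates). Each electrode samples the
#' conductive nodes `y` within Euclidean distance `< 2` of its centre `x`
#' -- the 3x3 Moore neighbourhood, since the distance-2 orthogonal
#' neighbours are excluded by the strict inequality.
#'
#' `electrode_layout()` validates a user-supplied table;
#' `default_electrode_layout()` places `n` electrodes evenly along the
#' medial axis of a template's mask, with `E1` in the toe lobe (low column
#' indices), `E2` in the heel lobe (high column indices) -- mirroring the
#' two stimulation loci -- and `E3..En` filling in between from toe to heel.
#'
#' @param layout data frame with columns `electrode`, `i`, `j`.
#' @param template a [conductive_template()] (used for bounds checking when
#'   supplied).
#' @return a tibble of class `electrode_layout`.
#' @export
electrode_layout <- function(layout, template = NULL) {
  layout <- as_tibble(layout)
  if (!all(c("electrode", "i", "j") %in% names(layout)))
    abort("layout needs columns `electrode`, `i`, `j`")
  if (anyDuplicated(layout$electrode)) abort("electrode ids must be unique")
  if (!is.null(template)) {
    g <- template_grid(template)
    if (any(layout$i < 1 | layout$i > nrow(g) | layout$j < 1 | layout$j > ncol(g)))
      abort("electrode coordinates outside the grid")
  }
  class(layout) <- c("electrode_layout", class(layout))
  layout
}

#' @rdname electrode_layout
#' @param n number of electrodes (default 16).
#' @export
default_electrode_layout <- function(template, n = 16) {
  g <- template_grid(template)
  mask <- attr(template, "mask") %||% g
  cols <- which(colSums(mask) > 0)
  if (!length(cols)) abort("template/mask is empty")
  lo <- stats::quantile(cols, 0.06); hi <- stats::quantile(cols, 0.94)
  jj <- round(seq(lo, hi, length.out = n))
  ii <- vapply(jj, function(j) {
    rows <- which(mask[, j] > 0)
    if (!length(rows)) round(nrow(g) / 2) else round(mean(rows))
  }, numeric(1))
  # snap each site to the nearest conductive node (within a local window)
  for (k in seq_len(n)) {
    if (g[ii[k], jj[k]] == 1L) next
    win <- 15L
    is <- max(1L, ii[k] - win):min(nrow(g), ii[k] + win)
    js <- max(1L, jj[k] - win):min(ncol(g), jj[k] + win)
    sub <- g[is, js, drop = FALSE]
    if (any(sub == 1L)) {
      w <- which(sub == 1L, arr.ind = TRUE)
      d <- (is[w[, 1]] - ii[k])^2 + (js[w[, 2]] - jj[k])^2
      b <- which.min(d)
      ii[k] <- is[w[b, 1]]; jj[k] <- js[w[b, 2]]
    }
  }
  # E1 = toe end, E2 = heel end, E3..En from toe to heel between them
  ord <- c(1L, n, seq(2L, n - 1L))
  electrode_layout(tibble(
    electrode = paste0("E", seq_len(n)),
    i = ii[ord], j = jj[ord]))
}

# 1-based flat indices of conductive nodes with |x - y| < 2 of each electrode
electrode_neighbourhoods <- function(layout, grid) {
  n_i <- nrow(grid); n_j <- ncol(grid)
  off <- expand.grid(di = -1:1, dj = -1:1)  # all 9 satisfy di^2 + dj^2 < 4
  lapply(seq_len(nrow(layout)), function(k) {
    ii <- layout$i[k] + off$di
    jj <- layout$j[k] + off$dj
    ok <- ii >= 1 & ii <= n_i & jj >= 1 & jj <= n_j
    ii <- ii[ok]; jj <- jj[ok]
    ok <- grid[cbind(ii, jj)] == 1L
    as.integer((jj[ok] - 1L) * n_i + ii[ok])
  })
}

#' Sample the potential at one electrode
#'
#' The electrode potential is the sum of `u - v` over the conductive nodes
#' in the electrode's 3x3 Moore neighbourhood (Euclidean distance < 2 from
#' the centre). With `summand = "centre"` the centre node's `u - v` is used
#' for every neighbourhood node instead (the literal reading of the printed
#' electrode formula, kept available for comparison).
#'
#' @param state a [field_state()].
#' @param layout an [electrode_layout()].
#' @param electrode electrode id (character) or row index.
#' @param template a [conductive_template()].
#' @param summand `"neighbour"` (default) or `"centre"`.
#' @return scalar potential (model units).
#' @export
sample_potential <- function(state, layout, electrode, template,
                             summand = c("neighbour", "centre")) {
  summand <- match.arg(summand)
  g <- template_grid(template)
  k <- if (is.character(electrode)) match(electrode, layout$electrode) else electrode
  if (is.na(k)) abort("unknown electrode id")
  if (layout$i[k] < 1 || layout$i[k] > nrow(g) ||
      layout$j[k] < 1 || layout$j[k] > ncol(g))
    abort("electrode coordinate outside the grid")
  idx <- electrode_neighbourhoods(layout[k, , drop = FALSE], g)[[1]]
  if (summand == "centre") {
    c0 <- (layout$j[k] - 1L) * nrow(g) + layout$i[k]
    (state$u[c0] - state$v[c0]) * length(idx)
  } else {
    sum(state$u[idx] - state$v[idx])
  }
}

#' Count of excited conductive nodes
#'
#' Number of conductive nodes with `u` strictly greater than the threshold
#' (default 0.1), the instantaneous network-activity measure.
#'
#' @param state a [field_state()].
#' @param template a [conductive_template()].
#' @param threshold activity threshold on `u`.
#' @return non-negative integer count.
#' @export
total_activity <- function(state, template, threshold = 0.1) {
  g <- template_grid(template)
  sum(state$u > threshold & g == 1L)
}

#' Coverage-frequency maps
#'
#' The raw coverage at a node is the number of recorded iterations at which
#' its excitation `u` strictly exceeded the threshold.
#' `new_coverage_map()` builds an empty map, [accumulate_coverage()] adds
#' one state, and [normalize_coverage()] divides by the grid-wide maximum
#' (an all-zero map stays all-zero, so never-excited regions map to 0).
#'
#' @param template a [conductive_template()].
#' @param threshold activity threshold on `u` (default 0.1).
#' @return `coverage_map` object: integer matrix of raw counts with a
#'   `threshold` attribute; normalized maps are numeric in `[0, 1]` with
#'   attribute `normalized = TRUE`.
#' @export
new_coverage_map <- function(template, threshold = 0.1) {
  g <- template_grid(template)
  structure(matrix(0L, nrow(g), ncol(g)), threshold = threshold,
            normalized = FALSE, class = c("coverage_map", "matrix", "array"))
}

#' @rdname new_coverage_map
#' @param coverage a raw `coverage_map`.
#' @param state a [field_state()].
#' @export
accumulate_coverage <- function(coverage, state) {
  if (any(dim(coverage) != dim(state$u)))
    abort("coverage map and state dimensions differ")
  if (isTRUE(attr(coverage, "normalized")))
    abort("cannot accumulate into a normalized map")
  out <- unclass(coverage) + (state$u > attr(coverage, "threshold"))
  structure(matrix(as.integer(out), nrow(out), ncol(out)),
            threshold = attr(coverage, "threshold"), normalized = FALSE,
            class = class(coverage))
}

#' @rdname new_coverage_map
#' @export
normalize_coverage <- function(coverage) {
  m <- max(coverage)
  out <- if (m > 0) unclass(coverage) / m else unclass(coverage) * 0
  structure(matrix(as.numeric(out), nrow(out), ncol(out)),
            threshold = attr(coverage, "threshold"), normalized = TRUE,
            class = c("coverage_map", "matrix", "array"))
}

#' Coverage map of a simulation
#'
#' @param sim an `fhn_sim` result.
#' @param normalized return the map normalized by its maximum (default) or
#'   the raw iteration counts.
#' @return a `coverage_map`.
#' @export
coverage_map <- function(sim, normalized = TRUE) {
  if (is.null(sim$coverage_raw)) abort("simulation was run without coverage tracking")
  raw <- structure(sim$coverage_raw, threshold = sim$activity_threshold,
                   normalized = FALSE,
                   class = c("coverage_map", "matrix", "array"))
  if (normalized) normalize_coverage(raw) else raw
}

#' Binary display snapshot of a field state
#'
#' Foreground = conductive nodes with `u` strictly above the display
#' threshold (default 0.04); everything else, including non-conductive
#' nodes, is background.
#'
#' @param state a [field_state()].
#' @param template a [conductive_template()].
#' @param display_threshold display threshold on `u`.
#' @return logical matrix with the grid's dimensions.
#' @export
render_snapshot <- function(state, template, display_threshold = 0.04) {
  g <- template_grid(template)
  state$u > display_threshold & g == 1L
}

#' Tidy accessors for simulation recordings
#'
#' `potential_traces()` returns the virtual-electrode potential recordings
#' in long form (`iteration`, `electrode`, `potential`);
#' `activity_trace()` returns the excited-node counts (`iteration`,
#' `active`).
#'
#' @param sim an `fhn_sim` result.
#' @return a tibble.
#' @export
potential_traces <- function(sim) {
  p <- sim$potentials
  if (ncol(p) == 0)
    return(tibble(iteration = integer(0), electrode = character(0),
                  potential = numeric(0)))
  as_tibble(p) |>
    dplyr::mutate(iteration = sim$rec_iter, .before = 1) |>
    tidyr::pivot_longer(-"iteration", names_to = "electrode",
                        values_to = "potential") |>
    dplyr::arrange(.data$electrode, .data$iteration)
}

#' @rdname potential_traces
#' @export
activity_trace <- function(sim) {
  tibble(iteration = sim$rec_iter, active = sim$activity)
}

#' @rdname potential_traces
#' @param path output file; tab-delimited, column 1 = iteration then one
#'   column per electrode.
#' @export
write_traces <- function(sim, path) {
  wide <- tibble(iteration = sim$rec_iter) |>
    dplyr::bind_cols(as_tibble(sim$potentials))
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Export a coverage map as text and 16-bit greyscale PNG
#'
#' @param coverage a `coverage_map`.
#' @param path output path; `.png` writes 16-bit greyscale (0 = never
#'   covered, white = maximum), anything else a plain-text count/value
#'   matrix.
#' @export
write_coverage <- function(coverage, path) {
  if (grepl("\\.png$", path)) {
    m <- unclass(normalize_coverage(coverage))
    png::writePNG(m, path, bits.per.sample = 16L)
  } else {
    utils::write.table(unclass(coverage), path,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @export
tidy.fhn_sim <- function(x, ...) potential_traces(x)

#' @export
glance.fhn_sim <- function(x, ...) {
  cov <- if (is.null(x$coverage_raw)) NA_real_ else {
    cond <- sum(x$template)
    sum(x$coverage_raw > 0 & unclass_template(x$template) == 1L) / cond
  }
  tibble(
    n_iter = x$n_iter,
    n_conductive = sum(x$template),
    n_electrodes = ncol(x$potentials),
    final_activity = x$activity[length(x$activity)],
    peak_activity = max(x$activity),
    coverage_fraction = cov)
}
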