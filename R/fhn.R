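#' FitzHugh--Nagumo model parameters
#'
#' Parameter set for the two-variable excitable-medium model integrated on
#' the conductive template:
#' \deqn{\partial u/\partial t = c_1 u (u-a)(1-u) - c_2 u v + I + D_u \nabla^2 u}
#' \deqn{\partial v/\partial t = b (u - v)}
#' where `u` is the trans-membrane potential and `v` the slow recovery
#' current. The cubic reaction term has stable fixed points at `u = 0` and
#' `u = 1` and an unstable excitation threshold at `u = a`. `c2` scales the
#' `u v` negative feedback and is the excitability dial; the endpoints of
#' its working range are 0.015 and 0.05 (see [fhn_excitability_scan()]).
#'
#' @param du diffusion conductance of `u`.
#' @param a excitation threshold, in `(0, 1)`.
#' @param b recovery rate.
#' @param c1 cubic reaction coefficient.
#' @param c2 recovery-coupling coefficient (excitability dial).
#' @param I external stimulation current (default none).
#' @param dt Euler time step. The default satisfies the explicit stability
#'   bound comfortably (`du * dt / dx^2 = 0.00375`).
#' @param dx grid spacing.
#' @return list of class `fhn_params`.
#' @export
fhn_params <- function(du = 1, a = 0.13, b = 0.013, c1 = 0.26, c2 = 0.05,
                       I = 0, dt = 0.015, dx = 2) {
  if (dt <= 0) abort("`dt` must be > 0")
  if (dx <= 0) abort("`dx` must be > 0")
  if (du < 0) abort("`du` must be >= 0")
  if (a <= 0 || a >= 1) abort("`a` must lie in (0, 1)")
  structure(list(du = du, a = a, b = b, c1 = c1, c2 = c2,
                 I = I, dt = dt, dx = dx),
            class = "fhn_params")
}

#' Local reaction kinetics of the excitation variable
#'
#' Evaluates `c1 * u * (u - a) * (1 - u) - c2 * u * v + I`, the non-diffusive
#' part of the `u` equation; useful for fixed-point and stability analysis.
#'
#' @param u,v field values (vectorised).
#' @param params an [fhn_params()] object.
#' @return numeric vector of du/dt contributions.
#' @export
fhn_reaction <- function(u, v = 0, params = fhn_params()) {
  params$c1 * u * (u - params$a) * (1 - u) - params$c2 * u * v + params$I
}

#' Per-node field state
#'
#' Holds the excitation field `u`, recovery field `v` and the iteration
#' counter. Non-conductive nodes must be (and stay) exactly zero.
#'
#' @param u,v numeric matrices, same dimensions as the template.
#' @param t iteration counter.
#' @param template optional [conductive_template()] used to validate masking.
#' @return object of class `field_state`.
#' @export
field_state <- function(u, v = NULL, t = 0L, template = NULL) {
  if (!is.matrix(u)) abort("`u` must be a matrix")
  if (is.null(v)) v <- matrix(0, nrow(u), ncol(u))
  if (any(dim(v) != dim(u))) abort("`u` and `v` dimensions differ")
  if (!is.null(template)) {
    g <- template_grid(template)
    if (any(dim(g) != dim(u))) abort("state and template dimensions differ")
    u[g == 0L] <- 0
    v[g == 0L] <- 0
  }
  structure(list(u = u, v = v, t = as.integer(t)), class = "field_state")
}

#' Rest state on a template
#'
#' @param template a [conductive_template()].
#' @return a [field_state()] with `u = v = 0` everywhere.
#' @export
rest_state <- function(template) {
  g <- template_grid(template)
  field_state(matrix(0, nrow(g), ncol(g)))
}

#' Masked five-node Laplacian with no-flux boundaries
#'
#' Discrete Laplacian `(sum of 4-neighbours - 4 u) / dx^2` evaluated on the
#' conductive set only. A neighbour that is off-grid or non-conductive is
#' mirrored to the centre value, the discrete form of the impermeable
#' boundary condition `du/dn = 0`; the output is zero at non-conductive
#' nodes.
#'
#' @param u numeric matrix (zero outside the conductive set).
#' @param template a [conductive_template()] or binary matrix.
#' @param dx grid spacing.
#' @return numeric matrix of the same dimensions.
#' @export
masked_laplacian <- function(u, template, dx = 2) {
  g <- template_grid(template)
  if (!is.matrix(u) || any(dim(u) != dim(g)))
    abort("field and template dimensions differ")
  masked_laplacian_cpp(u, g, dx)
}

#' One synchronous Euler step of the masked FHN system
#'
#' Advances `(u, v)` by one explicit Euler step using the pre-step fields
#' throughout. Non-conductive nodes are untouched (they stay zero).
#'
#' @param state a [field_state()].
#' @param params an [fhn_params()].
#' @param template a [conductive_template()].
#' @return the advanced [field_state()] (`t` incremented).
#' @export
euler_step <- function(state, params, template) {
  g <- template_grid(template)
  out <- euler_step_cpp(state$u, state$v, g,
                        params$du, params$a, params$b, params$c1, params$c2,
                        params$I, params$dt, params$dx)
  field_state(out$u, out$v, state$t + 1L)
}

#' Stimulus specification
#'
#' An instantaneous perturbation: at iteration `at`, the excitation field is
#' set to `value` on the conductive nodes within Euclidean distance
#' `radius` of each centre. The default radius 1.8 covers a 9-node disc
#' (centre, 4-neighbours and diagonals), i.e. the "small area, c. 10 nodes"
#' used to imitate pressure at an electrode site.
#'
#' @param centres integer matrix/data frame with columns `i`, `j` (1-based
#'   node coordinates), or a length-2 vector for a single site.
#' @param radius disc radius in node units (strict inequality).
#' @param value value assigned to `u` at the stimulated nodes.
#' @param at iteration at which the stimulus is applied.
#' @param label optional scenario label (e.g. `"E1"`, `"E2"`, `"E1+E2"`).
#' @return list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(centres, radius = 1.8, value = 1, at = 0L,
                          label = NULL) {
  if (is.null(dim(centres))) centres <- matrix(centres, nrow = 1)
  centres <- as.matrix(centres)[, 1:2, drop = FALSE]
  colnames(centres) <- c("i", "j")
  if (radius <= 0) abort("`radius` must be > 0")
  structure(list(centres = centres, radius = radius, value = value,
                 at = as.integer(at), label = label),
            class = "stimulus_spec")
}

# conductive nodes (1-based flat, column-major) within `radius` of the centres
stimulus_nodes <- function(stim, grid) {
  n_i <- nrow(grid); n_j <- ncol(grid)
  r <- stim$radius
  off <- expand.grid(di = -ceiling(r):ceiling(r), dj = -ceiling(r):ceiling(r))
  off <- off[off$di^2 + off$dj^2 < r^2, , drop = FALSE]
  idx <- integer(0)
  for (k in seq_len(nrow(stim$centres))) {
    ii <- stim$centres[k, 1] + off$di
    jj <- stim$centres[k, 2] + off$dj
    ok <- ii >= 1 & ii <= n_i & jj >= 1 & jj <= n_j
    ii <- ii[ok]; jj <- jj[ok]
    ok <- grid[cbind(ii, jj)] == 1L
    idx <- c(idx, (jj[ok] - 1L) * n_i + ii[ok])
  }
  unique(idx)
}

#' Apply a stimulus to a field state
#'
#' Sets `u` to the stimulus value at the conductive nodes within the
#' stimulus radius of each centre; `v` is unchanged. If no conductive node
#' falls inside any disc a warning is raised and the state returned
#' unchanged.
#'
#' @param state a [field_state()].
#' @param stim a [stimulus_spec()].
#' @param template a [conductive_template()].
#' @return the perturbed [field_state()].
#' @export
apply_stimulus <- function(state, stim, template) {
  g <- template_grid(template)
  if (any(stim$centres[, 1] < 1 | stim$centres[, 1] > nrow(g) |
          stim$centres[, 2] < 1 | stim$centres[, 2] > ncol(g)))
    abort("stimulus centre outside the grid")
  idx <- stimulus_nodes(stim, g)
  if (!length(idx)) {
    warn("stimulus disc contains no conductive nodes; state unchanged")
    return(state)
  }
  u <- state$u
  u[idx] <- stim$value
  field_state(u, state$v, state$t)
}

#' Integrate the FHN system on a template with recorders
#'
#' Runs the masked FitzHugh--Nagumo dynamics for `n_iter` Euler steps,
#' applying each stimulus at its scheduled iteration, and records
#' virtual-electrode potentials, the total-activity trace (number of
#' conductive nodes with `u` above `activity_threshold`), excited-region
#' extents, per-node coverage counts, and optionally binary display
#' snapshots (`u > snapshot_threshold`) and full `u` fields. The run is
#' bit-reproducible: it uses no random numbers.
#'
#' @param template a [conductive_template()].
#' @param params an [fhn_params()].
#' @param stimuli a [stimulus_spec()] or list of them (empty list for none).
#' @param n_iter number of Euler iterations (>= 1).
#' @param layout an electrode layout tibble (see [electrode_layout()]);
#'   `NULL` records no potentials.
#' @param record_every stride (iterations) for potentials/activity records;
#'   the initial state is always included as iteration 0.
#' @param activity_threshold threshold on `u` for the activity count and
#'   coverage map (default 0.1).
#' @param summand electrode summand: `"neighbour"` sums `u - v` over the
#'   conductive 3x3 neighbourhood (default); `"centre"` multiplies the
#'   centre-node `u - v` by the neighbourhood size (the literal reading of
#'   the printed formula).
#' @param coverage,track_max_u logical switches for the coverage map and the
#'   per-iteration maximum-`u` trace.
#' @param snapshot_every stride for binary display snapshots (0 = none).
#' @param snapshot_threshold display threshold for snapshots (default 0.04).
#' @param record_fields also store the full `u` field at every record
#'   stride (memory-heavy; small grids only).
#' @param state optional initial [field_state()] (default: rest).
#' @return object of class `fhn_sim`; see [tidy.fhn_sim()], [glance.fhn_sim()]
#'   and the accessors [potential_traces()], [activity_trace()],
#'   [coverage_map()].
#' @export
fhn_simulate <- function(template, params = fhn_params(), stimuli = list(),
                         n_iter, layout = NULL,
                         record_every = 1L,
                         activity_threshold = 0.1,
                         summand = c("neighbour", "centre"),
                         coverage = TRUE, track_max_u = FALSE,
                         snapshot_every = 0L, snapshot_threshold = 0.04,
                         record_fields = FALSE,
                         state = NULL) {
  g <- template_grid(template)
  if (!any(g == 1L)) abort("template has no conductive nodes")
  if (n_iter < 1) abort("`n_iter` must be >= 1")
  summand <- match.arg(summand)
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  if (is.null(state)) state <- rest_state(g)

  stim_idx <- lapply(stimuli, function(s) {
    idx <- stimulus_nodes(s, g)
    if (!length(idx)) warn("stimulus disc contains no conductive nodes")
    as.integer(idx - 1L)
  })
  stim_iter <- vapply(stimuli, function(s) s$at, integer(1))
  stim_val <- vapply(stimuli, function(s) s$value, numeric(1))

  if (is.null(layout)) {
    elec_idx <- list(); elec_centre <- integer(0); elec_n <- integer(0)
    elec_ids <- character(0)
  } else {
    nb <- electrode_neighbourhoods(layout, g)
    elec_idx <- lapply(nb, function(x) as.integer(x - 1L))
    elec_centre <- as.integer((layout$j - 1L) * nrow(g) + layout$i - 1L)
    elec_n <- vapply(nb, length, integer(1))
    elec_ids <- layout$electrode
  }

  res <- fhn_simulate_cpp(
    g, state$u, state$v,
    params$du, params$a, params$b, params$c1, params$c2,
    params$I, params$dt, params$dx,
    as.integer(n_iter),
    as.integer(stim_iter), stim_idx, stim_val,
    elec_idx, elec_centre, elec_n,
    summand == "centre",
    as.integer(record_every),
    activity_threshold,
    coverage, track_max_u,
    as.integer(snapshot_every), snapshot_threshold,
    record_fields)

  pots <- res$potentials
  colnames(pots) <- elec_ids
  structure(list(
    template = conductive_template(g),
    params = params,
    layout = layout,
    n_iter = as.integer(n_iter),
    record_every = as.integer(record_every),
    activity_threshold = activity_threshold,
    rec_iter = res$rec_iter,
    potentials = pots,
    activity = res$activity,
    extents = res$extents,
    coverage_raw = res$coverage,
    max_u = res$max_u,
    snapshots = res$snapshots,
    snapshot_every = as.integer(snapshot_every),
    snapshot_threshold = snapshot_threshold,
    fields = res$fields,
    fields_v = res$fields_v,
    final = field_state(res$u, res$v, res$t)
  ), class = "fhn_sim")
}

#' @export
print.fhn_sim <- function(x, ...) {
  cat(sprintf(
    "<fhn_sim> %d iterations on %d x %d template (%d conductive nodes)\n",
    x$n_iter, nrow(x$template), ncol(x$template), sum(x$template)))
  cat(sprintf("  electrodes: %d; records every %d iterations (%d rows)\n",
              ncol(x$potentials), x$record_every, length(x$rec_iter)))
  cat(sprintf("  final activity (u > %g): %d nodes\n",
              x$activity_threshold, x$activity[length(x$activity)]))
  invisible(x)
}

#' Excitability scan over the c2 endpoints
#'
#' Runs a centre-stimulated wave on a uniform fully conductive grid at each
#' supplied `c2` and reports whether a propagating closed wave reached all
#' four grid edges, together with the excited-node count at the final
#' iteration. The model's published working range for `c2` is 0.015--0.05;
#' which endpoint sustains a wave is an empirical property of the kinetics,
#' and this scan is how the package documents it (with these defaults the
#' *lower* endpoint, `c2 = 0.015`, is the excitable one).
#'
#' @param c2_values numeric vector of `c2` values to scan.
#' @param n_iter iterations per run. The front speed implied by the default
#'   constants is about 1.5e-3 nodes per iteration, so crossing half of a
#'   100-node grid takes roughly 4e4 iterations; the default leaves margin.
#' @param activity_at iteration at which the excited-node count is compared
#'   across endpoints (must be a multiple of 500 within `n_iter`).
#' @param grid_size side of the square uniform test grid.
#' @param params base [fhn_params()] (its `c2` is overridden).
#' @return tibble with one row per `c2`: `c2`, `reached_all_edges`,
#'   `activity_at` (count at the comparison iteration), `final_activity`,
#'   `peak_activity`.
#' @export
fhn_excitability_scan <- function(c2_values = c(0.015, 0.05),
                                  n_iter = 50000,
                                  activity_at = 20000,
                                  grid_size = 100,
                                  params = fhn_params()) {
  tmpl <- conductive_template(matrix(1L, grid_size, grid_size))
  stim <- centre_stimulus(grid_size)
  purrr::map_dfr(c2_values, function(c2) {
    p <- params; p$c2 <- c2
    sim <- fhn_simulate(tmpl, p, stim, n_iter = n_iter,
                        record_every = 500L, coverage = TRUE)
    cov <- sim$coverage_raw
    edges <- c(any(cov[1, ] > 0), any(cov[grid_size, ] > 0),
               any(cov[, 1] > 0), any(cov[, grid_size] > 0))
    at <- match(activity_at, sim$rec_iter)
    tibble(c2 = c2,
           reached_all_edges = all(edges),
           activity_at = sim$activity[at],
           final_activity = sim$activity[length(sim$activity)],
           peak_activity = max(sim$activity))
  })
}

# centre stimulus that respects the symmetry group of even- and odd-sized
# square grids: discs on the 1 or 4 central nodes
centre_stimulus <- function(grid_size, radius = 1.8, value = 1) {
  c0 <- (grid_size + 1) / 2
  ctr <- unique(expand.grid(i = c(floor(c0), ceiling(c0)),
                            j = c(floor(c0), ceiling(c0))))
  stimulus_spec(as.matrix(ctr), radius = radius, value = value, at = 0L)
}
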