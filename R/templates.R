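#' Conductive templates for the excitable-medium simulator
#'
#' A conductive template is a binary grid marking which nodes of the
#' simulation lattice are occupied by mycelium and therefore participate in
#' the reaction--diffusion dynamics. Templates are derived from RGB images of
#' colonies ([binarize_image()]), or grown synthetically
#' ([generate_mycelium()]) inside a foot-shaped mask ([insole_mask()]).
#'
#' @param grid integer/logical matrix of 0/1 node conductivities.
#' @param mask optional binary matrix of the same dimensions restricting the
#'   domain (e.g. an insole outline). When supplied, conductive nodes must
#'   lie inside it.
#'
#' @return An object of class `conductive_template`: the 0/1 integer matrix
#'   with an optional `mask` attribute.
#' @export
conductive_template <- function(grid, mask = NULL) {
  if (!is.matrix(grid)) abort("`grid` must be a matrix")
  g <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  if (!is.null(mask)) {
    if (!is.matrix(mask) || any(dim(mask) != dim(g)))
      abort("`mask` must be a matrix with the same dimensions as `grid`")
    mask <- matrix(as.integer(mask != 0), nrow(g), ncol(g))
    if (any(g == 1L & mask == 0L))
      abort("conductive nodes must lie inside the supplied mask")
  }
  structure(g, mask = mask, class = c("conductive_template", "matrix", "array"))
}

#' @export
print.conductive_template <- function(x, ...) {
  cat(sprintf(
    "<conductive_template> %d x %d nodes, %d conductive (%.1f%%)%s\n",
    nrow(x), ncol(x), sum(x), 100 * mean(x),
    if (is.null(attr(x, "mask"))) "" else ", masked"))
  invisible(x)
}

template_grid <- function(template) {
  if (inherits(template, "conductive_template")) {
    unclass_template(template)
  } else if (is.matrix(template)) {
    matrix(as.integer(template != 0), nrow(template), ncol(template))
  } else {
    abort("expected a `conductive_template` or a binary matrix")
  }
}

unclass_template <- function(x) {
  attr(x, "mask") <- NULL
  class(x) <- NULL
  matrix(as.integer(x), nrow(x), ncol(x))
}

#' Read a raster image into an RGB array
#'
#' Reads PNG/JPEG/TIFF rasters into an integer RGB array with channel values
#' in 0--255, the representation [binarize_image()] expects. Greyscale
#' images are replicated across the three channels.
#'
#' @param path path to a PNG, JPEG or TIFF file.
#' @return integer array `height x width x 3` with values in `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores images x-by-y; transpose to row (i) = image row
  if (length(dim(a)) == 2L) {
    a <- array(rep(t(a), 3L), c(dim(t(a)), 3L))
  } else {
    a <- aperm(a, c(2L, 1L, 3L))[, , 1:3, drop = FALSE]
  }
  storage.mode(a) <- "double"
  array(as.integer(round(a * 255)), dim(a))
}

#' Threshold an RGB image into a conductive template
#'
#' A node is conductive when its pixel looks like mycelium against the
#' background: red and green channels strictly above their thresholds and
#' blue strictly below its cap (`r > r_min`, `g > g_min`, `b < b_max`).
#'
#' @param image integer array `n_i x n_j x 3` of RGB values in 0--255 (see
#'   [read_rgb_image()]).
#' @param r_min,g_min lower (exclusive) thresholds on the red and green
#'   channels; defaults 170.
#' @param b_max upper (exclusive) threshold on the blue channel; default 200.
#' @return a [conductive_template()] with the image's dimensions.
#' @examples
#' px <- array(c(171, 171, 199), c(1, 1, 3))
#' binarize_image(px)[1, 1] == 1
#' @export
binarize_image <- function(image, r_min = 170, g_min = 170, b_max = 200) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L)
    abort("`image` must be an n_i x n_j x 3 RGB array")
  if (any(dim(image)[1:2] < 1L)) abort("`image` must be non-empty")
  for (th in c(r_min, g_min, b_max))
    if (th < 0 || th > 255) abort("thresholds must lie in [0, 255]")
  g <- (image[, , 1] > r_min) & (image[, , 2] > g_min) & (image[, , 3] < b_max)
  conductive_template(matrix(as.integer(g), dim(image)[1], dim(image)[2]))
}

#' Morphological dilation of a conductive template
#'
#' Thickens the conductive set with a 3x3 square structuring element: every
#' node 8-adjacent to a conductive node becomes conductive, repeated
#' `iterations` times. Applied after binarization so that thin hyphal
#' strands become wide enough to carry an excitation wave.
#'
#' @param template a [conductive_template()] or binary matrix.
#' @param iterations number of dilation passes (0 returns the input).
#' @return a `conductive_template`; any mask is intersected back in.
#' @export
dilate_template <- function(template, iterations = 1) {
  g <- template_grid(template)
  mask <- attr(template, "mask")
  iterations <- as.integer(iterations)
  if (iterations < 0) abort("`iterations` must be >= 0")
  if (iterations > 0 && any(g == 1L)) {
    kern <- EBImage::makeBrush(3, shape = "box")
    for (k in seq_len(iterations))
      g <- matrix(as.integer(EBImage::dilate(g, kern) > 0), nrow(g), ncol(g))
  }
  if (!is.null(mask)) g <- g * mask
  conductive_template(g, mask = mask)
}

#' Nearest-neighbour resampling of a template or image
#'
#' Maps a grid of one size onto another by nearest-neighbour lookup, for
#' projecting an image onto a differently sized simulation lattice.
#'
#' @param x binary matrix, `conductive_template`, or RGB array.
#' @param n_i,n_j target dimensions.
#' @return object of the same kind with dimensions `n_i x n_j`.
#' @export
resize_nearest <- function(x, n_i, n_j) {
  idx <- function(n_to, n_from) pmin(pmax(ceiling(seq_len(n_to) * n_from / n_to), 1L), n_from)
  if (is.array(x) && length(dim(x)) == 3L) {
    ri <- idx(n_i, dim(x)[1]); rj <- idx(n_j, dim(x)[2])
    return(x[ri, rj, , drop = FALSE])
  }
  g <- template_grid(x)
  ri <- idx(n_i, nrow(g)); rj <- idx(n_j, ncol(g))
  out <- g[ri, rj, drop = FALSE]
  if (inherits(x, "conductive_template")) conductive_template(out) else out
}

#' Foot-shaped binary mask
#'
#' Builds a connected, insole-shaped domain from two overlapping elliptical
#' lobes (toe and heel) joined by a tapered waist, oriented along the long
#' (column) axis. The toe lobe sits at low column indices. Area fraction of
#' the grid is in roughly 0.4--0.7 for any aspect ratio.
#'
#' @param n_i,n_j grid dimensions (rows, columns); both must be >= 32.
#' @return binary integer matrix `n_i x n_j`.
#' @export
insole_mask <- function(n_i, n_j) {
  n_i <- as.integer(n_i); n_j <- as.integer(n_j)
  if (n_i < 32L || n_j < 32L) abort("insole mask needs at least 32 x 32 nodes")
  ii <- matrix(seq_len(n_i), n_i, n_j)
  jj <- matrix(seq_len(n_j), n_i, n_j, byrow = TRUE)
  x <- (jj - 0.5) / n_j   # 0..1 along the foot, toe at x ~ 0
  y <- (ii - 0.5) / n_i
  toe  <- ((x - 0.23) / 0.22)^2 + ((y - 0.48) / 0.42)^2 < 1
  heel <- ((x - 0.78) / 0.20) ^2 + ((y - 0.52) / 0.36)^2 < 1
  # waist: full-length band whose half-width pinches mid-foot
  hw <- 0.34 - 0.10 * exp(-((x - 0.5) / 0.16)^2)
  waist <- x > 0.12 & x < 0.90 & abs(y - 0.5) < hw
  m <- matrix(as.integer(toe | heel | waist), n_i, n_j)
  m
}

#' Synthetic mycelium growth on a masked grid
#'
#' Grows a hyphal network as a set of correlated branching random walks from
#' a few inoculation points: each walker takes fixed-length steps, turning
#' by Gaussian angular noise, and with some probability per step spawns a
#' child walker deflected by +/- pi/4 from its heading. Trajectories are
#' rasterised onto the grid, clipped to the mask and finally dilated. With
#' the default parameters the result is a dense, predominantly connected
#' network spanning the mask, a stand-in for an imaged colony.
#'
#' @param mask binary matrix with non-empty interior (e.g. [insole_mask()]).
#' @param n_inoculation number of starting points, spread along the mask's
#'   long axis.
#' @param step_length step length in nodes.
#' @param branch_prob per-step probability that a walker branches.
#' @param turn_sd standard deviation (radians) of the per-step heading noise.
#' @param max_steps steps per walker before it retires.
#' @param max_walkers cap on simultaneous walkers. The default scales with
#'   the mask area (one walker per ~2200 mask nodes, at least 16) so that
#'   strand density -- and hence the strand-like, partly inhomogeneous look
#'   of the network -- is comparable across grid scales.
#' @param dilation_iterations dilation passes applied to the rasterised web.
#' @param seed integer; fixes the output exactly.
#' @return a [conductive_template()] carrying `mask`.
#' @export
generate_mycelium <- function(mask,
                              n_inoculation = 8,
                              step_length = 2,
                              branch_prob = 0.04,
                              turn_sd = 0.35,
                              max_steps = 500,
                              max_walkers = NULL,
                              dilation_iterations = 1,
                              seed = 1L) {
  mask <- template_grid(mask)
  if (!any(mask == 1L)) abort("mask has no interior nodes")
  if (is.null(max_walkers)) max_walkers <- max(16L, round(sum(mask) / 2200))
  if (branch_prob < 0 || branch_prob > 1) abort("`branch_prob` must be in [0, 1]")
  if (step_length < 1) abort("`step_length` must be >= 1")
  n_i <- nrow(mask); n_j <- ncol(mask)
  withr::with_seed(as.integer(seed), {
    inside <- which(mask == 1L)
    jj <- ((inside - 1L) %/% n_i) + 1L
    # inoculation points spaced along the long axis, at the mask's centre row
    qs <- stats::quantile(jj, probs = seq(0.08, 0.92, length.out = n_inoculation))
    starts <- vapply(qs, function(q) {
      cand <- inside[abs(jj - q) <= max(2, n_j * 0.01)]
      if (!length(cand)) cand <- inside
      cand[sample.int(length(cand), 1L)]
    }, numeric(1))
    wi <- as.numeric((starts - 1) %% n_i + 1)
    wj <- as.numeric((starts - 1) %/% n_i + 1)
    wth <- runif(length(starts), 0, 2 * pi)
    grid <- matrix(0L, n_i, n_j)
    grid[cbind(round(wi), round(wj))] <- 1L
    alive <- rep(TRUE, length(wi))
    steps <- 0L
    while (any(alive) && steps < max_steps) {
      steps <- steps + 1L
      k <- which(alive)
      wth[k] <- wth[k] + rnorm(length(k), 0, turn_sd)
      wi[k] <- wi[k] + step_length * sin(wth[k])
      wj[k] <- wj[k] + step_length * cos(wth[k])
      ri <- round(wi[k]); rj <- round(wj[k])
      ok <- ri >= 1 & ri <= n_i & rj >= 1 & rj <= n_j
      ok[ok] <- mask[cbind(ri[ok], rj[ok])] == 1L
      # walkers leaving the mask bounce back with a randomised heading
      bad <- k[!ok]
      if (length(bad)) {
        wi[bad] <- wi[bad] - step_length * sin(wth[bad])
        wj[bad] <- wj[bad] - step_length * cos(wth[bad])
        wth[bad] <- runif(length(bad), 0, 2 * pi)
      }
      good <- k[ok]
      if (length(good)) grid[cbind(round(wi[good]), round(wj[good]))] <- 1L
      if (branch_prob > 0 && length(good) && length(wi) < max_walkers) {
        br <- good[runif(length(good)) < branch_prob]
        if (length(br)) {
          br <- br[seq_len(min(length(br), max_walkers - length(wi)))]
          sgn <- ifelse(runif(length(br)) < 0.5, -1, 1)
          wi <- c(wi, wi[br]); wj <- c(wj, wj[br])
          wth <- c(wth, wth[br] + sgn * pi / 4)
          alive <- c(alive, rep(TRUE, length(br)))
        }
      }
    }
    out <- dilate_template(conductive_template(grid * mask, mask = mask),
                           iterations = dilation_iterations)
    out
  })
}

#' Sizes of the 8-connected components of a template
#'
#' @param template a [conductive_template()] or binary matrix.
#' @return integer vector of component sizes, descending; `integer(0)` for an
#'   empty template. Sizes sum to the number of conductive nodes.
#' @export
connectivity_report <- function(template) {
  g <- template_grid(template)
  lab <- label_components_cpp(g)
  if (max(lab) == 0L) return(integer(0))
  sort(tabulate(lab[lab > 0L]), decreasing = TRUE)
}

#' Label map of the 8-connected components
#'
#' @inheritParams connectivity_report
#' @return integer matrix; 0 = background, components numbered from 1 with
#'   sizes retrievable via `tabulate()`.
#' @export
label_components <- function(template) {
  label_components_cpp(template_grid(template))
}

#' Read/write templates as plain-text 0/1 matrices or PNG
#'
#' `write_template()` persists a template either as a whitespace-delimited
#' 0/1 text matrix (`format = "text"`) or as a greyscale PNG with
#' conductive = white (`format = "png"`). `read_template()` reads the text
#' form back.
#'
#' @param template a [conductive_template()].
#' @param path output/input file path.
#' @param format `"text"` or `"png"`.
#' @return `read_template()` returns a `conductive_template`;
#'   `write_template()` returns `path` invisibly.
#' @export
write_template <- function(template, path, format = c("text", "png")) {
  format <- match.arg(format)
  g <- template_grid(template)
  if (format == "text") {
    utils::write.table(g, path, row.names = FALSE, col.names = FALSE)
  } else {
    png::writePNG(g, path)
  }
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  g <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(g) <- NULL
  conductive_template(g)
}
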