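# Brute-force reference implementations, kept deliberately naive and
# independent of the package's compiled kernels.

# five-node Laplacian with mirrored (no-flux) boundaries, per-node loops
oracle_laplacian <- function(u, mask, dx = 2) {
  nr <- nrow(u); nc <- ncol(u)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] == 0) next
      uc <- u[i, j]
      nb <- function(ii, jj) {
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || mask[ii, jj] == 0) uc
        else u[ii, jj]
      }
      s <- nb(i - 1, j) + nb(i + 1, j) + nb(i, j - 1) + nb(i, j + 1)
      out[i, j] <- (s - 4 * uc) / dx^2
    }
  }
  out
}

# one synchronous Euler step, per-node loops, reading pre-step fields
oracle_euler_step <- function(u, v, mask, p) {
  lap <- oracle_laplacian(u, mask, p$dx)
  un <- u; vn <- v
  for (i in seq_len(nrow(u))) {
    for (j in seq_len(ncol(u))) {
      if (mask[i, j] == 0) next
      uc <- u[i, j]; vc <- v[i, j]
      un[i, j] <- uc + p$dt * (p$c1 * uc * (uc - p$a) * (1 - uc) -
                                 p$c2 * uc * vc + p$I + p$du * lap[i, j])
      vn[i, j] <- vc + p$dt * (p$b * (uc - vc))
    }
  }
  list(u = un, v = vn)
}

# random connected-ish binary template for equivalence testing
random_template <- function(nr = 20, nc = 20, p = 0.6) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}

# truth table of every Boolean function of (x, y) restricted to the input
# pairs (0,1), (1,0), (1,1): used to verify the gate lookup exhaustively
boolean_function_patterns <- function() {
  funs <- list(
    `CONST-FALSE` = function(x, y) FALSE,
    `AND`         = function(x, y) x & y,
    `x-AND-NOT-y` = function(x, y) x & !y,
    `SELECT-x`    = function(x, y) x,
    `NOT-x-AND-y` = function(x, y) !x & y,
    `SELECT-y`    = function(x, y) y,
    `XOR`         = function(x, y) xor(x, y),
    `OR`          = function(x, y) x | y)
  purrr::map_dfr(names(funs), function(nm) {
    f <- funs[[nm]]
    tibble::tibble(gate = nm,
                   s01 = f(FALSE, TRUE), s10 = f(TRUE, FALSE),
                   s11 = f(TRUE, TRUE))
  })
}

# peak apexes + prominences via SciPy, as an independent oracle
scipy_find_peaks <- function(x, prominence) {
  infile <- tempfile(fileext = ".txt"); outfile <- tempfile(fileext = ".txt")
  writeLines(format(x, digits = 17, scientific = TRUE, trim = TRUE), infile)
  code <- sprintf(paste0(
    "import numpy as np; from scipy.signal import find_peaks\n",
    "x = np.loadtxt('%s')\n",
    "pk, pr = find_peaks(x, prominence=%.17g)\n",
    "np.savetxt('%s', np.column_stack([pk + 1, pr['prominences']]))\n"),
    infile, prominence, outfile)
  res <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                  stdout = TRUE, stderr = TRUE))
  if (!file.exists(outfile) || !is.null(attr(res, "status")))
    return(NULL)
  m <- tryCatch(as.matrix(read.table(outfile)), error = function(e) NULL)
  if (is.null(m)) return(NULL)
  if (nrow(m) == 0) list(index = integer(0), prominence = numeric(0))
  else list(index = as.integer(m[, 1]), prominence = m[, 2])
}
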