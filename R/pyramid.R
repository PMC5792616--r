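#' Dyadic resolution ladder
#'
#' @param base_cell_size cell size of the finest level (m), default 0.5.
#' @param factors integer decimation factors, powers of two starting at 1.
#'   The default \code{c(1, 2, 4, 8, 16)} turns a 0.5 m model into the
#'   0.5/1/2/4/8 m stack.
#' @return a \code{resolution_ladder} list with the resulting cell sizes.
#' @export
resolution_ladder <- function(base_cell_size = 0.5, factors = c(1, 2, 4, 8, 16)) {
  stopifnot(base_cell_size > 0, length(factors) >= 1,
            factors[1] == 1, all(diff(factors) > 0),
            all(log2(factors) == round(log2(factors))))
  structure(list(base_cell_size = base_cell_size,
                 factors = as.integer(factors),
                 cell_sizes = base_cell_size * factors),
            class = "resolution_ladder")
}

# Even-phase cubic B-spline reduction kernel. Output samples sit midway
# between input pairs, i.e. at the centroid of each 2x2 block, so taps are
# the cubic B-spline evaluated at +-0.5 and +-1.5 cells: (1, 23, 23, 1)/48.
# Partition of unity => constants preserved; symmetry => linear ramps
# preserved away from boundaries.
bspline_reduce_1d <- function(m) {
  n <- nrow(m)
  n_out <- n %/% 2
  p <- 2 * seq_len(n_out) - 1        # left of the pair (1-based)
  i0 <- pmax(p - 1, 1)               # half-sample mirror at the edges
  i3 <- pmin(p + 2, n)
  (m[i0, , drop = FALSE] + 23 * m[p, , drop = FALSE] +
     23 * m[p + 1, , drop = FALSE] + m[i3, , drop = FALSE]) / 48
}

#' Halve the resolution of a grid once
#'
#' Low-pass filters with a separable cubic B-spline kernel and decimates by
#' two; output cell centres coincide with the centroids of the 2x2 input
#' blocks, so the georeferenced origin is unchanged. Cells whose filter
#' support touches nodata become nodata (conservative propagation).
#'
#' @param g an [lg_grid] with at least 4 rows and 4 columns.
#' @return an [lg_grid] with doubled cell size.
#' @export
downscale_once <- function(g) {
  stopifnot(inherits(g, "lg_grid"))
  v <- g$values
  if (nrow(v) < 4 || ncol(v) < 4)
    stop("grid too small to downscale (need >= 4 rows and columns)")
  out <- bspline_reduce_1d(v)          # rows
  out <- t(bspline_reduce_1d(t(out)))  # columns
  lg_grid(out, x_origin = g$x_origin, y_origin = g$y_origin,
          cell_size = 2 * g$cell_size, nodata = g$nodata, crs = g$crs)
}

#' Build the multiscale grid pyramid
#'
#' Level k is obtained by k successive [downscale_once] calls; all levels
#' share the original footprint up to trimmed margins when dimensions are
#' odd.
#'
#' @param g the base-resolution [lg_grid].
#' @param ladder a [resolution_ladder]; its \code{base_cell_size} must match
#'   \code{g$cell_size}.
#' @return named list of [lg_grid]s, names are the cell sizes in metres
#'   (e.g. \code{"0.5"}, \code{"1"}, ...).
#' @export
build_pyramid <- function(g, ladder = resolution_ladder(g$cell_size)) {
  stopifnot(inherits(g, "lg_grid"), inherits(ladder, "resolution_ladder"))
  if (abs(ladder$base_cell_size - g$cell_size) > 1e-9)
    stop("ladder base_cell_size (", ladder$base_cell_size,
         ") does not match grid cell_size (", g$cell_size, ")")
  out <- list()
  cur <- g
  cur_fac <- 1L
  for (k in seq_along(ladder$factors)) {
    while (cur_fac < ladder$factors[k]) {
      cur <- downscale_once(cur)
      cur_fac <- cur_fac * 2L
    }
    out[[format(ladder$cell_sizes[k])]] <- cur
  }
  out
}
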