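# Full-field processing: tile planning with minimum overlap and
# alpha-blended recombination of per-tile reconstructions.

#' Plan overlapping tiles over a sensor frame
#'
#' Covers a frame with equal-sized, axis-aligned tiles such that adjacent
#' tiles overlap by at least \code{min_overlap} pixels per shared edge.  Per
#' axis the tile count is \eqn{\lceil (L - T)/(T - m) \rceil + 1}; the
#' leftover overlap budget is spread as evenly as possible, with earlier
#' gaps receiving the extra pixel (deterministic tie-break).  The last
#' row/column of tiles is flush with the frame edge.
#'
#' @param frame_shape frame dimensions in pixels (length 2).
#' @param tile tile side length in pixels.
#' @param min_overlap minimum overlap in pixels (0 <= m < tile).
#' @return Object of class \code{tile_plan}: \code{frame_shape},
#'   \code{tile}, \code{min_overlap}, per-axis 0-based \code{offsets}, and
#'   the tile \code{grid} dimensions.
#' @examples
#' plan_tiles(c(3872, 2764), 500, 50)$grid  # 9 x 7
#' @export
plan_tiles <- function(frame_shape, tile, min_overlap) {
  frame_shape <- as.integer(frame_shape)
  tile <- as.integer(tile); min_overlap <- as.integer(min_overlap)
  if (length(frame_shape) != 2L) stop("'frame_shape' must have length 2")
  if (any(tile > frame_shape)) stop("tile exceeds the frame dimensions")
  if (min_overlap < 0L || min_overlap >= tile)
    stop("need 0 <= min_overlap < tile")
  axis_offsets <- function(L) {
    if (L == tile) return(0L)
    count <- as.integer(ceiling((L - tile) / (tile - min_overlap))) + 1L
    span <- L - tile
    base <- span %/% (count - 1L)
    rem <- span %% (count - 1L)
    # earlier gaps take the extra overlap pixel -> earlier steps are smaller
    steps <- rep(base + 1L, count - 1L)
    if (rem < count - 1L) steps[seq_len(count - 1L - rem)] <- base
    cumsum(c(0L, steps))
  }
  offs <- lapply(frame_shape, axis_offsets)
  structure(list(frame_shape = frame_shape, tile = tile,
                 min_overlap = min_overlap,
                 offsets = offs,
                 grid = vapply(offs, length, 0L)),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("Tile plan: %d x %d tiles of %d px over a %s frame (>= %d px overlap)\n",
              x$grid[1], x$grid[2], x$tile,
              paste(x$frame_shape, collapse = " x "), x$min_overlap))
  invisible(x)
}

# separable per-axis blend weight for the tile at position j (1-based) along
# one axis: linear ramps over the overlap with each neighbour, flat 1 inside;
# matched ramps of two neighbours sum to 1 across their shared overlap
#' @noRd
axis_weight <- function(offsets, tile, j) {
  w <- rep(1, tile)
  o <- offsets[j]
  if (j > 1L) {
    m <- offsets[j - 1L] + tile - o       # overlap with the left neighbour
    if (m > 0L) w[seq_len(m)] <- seq_len(m) / (m + 1)
  }
  if (j < length(offsets)) {
    m <- o + tile - offsets[j + 1L]       # overlap with the right neighbour
    if (m > 0L) w[tile - m + seq_len(m)] <- rev(seq_len(m)) / (m + 1)
  }
  w
}

#' Alpha-blend tiles into a full-frame mosaic
#'
#' Recombines per-tile results with separable linear-ramp weights across
#' overlap zones and flat unit weight inside:
#' \eqn{out = \sum_t w_t x_t / \sum_t w_t}.  Accepts 2D tiles (matrices) or
#' 3D tiles (lateral x lateral x z; weights broadcast over z).
#'
#' @param tiles list of tiles in plan order (column-major over the tile
#'   grid: first axis fastest).
#' @param plan the \code{\link{plan_tiles}} result.
#' @return Blended array of shape \code{plan$frame_shape} (times the shared
#'   z extent for 3D tiles).
#' @export
alpha_blend <- function(tiles, plan) {
  stopifnot(inherits(plan, "tile_plan"))
  if (length(tiles) != prod(plan$grid))
    stop("expected ", prod(plan$grid), " tiles, got ", length(tiles))
  t3 <- length(dim(tiles[[1]])) == 3L
  nz <- if (t3) dim(tiles[[1]])[3] else 1L
  tsz <- plan$tile
  num <- array(0, c(plan$frame_shape, nz))
  den <- matrix(0, plan$frame_shape[1], plan$frame_shape[2])
  k <- 0L
  for (jy in seq_along(plan$offsets[[2]])) {
    for (jx in seq_along(plan$offsets[[1]])) {
      k <- k + 1L
      tl <- tiles[[k]]
      dt <- dim(tl)
      if (any(dt[1:2] != tsz)) stop("tile ", k, " does not match the plan size")
      wx <- axis_weight(plan$offsets[[1]], tsz, jx)
      wy <- axis_weight(plan$offsets[[2]], tsz, jy)
      w <- outer(wx, wy)
      xs <- plan$offsets[[1]][jx] + seq_len(tsz)
      ys <- plan$offsets[[2]][jy] + seq_len(tsz)
      if (t3) {
        num[xs, ys, ] <- num[xs, ys, ] + array(w, c(tsz, tsz, nz)) *
          tl
      } else {
        num[xs, ys, 1] <- num[xs, ys, 1] + w * tl
      }
      den[xs, ys] <- den[xs, ys] + w
    }
  }
  if (any(den == 0)) {
    bad <- which(den == 0, arr.ind = TRUE)
    stop(sprintf("coverage gap: %d uncovered pixels, first at (%d, %d)",
                 nrow(bad), bad[1, 1], bad[1, 2]))
  }
  out <- num / array(den, dim(num))
  if (t3) out else out[, , 1]
}

#' Lateral shape of the stitched high-resolution output
#'
#' @param sensor_shape sensor frame shape in pixels.
#' @param s integer upsampling factor (>= 1).
#' @return Elementwise product \code{sensor_shape * s}.
#' @examples
#' upsampled_output_shape(c(3872, 2764), 4)  # 15488 x 11056
#' @export
upsampled_output_shape <- function(sensor_shape, s) {
  if (s < 1) stop("'s' must be >= 1")
  as.integer(sensor_shape) * as.integer(s)
}
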