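#' Idealized stenosed-channel geometry
#'
#' A 2-D planar channel of reference width `d` with a smooth cosine-bell
#' constriction, the desk-scale stand-in for a severely stenosed vessel
#' segment. The occlusion fraction follows the percent-diameter-reduction
#' (NASCET) convention: an occlusion of 0.76 leaves a throat of width
#' `d * (1 - 0.76)`.
#'
#' @param length channel length L (m).
#' @param width reference channel width d (m).
#' @param occlusion occlusion fraction in `[0, 1)`; 0 gives a straight
#'   channel.
#' @param center constriction centre x_c (m); default mid-upstream at
#'   `0.375 * length`.
#' @param constriction_length axial extent of the cosine bell (m); default
#'   `0.75 * width`, an axially compact (focal) constriction as seen in
#'   severe carotid plaque.
#' @return Object of class `channel_geometry`.
#' @examples
#' geo <- channel_geometry(length = 4, width = 1, occlusion = 0.76)
#' throat_width(geo)  # 0.24
#' @export
channel_geometry <- function(length, width, occlusion = 0,
                             center = 0.375 * length,
                             constriction_length = 0.75 * width) {
  stopifnot(length > 0, width > 0, constriction_length > 0)
  if (!(occlusion >= 0 && occlusion < 1))
    stop("channel_geometry: occlusion fraction must lie in [0, 1)",
         call. = FALSE)
  structure(list(length = length, width = width, occlusion = occlusion,
                 center = center,
                 constriction_length = constriction_length),
            class = "channel_geometry")
}

#' @rdname channel_geometry
#' @param geometry a `channel_geometry`.
#' @export
throat_width <- function(geometry) {
  geometry$width * (1 - geometry$occlusion)
}

# Local half-blockage b(x) per wall: each wall bulges inward by b(x), with a
# cosine bell so that the throat half-gap is d*(1-occ)/2 at x = center.
wall_blockage <- function(geometry, x) {
  amp <- geometry$width * geometry$occlusion / 2
  s <- (x - geometry$center) / (geometry$constriction_length / 2)
  b <- ifelse(abs(s) < 1, amp * 0.5 * (1 + cos(pi * s)), 0)
  b
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat("<channel_geometry> L =", x$length, "m, d =", x$width,
      "m, occlusion =", sprintf("%.0f%%", 100 * x$occlusion),
      "(throat", throat_width(x), "m)\n")
  invisible(x)
}

#' Build a staggered Cartesian grid with a stair-step solid mask
#'
#' Discretizes a [channel_geometry()] on a uniform MAC grid: pressure at cell
#' centres, `u` on vertical faces, `v` on horizontal faces. Cells whose
#' centre lies inside the constricted wall region are masked solid
#' (stair-step immersed boundary).
#'
#' @param geometry a [channel_geometry()].
#' @param dx target grid spacing (m); the channel width is resolved with an
#'   integer number of cells of size `h <= dx`.
#' @param bc `"channel"` (inlet/outlet/walls) or `"periodic"` (doubly
#'   periodic box for conservation tests; the mask is empty).
#' @return Object of class `flow_grid`: `nx`, `ny`, `h`, cell-centre
#'   coordinates `x`, `y`, logical solid `mask` (nx-by-ny), `cells` (fluid
#'   cell count) and `avg_cell_length` (= `h`).
#' @export
build_grid <- function(geometry, dx, bc = c("channel", "periodic")) {
  bc <- match.arg(bc)
  stopifnot(inherits(geometry, "channel_geometry"), dx > 0)
  ny <- max(2L, as.integer(ceiling(geometry$width / dx)))
  h <- geometry$width / ny
  nx <- max(2L, as.integer(round(geometry$length / h)))
  throat_cells <- throat_width(geometry) / h
  if (bc == "channel" && geometry$occlusion > 0 && throat_cells < 4)
    stop(sprintf(paste0("build_grid: throat resolved by only %.1f cells; ",
                        "need >= 4 (use dx <= %.3g m)"),
                 throat_cells, throat_width(geometry) / 4), call. = FALSE)
  x <- (seq_len(nx) - 0.5) * h
  y <- (seq_len(ny) - 0.5) * h
  mask <- matrix(FALSE, nx, ny)
  if (bc == "channel" && geometry$occlusion > 0) {
    b <- wall_blockage(geometry, x)
    for (i in seq_len(nx)) {
      solid <- y < b[i] | y > geometry$width - b[i]
      mask[i, ] <- solid
    }
  }
  structure(list(nx = nx, ny = ny, h = h, x = x, y = y,
                 Lx = nx * h, Ly = geometry$width,
                 mask = mask, bc = bc, geometry = geometry,
                 cells = sum(!mask), avg_cell_length = h),
            class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  cat("<flow_grid>", x$nx, "x", x$ny, "cells, h =", signif(x$h, 4),
      "m,", x$cells, "fluid cells,", x$bc, "boundaries\n")
  invisible(x)
}
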