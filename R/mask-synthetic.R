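# Synthetic midsagittal masks with analytically known streamline thickness.
# These are the ground-truth fixtures for the Laplace/streamline solver: the
# band has vertical streamlines of length equal to its height, and the
# half-annulus has radial streamlines of length outer - inner.

new_cc_mask <- function(grid, pixel_mm, orientation = c("right", "left")) {
  orientation <- match.arg(orientation)
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, pixel_mm = pixel_mm, orientation = orientation),
            class = "cc_mask")
}

#' @export
print.cc_mask <- function(x, ...) {
  cat(sprintf("<cc_mask> %d x %d grid, %d foreground px, %.3g mm/px, anterior = %s\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid), x$pixel_mm, x$orientation))
  invisible(x)
}

#' Rectangular band mask of known thickness
#'
#' Builds a solid horizontal rectangle whose true streamline thickness equals
#' `height_mm` at every node: the Laplace potential between the bottom and top
#' edges is linear in height, so every streamline is vertical.
#'
#' @param height_mm band height in mm (this is the true thickness).
#' @param width_mm band width in mm.
#' @param pixel_mm isotropic pixel size in mm.
#' @param margin background margin, in pixels, around the shape.
#' @return a `cc_mask` object.
#' @examples
#' m <- make_band_mask(6, 60, 0.5)
#' sum(m$grid) # 12 * 120 foreground pixels
#' @export
make_band_mask <- function(height_mm, width_mm, pixel_mm, margin = 4L) {
  if (!all(is.finite(c(height_mm, width_mm, pixel_mm))) ||
      height_mm <= 0 || width_mm <= 0 || pixel_mm <= 0)
    stop_invalid("band dimensions and pixel size must be positive")
  h <- as.integer(round(height_mm / pixel_mm))
  w <- as.integer(round(width_mm / pixel_mm))
  if (h < 8L || w < 8L)
    stop_invalid("band must span at least 8 pixels in each direction (got %d x %d)", h, w)
  grid <- matrix(0L, h + 2L * margin, w + 2L * margin)
  grid[margin + seq_len(h), margin + seq_len(w)] <- 1L
  new_cc_mask(grid, pixel_mm)
}

#' Half-annulus arch mask of known thickness
#'
#' Builds an annular arch opening downward, mimicking the midsagittal arch of
#' the corpus callosum. By radial symmetry the potential between the inner
#' (inferior) and outer (superior) arcs depends on radius only, so streamlines
#' are radial and the true thickness is `outer_radius_mm - inner_radius_mm`
#' everywhere along the arch.
#'
#' The pixel lattice is placed with the annulus centre on a pixel corner, so
#' pixel-centre radii are never exactly on the nominal circles and the
#' discretized shape is unambiguous.
#'
#' @param inner_radius_mm,outer_radius_mm arch radii in mm (`outer > inner > 0`).
#' @param pixel_mm isotropic pixel size in mm.
#' @param angular_extent angular span of the arch in radians, in (0, pi];
#'   `pi` gives a full half-annulus with both ends at the bottom.
#' @param margin background margin in pixels.
#' @return a `cc_mask` object.
#' @export
make_arch_mask <- function(inner_radius_mm, outer_radius_mm, pixel_mm,
                           angular_extent = pi, margin = 4L) {
  if (!all(is.finite(c(inner_radius_mm, outer_radius_mm, pixel_mm, angular_extent))) ||
      inner_radius_mm <= 0 || pixel_mm <= 0)
    stop_invalid("radii and pixel size must be positive")
  if (outer_radius_mm <= inner_radius_mm)
    stop_invalid("outer radius (%.3g) must exceed inner radius (%.3g)",
                 outer_radius_mm, inner_radius_mm)
  if (angular_extent <= 0 || angular_extent > pi)
    stop_invalid("angular extent must lie in (0, pi]")
  r1 <- inner_radius_mm / pixel_mm
  r2 <- outer_radius_mm / pixel_mm
  if ((r2 - r1) < 8)
    stop_invalid("annulus must be at least 8 pixels thick")
  rad <- ceiling(r2)
  # centre sits on a pixel corner at (row rad + margin, col rad + margin)
  nr <- rad + 2L * margin
  nc <- 2L * rad + 2L * margin
  rows <- seq_len(nr); cols <- seq_len(nc)
  yc <- (rad + margin) - (rows - 0.5)          # height above centre, half-integers
  xc <- (cols - 0.5) - (rad + margin)          # signed horizontal offset
  Y <- matrix(yc, nr, nc)
  X <- matrix(xc, nr, nc, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X)
  keep <- R >= r1 & R <= r2 & abs(TH - pi / 2) <= angular_extent / 2
  new_cc_mask(matrix(as.integer(keep), nr, nc), pixel_mm)
}
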