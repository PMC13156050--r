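`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Bilinear interpolation on a matrix
#'
#' Samples matrix `M` at fractional (row, col) positions. Positions are in
#' matrix coordinates: (1, 1) is the centre of the top-left pixel. Points are
#' clamped to the grid.
#'
#' @param M numeric matrix.
#' @param r,c numeric vectors of row/column positions.
#' @return numeric vector of interpolated values.
#' @keywords internal
#' @noRd
bilinear <- function(M, r, c) {
  nr <- nrow(M); nc <- ncol(M)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v00 <- M[i00];       v10 <- M[i00 + 1]
  v01 <- M[i00 + nr];  v11 <- M[i00 + nr + 1]
  (1 - fc) * ((1 - fr) * v00 + fr * v10) + fc * ((1 - fr) * v01 + fr * v11)
}

# Derive block-specific RNG seeds from one user seed, keeping the result a
# valid 32-bit integer for any small input seed.
derive_seed <- function(seed, block) {
  offs <- c(demographics = 0, noise = 1000003, symptoms = 2000003,
            permutation = 3000017, bootstrap = 4000037, masks = 5000011)
  as.integer((as.numeric(seed) + offs[[block]]) %% .Machine$integer.max)
}
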