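# Finite-difference Laplace solver on the mask interior.
#
# Dirichlet data: inferior contour pixels = 0, superior = 1 (shared endpoint
# pixels carry the inferior value). "Open" lateral end-face pixels (see
# split_boundary) are free unknowns whose stencil averages over foreground
# neighbours only, which imposes a homogeneous Neumann (no-flux) condition
# there. Interior pixels are relaxed with red-black successive
# over-relaxation until the maximum residual against the stencil falls below
# `tol`.

# separable Gaussian smoothing of a matrix, zero-padded at the edges
gauss_smooth <- function(M, sigma = 0.8, radius = 3L) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm_dim <- function(A, along_rows) {
    out <- A * k[radius + 1L]
    for (s in seq_len(radius)) {
      w <- k[radius + 1L + s]
      if (along_rows) {
        up <- rbind(A[-seq_len(s), , drop = FALSE], matrix(0, s, ncol(A)))
        dn <- rbind(matrix(0, s, ncol(A)), A[seq_len(nrow(A) - s), , drop = FALSE])
      } else {
        up <- cbind(A[, -seq_len(s), drop = FALSE], matrix(0, nrow(A), s))
        dn <- cbind(matrix(0, nrow(A), s), A[, seq_len(ncol(A) - s), drop = FALSE])
      }
      out <- out + w * (up + dn)
    }
    out
  }
  sm_dim(sm_dim(M, TRUE), FALSE)
}

# Extrude the mask through its open lateral faces: translate each face's
# cross-section outward along the face normal. This continues the superior
# and inferior edges tangentially past the face (consistent with the no-flux
# model by mirror symmetry), so the smoothed termination indicator is not
# corrupted by corner rounding near the ends.
extrude_faces <- function(fg, open_faces, depth) {
  if (length(open_faces) == 0L) return(fg)
  nr <- nrow(fg); nc <- ncol(fg)
  out <- fg
  fgi <- which(fg)
  prc <- cbind((fgi - 1L) %% nr + 1L, (fgi - 1L) %/% nr + 1L)
  for (face in open_faces) {
    if (nrow(face) < 2L) next
    v <- face[nrow(face), ] - face[1, ]
    half_len <- sqrt(sum(v^2)) / 2
    v <- v / (2 * half_len)
    nvec <- c(-v[2], v[1])
    ctr <- colMeans(face)
    probe <- round(ctr + 2 * nvec)
    if (probe[1] >= 1 && probe[1] <= nr && probe[2] >= 1 && probe[2] <= nc &&
        fg[probe[1], probe[2]]) nvec <- -nvec
    # slab: full foreground cross-section within 1 px of the face line,
    # restricted to the face's extent (plus corner slack)
    d_n <- (prc[, 1] - ctr[1]) * nvec[1] + (prc[, 2] - ctr[2]) * nvec[2]
    d_v <- (prc[, 1] - ctr[1]) * v[1] + (prc[, 2] - ctr[2]) * v[2]
    slab <- prc[abs(d_n) <= 1 & abs(d_v) <= half_len + 3, , drop = FALSE]
    if (nrow(slab) == 0L) next
    for (k in seq_len(2L * depth)) {   # half-steps close diagonal gaps
      pts <- round(sweep(slab, 2, 0.5 * k * nvec, `+`))
      keep <- pts[, 1] >= 1 & pts[, 1] <= nr & pts[, 2] >= 1 & pts[, 2] <= nc
      out[pts[keep, , drop = FALSE]] <- TRUE
    }
  }
  out
}

# extend foreground values into the background by iterative nearest-neighbour
# averaging, so gradients and contour extraction behave near the mask edge
extend_field <- function(u, known) {
  nr <- nrow(u); nc <- ncol(u)
  u[!known] <- 0
  it <- 0L
  while (!all(known) && it < nr + nc + 16L) {
    it <- it + 1L
    kn <- matrix(0, nr, nc); kn[known] <- 1
    shift <- function(A, dr, dc) {
      B <- matrix(0, nr, nc)
      rs <- seq_len(nr - abs(dr)); cs <- seq_len(nc - abs(dc))
      B[rs + max(dr, 0), cs + max(dc, 0)] <- A[rs + max(-dr, 0), cs + max(-dc, 0)]
      B
    }
    ssum <- shift(u * kn, 1, 0) + shift(u * kn, -1, 0) + shift(u * kn, 0, 1) + shift(u * kn, 0, -1)
    scnt <- shift(kn, 1, 0) + shift(kn, -1, 0) + shift(kn, 0, 1) + shift(kn, 0, -1)
    newly <- !known & scnt > 0
    u[newly] <- ssum[newly] / scnt[newly]
    known <- known | newly
  }
  u
}

#' Solve Laplace's equation between the superior and inferior contours
#'
#' Computes the harmonic potential on the mask foreground with the inferior
#' contour held at 0 and the superior contour at 1, by red-black successive
#' over-relaxation on the 5-point stencil. The converged potential, its
#' gradient, a smoothed mask-edge indicator and a harmonic extension into the
#' background (used by the midline and streamline stages) are returned
#' together.
#'
#' @param mask a `cc_mask`.
#' @param split a `cc_boundary_split` from [split_boundary()]; computed from
#'   `mask` when omitted.
#' @param tol convergence tolerance: maximum absolute residual of the 5-point
#'   stencil over interior pixels. Must be positive.
#' @param max_iter iteration cap; defaults to `100 * max(dim(grid))`.
#' @param sigma_term width (pixels) of the Gaussian smoothing of the mask
#'   indicator used for sub-pixel streamline termination; chosen on the
#'   stable plateau between staircase-quantization averaging and kernel
#'   reach (see the methods vignette).
#' @return an object of class `cc_potential` with fields `u` (full-grid
#'   potential, harmonically extended outside the mask), `fg`, `fixed0`,
#'   `fixed1` (logical matrices), `B` (smoothed mask indicator), `gx`/`gy`
#'   (central-difference gradient), `iterations`, `residual`, `converged`.
#' @export
solve_laplace <- function(mask, split = NULL, tol = 1e-6, max_iter = NULL,
                          sigma_term = 2.5) {
  stopifnot(inherits(mask, "cc_mask"))
  if (!is.numeric(tol) || tol <= 0)
    stop_invalid("tol must be > 0 (got %g)", tol)
  if (is.null(split)) split <- split_boundary(mask)
  stopifnot(inherits(split, "cc_boundary_split"))
  grid <- mask$grid
  nr <- nrow(grid); nc <- ncol(grid)
  if (is.null(max_iter)) max_iter <- 100L * max(nr, nc)
  fg <- grid > 0
  fixed1 <- matrix(FALSE, nr, nc)
  fixed1[split$superior] <- TRUE
  fixed0 <- matrix(FALSE, nr, nc)
  fixed0[split$inferior] <- TRUE
  fixed1 <- fixed1 & !fixed0  # shared endpoints carry the inferior value
  u <- matrix(0, nr, nc)
  u[fg] <- 0.5
  u[fixed0] <- 0
  u[fixed1] <- 1
  free <- fg & !fixed0 & !fixed1
  idx <- which(free)
  if (length(idx) == 0L)
    stop_invalid("mask has no interior pixels between the contours")
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  red <- (rr + cc) %% 2L == 0L
  # neighbour bookkeeping: open-face pixels average over foreground
  # neighbours only (no-flux); the 2-px margin keeps all indices in-grid
  nb_of <- function(i) cbind(i - 1L, i + 1L, i - nr, i + nr)
  mk <- function(i) {
    nbi <- nb_of(i)
    ok <- matrix(fg[nbi], nrow(nbi), 4L)
    list(i = i, nbi = nbi, ok = ok, cnt = pmax(rowSums(ok), 1L))
  }
  blk_r <- mk(idx[red]); blk_b <- mk(idx[!red]); blk_a <- mk(idx)
  avg <- function(b) {
    v <- matrix(u[b$nbi], nrow(b$nbi), 4L) * b$ok
    (v[, 1] + v[, 2] + v[, 3] + v[, 4]) / b$cnt
  }
  omega <- 2 / (1 + sin(pi / (max(nr, nc) + 1)))
  iter <- 0L; res <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    u[blk_r$i] <- u[blk_r$i] + omega * (avg(blk_r) - u[blk_r$i])
    u[blk_b$i] <- u[blk_b$i] + omega * (avg(blk_b) - u[blk_b$i])
    if (iter %% 16L == 0L || iter == max_iter) {
      res <- max(abs(avg(blk_a) - u[blk_a$i]))
      if (res <= tol) break
    }
  }
  if (res > tol)
    stop_invalid("Laplace solver did not converge in %d iterations (residual %.3g > tol %.3g)",
                 iter, res, tol)
  u[fg] <- pmin(pmax(u[fg], 0), 1)
  uext <- extend_field(u, fg)
  # termination indicator: wide kernel for sub-pixel edge localization, on
  # the face-extruded mask; midline indicator: narrow kernel, unextruded,
  # so the midline is trimmed at the physical end faces
  fg_ext <- extrude_faces(fg, split$open_faces %||% list(),
                          depth = ceiling(4 * sigma_term) + 2L)
  B <- gauss_smooth(matrix(as.numeric(fg_ext), nr, nc),
                    sigma = sigma_term, radius = max(6L, ceiling(3.2 * sigma_term)))
  Bmid <- gauss_smooth(matrix(as.numeric(fg), nr, nc))
  gy <- matrix(0, nr, nc); gx <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (uext[3:nr, ] - uext[1:(nr - 2), ]) / 2
  gx[, 2:(nc - 1)] <- (uext[, 3:nc] - uext[, 1:(nc - 2)]) / 2
  structure(list(u = uext, fg = fg, fixed0 = fixed0, fixed1 = fixed1,
                 B = B, Bmid = Bmid, gx = gx, gy = gy,
                 pixel_mm = mask$pixel_mm, orientation = mask$orientation,
                 tol = tol, iterations = iter, residual = res, converged = TRUE,
                 split = split),
            class = "cc_potential")
}

#' @export
print.cc_potential <- function(x, ...) {
  cat(sprintf("<cc_potential> %d x %d grid, converged in %d SOR iterations (residual %.2g)\n",
              nrow(x$u), ncol(x$u), x$iterations, x$residual))
  invisible(x)
}
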