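# Outer boundary tracing and the superior/inferior split.
#
# The callosum outline is split at its two "bottommost extremities": the
# lowest boundary pixel within the posterior third of the bounding box and the
# lowest within the anterior third. The arc through the topmost pixel is the
# superior contour (Dirichlet value 1), the other arc the inferior contour
# (value 0).
#
# Blunt-ended shapes (validation fixtures such as a rectangle band or an
# annular arch with flat feet) additionally have short lateral end faces that
# connect the two contours. Holding such a face at a Dirichlet value would
# bend the equipotentials into the corners; physically the through-thickness
# flow runs parallel to these faces, so they are classified as "open"
# (no-flux) instead. Faces are detected by walking from each endpoint to the
# first sharp corner of the outline; anatomical masks taper to points and
# carry no sharp corners, so the rule is inert for them.

# Moore-neighbour tracing of the outer boundary of a single 4-connected
# component with >= 2 px background margin. Returns ordered (row, col) pixels.
trace_outer_boundary <- function(fg) {
  nr <- nrow(fg)
  idx <- which(fg)
  cols <- (idx - 1L) %/% nr + 1L
  rows <- (idx - 1L) %% nr + 1L
  o <- order(cols, rows)
  start <- c(rows[o[1]], cols[o[1]])
  # 8 neighbours clockwise starting West (as seen with row down, col right)
  offs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  boundary <- matrix(start, 1L, 2L)
  cur <- start
  back_dir <- 1L  # we "came from" the West (background by start construction)
  first_move <- NULL
  steps <- 0L; max_steps <- 8L * length(idx) + 64L
  repeat {
    steps <- steps + 1L
    if (steps > max_steps) stop_invalid("boundary tracing failed to close")
    found <- FALSE
    for (k in seq_len(8L)) {
      d <- (back_dir - 1L + k - 1L) %% 8L + 1L
      p <- cur + offs[d, ]
      if (fg[p[1], p[2]]) {
        dprev <- (d - 2L) %% 8L + 1L
        bpix <- cur + offs[dprev, ]
        move <- c(d, p)
        if (is.null(first_move)) first_move <- move
        else if (all(cur == start) && all(move == first_move))
          return(boundary[-nrow(boundary), , drop = FALSE])
        cur <- p
        boundary <- rbind(boundary, cur)
        delta <- bpix - cur
        back_dir <- which(offs[, 1] == delta[1] & offs[, 2] == delta[2])
        found <- TRUE
        break
      }
    }
    if (!found) return(boundary)  # isolated pixel
  }
}

# Turning angle (radians) at each position of a closed pixel outline,
# measured between chords of half-window w.
turning_angles <- function(bd, w = 2L) {
  n <- nrow(bd)
  im <- ((seq_len(n) - 1L - w) %% n) + 1L
  ip <- ((seq_len(n) - 1L + w) %% n) + 1L
  v1 <- bd - bd[im, , drop = FALSE]
  v2 <- bd[ip, , drop = FALSE] - bd
  dotp <- rowSums(v1 * v2)
  nn <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  acos(pmin(pmax(dotp / pmax(nn, 1e-12), -1), 1))
}

# Walk from boundary index i0 in the given direction and report the distance
# (in boundary steps) to the first sharp corner, or Inf if none within cap.
# The turning run belonging to the endpoint's own corner (if any) is skipped
# first, so the distance refers to the far corner of a lateral face.
first_corner <- function(ang, i0, dir, cap, thresh = pi / 3) {
  n <- length(ang)
  at <- function(s) ang[((i0 - 1L + dir * s) %% n) + 1L]
  s <- 1L
  while (s <= cap && at(s) >= thresh) s <- s + 1L
  while (s <= cap) {
    if (at(s) >= thresh)
      return(list(dist = s, index = ((i0 - 1L + dir * s) %% n) + 1L))
    s <- s + 1L
  }
  list(dist = Inf, index = NA_integer_)
}

#' Split the callosum outline into superior and inferior contours
#'
#' Traces the closed outer boundary of the mask and splits it at the two
#' bottommost extremities: the lowest boundary pixel within the posterior
#' third of the bounding box and the lowest within the anterior third (ties
#' broken towards the respective extremity). The arc containing the topmost
#' boundary pixel becomes the superior contour; both contours are returned
#' ordered posterior to anterior.
#'
#' On blunt-ended shapes, the short lateral faces that join the two contours
#' at the ends are detected (walk from each endpoint to the first sharp
#' outline corner) and returned as `open`: these pixels receive a no-flux
#' rather than a Dirichlet condition in [solve_laplace()].
#'
#' @param mask a `cc_mask`.
#' @return an object of class `cc_boundary_split` with fields `endpoints`
#'   (2 x 2 matrix, posterior then anterior), `superior`, `inferior` and
#'   `open` (possibly 0-row) ordered (row, col) matrices.
#' @export
split_boundary <- function(mask) {
  stopifnot(inherits(mask, "cc_mask"))
  fg <- mask$grid > 0
  bd <- trace_outer_boundary(fg)
  dimnames(bd) <- NULL
  n <- nrow(bd)
  if (n < 16L)
    stop_invalid("boundary has only %d pixels; shape too degenerate to split", n)
  cr <- range(bd[, 2])
  third <- (cr[2] - cr[1]) / 3
  anterior_right <- identical(mask$orientation, "right")
  post_sel <- if (anterior_right) bd[, 2] <= cr[1] + third else bd[, 2] >= cr[2] - third
  ant_sel  <- if (anterior_right) bd[, 2] >= cr[2] - third else bd[, 2] <= cr[1] + third
  lowest <- function(sel, toward_min_col) {
    cand <- which(sel)
    cand <- cand[bd[cand, 1] == max(bd[cand, 1])]
    cc <- bd[cand, 2]
    cand[if (toward_min_col) which.min(cc) else which.max(cc)]
  }
  i_post <- lowest(post_sel, toward_min_col = anterior_right)
  i_ant  <- lowest(ant_sel,  toward_min_col = !anterior_right)
  if (i_post == i_ant)
    stop_invalid("posterior and anterior extremities coincide; shape too degenerate")

  # lateral end faces: from each endpoint, the shorter walk to a sharp corner
  ang <- turning_angles(bd)
  cap <- max(8L, n %/% 4L)
  open_idx <- integer(0)
  open_faces <- list()
  split_at <- c(i_post, i_ant)
  for (e in 1:2) {
    i0 <- split_at[e]
    fwd <- first_corner(ang, i0, +1L, cap)
    bwd <- first_corner(ang, i0, -1L, cap)
    if (is.finite(fwd$dist) || is.finite(bwd$dist)) {
      pick <- if (fwd$dist <= bwd$dist) fwd else bwd
      dir <- if (fwd$dist <= bwd$dist) +1L else -1L
      if (pick$dist >= 2L && pick$dist < cap) {
        face <- ((i0 - 1L + dir * seq(0L, pick$dist - 1L)) %% n) + 1L
        open_idx <- c(open_idx, face)
        open_faces[[length(open_faces) + 1L]] <- bd[face, , drop = FALSE]
      }
    }
  }
  open_idx <- unique(open_idx)

  seg <- function(i, j) if (i <= j) i:j else c(i:n, 1:j)
  arc1_idx <- seg(i_post, i_ant)
  arc2_idx <- rev(seg(i_ant, i_post))
  strip <- function(idx) idx[!(idx %in% open_idx)]
  arc1_idx <- strip(arc1_idx); arc2_idx <- strip(arc2_idx)
  if (length(arc1_idx) < 2L || length(arc2_idx) < 2L)
    stop_invalid("contour split degenerate after end-face removal")
  arc1 <- bd[arc1_idx, , drop = FALSE]
  arc2 <- bd[arc2_idx, , drop = FALSE]
  sup_is_1 <- min(arc1[, 1]) < min(arc2[, 1])
  superior <- if (sup_is_1) arc1 else arc2
  inferior <- if (sup_is_1) arc2 else arc1
  structure(list(endpoints = rbind(posterior = bd[i_post, ], anterior = bd[i_ant, ]),
                 superior = superior, inferior = inferior,
                 open = bd[open_idx, , drop = FALSE],
                 open_faces = open_faces),
            class = "cc_boundary_split")
}

#' @export
print.cc_boundary_split <- function(x, ...) {
  cat(sprintf("<cc_boundary_split> superior %d px, inferior %d px, open %d px; endpoints (%d,%d) / (%d,%d)\n",
              nrow(x$superior), nrow(x$inferior), nrow(x$open),
              x$endpoints[1, 1], x$endpoints[1, 2], x$endpoints[2, 1], x$endpoints[2, 2]))
  invisible(x)
}
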