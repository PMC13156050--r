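# Extraction of the equipotential midline (0.5 level set).

#' Extract the equipotential midline
#'
#' The callosal midline is the 0.5 level set of the harmonic potential,
#' extracted as an ordered polyline and trimmed to the mask interior (where
#' the smoothed mask indicator is at least 0.5). The polyline is ordered
#' posterior to anterior according to the mask orientation, and its arc length
#' is reported in mm.
#'
#' @param field a `cc_potential` from [solve_laplace()].
#' @return an object of class `cc_midline` with fields `points` (ordered
#'   (row, col) matrix in pixel coordinates), `arclength_mm`, `pixel_mm`,
#'   `orientation`.
#' @export
extract_midline <- function(field) {
  stopifnot(inherits(field, "cc_potential"))
  interior <- field$fg & !field$fixed0 & !field$fixed1
  vals <- field$u[interior]
  if (!any(vals > 0.25 & vals < 0.75))
    stop_invalid("potential field has no intermediate values; 0.5 level set is degenerate")
  cl <- grDevices::contourLines(x = seq_len(nrow(field$u)), y = seq_len(ncol(field$u)),
                                z = field$u, levels = 0.5)
  if (length(cl) == 0L) stop_invalid("no 0.5 level set found")
  runs <- lapply(cl, function(ct) {
    pts <- cbind(ct$x, ct$y)
    inside <- bilinear(field$Bmid, pts[, 1], pts[, 2]) >= 0.5
    if (!any(inside)) return(NULL)
    # longest contiguous inside run
    r <- rle(inside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cand <- which(r$values)
    best <- cand[which.max(r$lengths[cand])]
    seg <- pts[starts[best]:ends[best], , drop = FALSE]
    if (nrow(seg) < 2L) return(NULL)
    list(points = seg, len = sum(sqrt(rowSums(diff(seg)^2))),
         extra = sum(r$lengths[cand]) - r$lengths[best])
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L) stop_invalid("0.5 level set lies outside the mask")
  lens <- vapply(runs, `[[`, numeric(1), "len")
  best <- which.max(lens)
  other <- sum(lens[-best]) + runs[[best]]$extra
  if (other > 4)
    stop_invalid("0.5 level set is disconnected inside the mask (stray length %.1f px)", other)
  pts <- runs[[best]]$points
  if (lens[best] < 4)
    stop_invalid("midline is too short (%.1f px)", lens[best])
  # order posterior -> anterior: with anterior on the right of the image the
  # posterior end has the smaller column
  head_col <- mean(pts[seq_len(min(5L, nrow(pts))), 2])
  tail_col <- mean(pts[nrow(pts) - seq_len(min(5L, nrow(pts))) + 1L, 2])
  flip <- if (identical(field$orientation, "right")) head_col > tail_col else head_col < tail_col
  if (flip) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  structure(list(points = pts,
                 arclength_mm = sum(sqrt(rowSums(diff(pts)^2))) * field$pixel_mm,
                 pixel_mm = field$pixel_mm, orientation = field$orientation),
            class = "cc_midline")
}

#' @export
print.cc_midline <- function(x, ...) {
  cat(sprintf("<cc_midline> %d points, arc length %.2f mm\n",
              nrow(x$points), x$arclength_mm))
  invisible(x)
}
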