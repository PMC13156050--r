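# Reading, writing and cleaning binary midsagittal masks.

# 4-connected component labelling by vectorized frontier expansion.
label_4conn <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(fg)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    frontier <- start
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cand <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
                frontier[frontier > nr] - nr,
                frontier[frontier <= (nc - 1L) * nr] + nr)
      cand <- unique(cand[fg[cand] & lab[cand] == 0L])
      lab[cand] <- cur
      frontier <- cand
    }
  }
  lab
}

# Fill interior holes: background components not reachable from the border.
fill_holes <- function(fg) {
  bg <- !fg
  lab <- label_4conn(bg)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  holes <- bg & !(lab %in% border)
  fg | holes
}

clean_mask_grid <- function(grid) {
  fg <- grid > 0
  if (!any(fg)) stop_invalid("mask has no foreground pixels")
  lab <- label_4conn(fg)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L)
    stop_invalid("mask has %d equally largest 4-connected components (size %d each); cannot choose one",
                 length(biggest), max(sizes))
  fg <- lab == biggest
  fg <- fill_holes(fg)
  # guarantee a 2-pixel background margin for boundary tracing
  rr <- range(which(rowSums(fg) > 0)); cc <- range(which(colSums(fg) > 0))
  pad_top <- max(0L, 3L - rr[1]); pad_bot <- max(0L, rr[2] - (nrow(fg) - 3L))
  pad_left <- max(0L, 3L - cc[1]); pad_right <- max(0L, cc[2] - (ncol(fg) - 3L))
  if (pad_top + pad_bot + pad_left + pad_right > 0L) {
    out <- matrix(FALSE, nrow(fg) + pad_top + pad_bot, ncol(fg) + pad_left + pad_right)
    out[pad_top + seq_len(nrow(fg)), pad_left + seq_len(ncol(fg))] <- fg
    fg <- out
  }
  matrix(as.integer(fg), nrow(fg), ncol(fg))
}

#' Load a binary midsagittal mask
#'
#' Reads a 2-D binary corpus-callosum mask from PNG, plain-text 0/1 grid, or
#' single-slice NIfTI. Values greater than zero are treated as foreground.
#' Load-time cleanup retains the largest 4-connected component, fills interior
#' holes, and pads the grid so the foreground keeps a 2-pixel margin from the
#' image border.
#'
#' @param path file path; format is inferred from the extension
#'   (`.png`, `.txt`/`.tsv`, `.nii`/`.nii.gz`).
#' @param pixel_mm isotropic pixel size in mm. Required for PNG; read from the
#'   header for text masks and from `pixdim` for NIfTI (an explicit argument
#'   overrides either).
#' @param orientation which image side is anterior, `"right"` (default) or
#'   `"left"`. Node 0 of a thickness profile is at the posterior end.
#' @return a `cc_mask` object.
#' @seealso [make_band_mask()], [write_mask_png()], [write_mask_text()]
#' @export
load_mask <- function(path, pixel_mm = NULL, orientation = "right") {
  if (!file.exists(path)) stop_invalid("mask file not found: %s", path)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    if (is.null(pixel_mm))
      stop_invalid("pixel_mm must be supplied for PNG masks")
    grid <- matrix(as.integer(img > 0), nrow(img), ncol(img))
  } else if (grepl("\\.(txt|tsv)$", lower)) {
    header <- readLines(path, n = 1L)
    m <- regmatches(header, regexec("pixel_mm\\s*[=:]\\s*([0-9.eE+-]+)", header))[[1]]
    if (length(m) == 2L && is.null(pixel_mm)) pixel_mm <- as.numeric(m[2])
    if (is.null(pixel_mm))
      stop_invalid("pixel size missing: no pixel_mm header in %s and none supplied", path)
    grid <- as.matrix(read.table(path, skip = 1L))
    dimnames(grid) <- NULL
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
    arr <- as.array(img)
    d <- dim(arr)
    if (sum(d > 1L) > 2L)
      stop_invalid("NIfTI mask must be a single 2-D slice, got dims %s",
                   paste(d, collapse = " x "))
    arr <- array(arr, d[d > 1L])
    if (is.null(pixel_mm)) pixel_mm <- pd[which(d > 1L)][1]
    grid <- matrix(as.integer(arr > 0), nrow(arr), ncol(arr))
  } else {
    stop_invalid("unrecognized mask format: %s", path)
  }
  if (!is.numeric(pixel_mm) || pixel_mm <= 0)
    stop_invalid("pixel_mm must be positive")
  new_cc_mask(clean_mask_grid(grid), pixel_mm, orientation)
}

#' Write a mask as PNG
#'
#' Foreground is written as white (255), background black.
#'
#' @param mask a `cc_mask`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask$grid > 0), nrow(mask$grid), ncol(mask$grid)), path)
  invisible(path)
}

#' Write a mask as a plain-text 0/1 grid
#'
#' The first line is a comment header carrying the pixel size, e.g.
#' `# cc_mask pixel_mm=0.5`; subsequent lines are space-separated 0/1 rows.
#'
#' @inheritParams write_mask_png
#' @return the path, invisibly.
#' @export
write_mask_text <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cc_mask pixel_mm=%g orientation=%s", mask$pixel_mm, mask$orientation), con)
  write.table(mask$grid, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
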