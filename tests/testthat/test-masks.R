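# Synthetic mask fixtures and mask I/O.

test_that("band mask has the exact rectangle geometry at any resolution", {
  m <- make_band_mask(6, 60, 0.5)
  expect_s3_class(m, "cc_mask")
  expect_equal(sum(m$grid), 12L * 120L)
  rr <- range(which(rowSums(m$grid) > 0))
  expect_equal(diff(rr) + 1L, 12L)
  # ground truth is resolution independent
  for (px in c(0.75, 0.25)) {
    mi <- make_band_mask(6, 60, px)
    expect_equal(sum(mi$grid), round(6 / px) * round(60 / px))
  }
})

test_that("arch mask is a half-annulus with radial width independent of extent", {
  a <- make_arch_mask(10, 14, 0.25)
  expect_s3_class(a, "cc_mask")
  # area check: half annulus area pi (r2^2 - r1^2) / 2 in pixels
  expected_px <- pi * ((14 / 0.25)^2 - (10 / 0.25)^2) / 2
  expect_lt(abs(sum(a$grid) - expected_px) / expected_px, 0.01)
  # both ends at the bottom: lowest foreground row is adjacent to the centre row
  aq <- make_arch_mask(10, 14, 0.25, angular_extent = pi / 2)
  expect_lt(sum(aq$grid), sum(a$grid))  # narrower extent, same radii
})

test_that("degenerate mask arguments are rejected", {
  expect_error(make_band_mask(0, 60, 0.5), "positive")
  expect_error(make_band_mask(6, 60, -1), "positive")
  expect_error(make_band_mask(2, 60, 0.5), "8 pixels")
  expect_error(make_arch_mask(14, 10, 0.25), "exceed")
  expect_error(make_arch_mask(10, 14, 0.25, angular_extent = 4), "extent")
})

test_that("PNG and text round-trips preserve the mask", {
  m <- make_band_mask(6, 60, 0.5)
  png_path <- withr::local_tempfile(fileext = ".png")
  txt_path <- withr::local_tempfile(fileext = ".txt")
  write_mask_png(m, png_path)
  write_mask_text(m, txt_path)
  m_png <- load_mask(png_path, pixel_mm = 0.5)
  m_txt <- load_mask(txt_path)  # pixel size from header
  expect_equal(sum(m_png$grid), sum(m$grid))
  expect_equal(m_txt$pixel_mm, 0.5)
  expect_equal(dim(m_txt$grid), dim(m$grid))
  expect_equal(which(m_txt$grid > 0), which(m$grid > 0))
})

test_that("load-time cleanup keeps the largest component and fills holes", {
  m <- make_band_mask(6, 20, 0.5)
  g <- m$grid
  g[10, 20] <- 0L              # 1-px interior hole
  g[2, 2] <- 1L                # small stray speck
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# cc_mask pixel_mm=0.5",
               apply(g, 1, paste, collapse = " ")), p)
  got <- load_mask(p)
  # hole filled, speck dropped: same foreground count as the clean band
  expect_equal(sum(got$grid), sum(m$grid))
  # flood-fill oracle: single 4-connected component
  lab <- callothick:::label_4conn(got$grid > 0)
  expect_equal(max(lab), 1L)
})

test_that("empty and ambiguous masks are rejected with diagnostics", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# cc_mask pixel_mm=0.5",
               apply(matrix(0L, 10, 10), 1, paste, collapse = " ")), p)
  expect_error(load_mask(p), "no foreground")
  g <- matrix(0L, 12, 30)
  g[3:6, 3:10] <- 1L
  g[3:6, 20:27] <- 1L  # two equally largest components
  writeLines(c("# cc_mask pixel_mm=0.5", apply(g, 1, paste, collapse = " ")), p)
  expect_error(load_mask(p), "equally largest")
})

test_that("NIfTI single-slice masks load with pixel size from the header", {
  skip_if_not_installed("RNifti")
  m <- make_band_mask(6, 20, 0.5)
  arr <- array(as.numeric(m$grid), dim = c(nrow(m$grid), ncol(m$grid)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(0.5, 0.5)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, p)
  got <- load_mask(p)
  expect_equal(got$pixel_mm, 0.5)
  expect_equal(sum(got$grid), sum(m$grid))
})
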