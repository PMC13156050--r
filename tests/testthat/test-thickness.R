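# Laplace-streamline thickness stage, validated against analytic fixtures.
# The fine-resolution (0.25 mm) recovery checks live in the acceptance suite;
# here 0.5 mm keeps things fast.

test_that("boundary split of the band puts endpoints at the bottom corners", {
  m <- make_band_mask(6, 60, 0.5)
  s <- split_boundary(m)
  fgrows <- range(which(rowSums(m$grid) > 0))
  fgcols <- range(which(colSums(m$grid) > 0))
  expect_equal(unname(s$endpoints[, 1]), rep(fgrows[2], 2))  # bottom row
  expect_equal(sort(unname(s$endpoints[, 2])), fgcols)       # extreme columns
  # superior contour contains the top edge, inferior stays on the bottom row
  expect_equal(min(s$superior[, 1]), fgrows[1])
  expect_true(all(s$inferior[, 1] == fgrows[2]))
  # contours ordered posterior (left) to anterior (right)
  expect_lt(s$inferior[1, 2], s$inferior[nrow(s$inferior), 2])
  expect_lt(s$superior[1, 2], s$superior[nrow(s$superior), 2])
})

test_that("boundary split of the arch matches the analytic annulus classification", {
  a <- make_arch_mask(10, 14, 0.5)
  s <- split_boundary(a)
  rad <- ceiling(14 / 0.5); mar <- 4
  ctr <- c(rad + mar, rad + mar)  # corner coordinates of the annulus centre
  radial <- function(pts) sqrt((ctr[1] - (pts[, 1] - 0.5))^2 + ((pts[, 2] - 0.5) - ctr[2])^2)
  # superior pixels near the outer radius, inferior near the inner
  expect_true(all(abs(radial(s$superior) - 28) < 1.6))
  expect_true(all(abs(radial(s$inferior) - 20) < 1.6))
  # open faces detected at both feet
  expect_gte(length(s$open_faces), 2L)
})

test_that("a disk still splits without error under the tie rule", {
  px <- 0.5
  g <- outer(seq_len(40), seq_len(40), function(r, c) (r - 20.5)^2 + (c - 20.5)^2 <= 15^2)
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# cc_mask pixel_mm=0.5", apply(g * 1L, 1, paste, collapse = " ")), p)
  m <- load_mask(p)
  s <- split_boundary(m)
  expect_s3_class(s, "cc_boundary_split")
  expect_gt(nrow(s$superior), 2)
  expect_gt(nrow(s$inferior), 2)
})

test_that("degenerate boundaries are rejected", {
  g <- matrix(0L, 12, 12); g[6, 5:7] <- 1L
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# cc_mask pixel_mm=0.5", apply(g, 1, paste, collapse = " ")), p)
  m <- load_mask(p)
  expect_error(split_boundary(m), "degenerate|boundary")
})

test_that("band potential is linear in height within solver tolerance", {
  m <- make_band_mask(6, 30, 0.5)
  s <- split_boundary(m)
  f <- solve_laplace(m, s, tol = 1e-8)
  fg_rows <- range(which(rowSums(m$grid) > 0))
  mid_col <- ncol(m$grid) %/% 2
  rows <- fg_rows[1]:fg_rows[2]
  got <- f$u[rows, mid_col]
  want <- rev(seq(0, 1, length.out = length(rows)))  # bottom = 0, top = 1
  expect_lt(max(abs(got - want)), 1e-5)
  # harmonicity invariant: interior residual below tol
  expect_true(f$converged)
  expect_lte(f$residual, 1e-8)
  expect_true(all(f$u[f$fg] >= 0 & f$u[f$fg] <= 1))
})

test_that("arch potential matches the polar closed form ln(r/r1)/ln(r2/r1)", {
  a <- make_arch_mask(10, 14, 0.5)
  s <- split_boundary(a)
  f <- solve_laplace(a, s)
  rad <- ceiling(14 / 0.5); mar <- 4
  idx <- which(f$fg & !f$fixed0 & !f$fixed1, arr.ind = TRUE)
  y <- (rad + mar) - (idx[, 1] - 0.5); x <- (idx[, 2] - 0.5) - (rad + mar)
  r <- sqrt(x^2 + y^2); th <- atan2(y, x)
  keep <- th > pi / 6 & th < 5 * pi / 6 & r > 22 & r < 26  # away from ends/walls
  uk <- f$u[f$fg & !f$fixed0 & !f$fixed1][keep]
  # discretization shifts the effective Dirichlet radii by a fraction of a
  # pixel, so compare against the log-radius form with fitted radii ...
  co <- coef(lm(uk ~ log(r[keep])))
  r1_eff <- exp(-co[1] / co[2]); r2_eff <- exp((1 - co[1]) / co[2])
  expect_lt(abs(r1_eff - 20), 1)
  expect_lt(abs(r2_eff - 28), 1)
  expect_lt(max(abs(uk - log(r[keep] / r1_eff) / log(r2_eff / r1_eff))), 0.025)
  # ... and against the nominal radii within the O(h) boundary-placement error
  expect_lt(max(abs(uk - log(r[keep] / 20) / log(28 / 20))), 0.1)
})

test_that("solver contract: bad tolerance or iteration budget never passes silently", {
  m <- make_band_mask(6, 30, 0.5)
  s <- split_boundary(m)
  expect_error(solve_laplace(m, s, tol = 0), "tol")
  expect_error(solve_laplace(m, s, tol = 1e-12, max_iter = 5L), "converge")
})

test_that("band midline is the horizontal mid-height line spanning the width", {
  m <- make_band_mask(6, 60, 0.5)
  f <- solve_laplace(m, split_boundary(m))
  ml <- extract_midline(f)
  fg_rows <- range(which(rowSums(m$grid) > 0))
  expect_lt(max(abs(ml$points[, 1] - mean(fg_rows))), 0.51)
  expect_lt(abs(ml$arclength_mm - 60) / 60, 0.02)
})

test_that("arch midline sits at the harmonic mid-potential radius sqrt(r1 r2)", {
  a <- make_arch_mask(10, 14, 0.25)
  f <- solve_laplace(a, split_boundary(a))
  ml <- extract_midline(f)
  rad <- ceiling(14 / 0.25); mar <- 4
  r <- sqrt(((rad + mar) - (ml$points[, 1] - 0.5))^2 +
              ((ml$points[, 2] - 0.5) - (rad + mar))^2) * 0.25
  interior <- seq(round(nrow(ml$points) * 0.1), round(nrow(ml$points) * 0.9))
  expect_lt(max(abs(r[interior] - sqrt(10 * 14))), sqrt(10 * 14) * 0.02)
})

test_that("a clipped 0/1 field is rejected as degenerate", {
  m <- make_band_mask(6, 30, 0.5)
  f <- solve_laplace(m, split_boundary(m))
  f$u[f$fg] <- round(f$u[f$fg])
  expect_error(extract_midline(f), "degenerate")
})

test_that("band streamlines recover the height at every node", {
  p <- thickness_profile(make_band_mask(6, 60, 0.5))
  expect_profile_within(p, 6, 0.02)
  expect_equal(p$n_nodes, 100L)
  expect_equal(p$node, 0:99)
})

test_that("arch streamlines are radial: thickness = outer - inner at all nodes", {
  p <- thickness_profile(make_arch_mask(10, 14, 0.5))
  expect_profile_within(p, 4, 0.02)
})

test_that("n_nodes contract holds down to 2 stations", {
  m <- make_band_mask(6, 30, 0.5)
  f <- solve_laplace(m, split_boundary(m))
  ml <- extract_midline(f)
  p2 <- trace_streamlines(f, ml, n_nodes = 2L)
  expect_length(p2$thickness_mm, 2L)
  expect_error(trace_streamlines(f, ml, n_nodes = 1L), "at least 2")
})

test_that("mirroring the mask left-right reverses the profile", {
  a <- make_arch_mask(10, 14, 0.5)
  p <- thickness_profile(a)
  af <- a
  af$grid <- a$grid[, rev(seq_len(ncol(a$grid)))]
  pf <- thickness_profile(af)
  expect_lt(max(abs(rev(pf$thickness_mm) - p$thickness_mm)), 1e-6)
})

test_that("halving the pixel size does not increase the analytic error", {
  e_coarse <- max(abs(thickness_profile(make_arch_mask(10, 14, 0.5))$thickness_mm - 4))
  e_fine <- max(abs(thickness_profile(make_arch_mask(10, 14, 0.25))$thickness_mm - 4))
  expect_lte(e_fine, e_coarse)
  b_coarse <- max(abs(thickness_profile(make_band_mask(6, 60, 0.5))$thickness_mm - 6))
  b_fine <- max(abs(thickness_profile(make_band_mask(6, 60, 0.25))$thickness_mm - 6))
  expect_lte(b_fine, b_coarse)
})

test_that("profiles agree across resolutions node-wise within 3 percent", {
  p1 <- thickness_profile(make_arch_mask(10, 14, 0.5))
  p2 <- thickness_profile(make_arch_mask(10, 14, 0.25))
  expect_lt(max(abs(p1$thickness_mm - p2$thickness_mm) / p2$thickness_mm), 0.03)
})
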