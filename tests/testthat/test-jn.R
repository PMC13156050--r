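# Moderation fit, conditional effects, Johnson-Neyman boundaries, pointwise
# scan and region aggregation.

test_that("noise-free group effect is recovered exactly", {
  set.seed(1)
  g <- rep(0:1, each = 20)
  m <- runif(40, 11, 42)
  fit <- fit_moderation(2 * g, g, m)
  expect_equal(unname(fit$coef[2]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$coef[4]), 0, tolerance = 1e-10)
})

test_that("single-level group and aliased covariates raise rank errors", {
  set.seed(2)
  m <- runif(30, 11, 42)
  expect_error(fit_moderation(rnorm(30), rep(0, 30), m), "single level")
  g <- rep(0:1, 15)
  expect_error(fit_moderation(rnorm(30), g, m, covariates = data.frame(dup = g)),
               "rank deficient")
})

test_that("conditional effect matches its closed form and the re-centering oracle", {
  set.seed(3)
  n <- 120
  g <- rep(0:1, each = n / 2)
  m <- runif(n, 11, 42)
  y <- 1 + 0.8 * g + 0.02 * m - 0.03 * g * m + rnorm(n, 0, 0.7)
  fit <- fit_moderation(y, g, m)
  ce0 <- conditional_effect(fit, 0)
  expect_equal(ce0$theta, unname(fit$coef[2]))
  expect_equal(ce0$se, sqrt(fit$vcov[2, 2]))
  # identity theta(M)/SE(M) = t(M) on a grid
  ce <- conditional_effect(fit, seq(11, 42, by = 1))
  expect_equal(ce$t, ce$theta / ce$se)
  expect_equal(ce$ci_upper - ce$theta, qt(0.975, fit$df) * ce$se)
  # re-centering: p at M equals the group coefficient p with (m - M)
  for (M in c(15, 25, 38)) {
    fitc <- fit_moderation(y, g, m - M)
    tc <- unname(fitc$coef[2] / sqrt(fitc$vcov[2, 2]))
    expect_equal(conditional_effect(fit, M)$t, tc, tolerance = 1e-8)
    expect_equal(conditional_effect(fit, M)$theta, unname(fitc$coef[2]),
                 tolerance = 1e-8)
  }
})

test_that("constant significant effect yields no boundaries", {
  fit <- structure(list(
    coef = c("(Intercept)" = 0, ".x" = 2, ".m" = 0, ".x:.m" = 0),
    vcov = diag(c(0.01, 0.04, 1e-6, 1e-8)), df = 100L, n = 104L,
    sigma2 = 1, moderator_range = c(11, 42), dropped = 0L), class = "jn_fit")
  jn <- jn_boundaries(fit)
  expect_length(jn$boundaries, 0)
  expect_true(all(jn$intervals$significant))
  expect_true(all(jn$intervals$theta_sign > 0))
})

test_that("JN boundaries agree with a dense grid-scan oracle on random fits", {
  set.seed(42)
  for (i in 1:60) {
    fit <- random_jn_fit()
    jn <- jn_boundaries(fit, moderator_range = c(11, 42))
    oracle <- grid_scan_boundaries(fit, moderator_range = c(11, 42))
    # ignore roots hugging the range limits (grid endpoints blur them)
    inner <- function(x) x[x > 11.01 & x < 41.99]
    got <- inner(jn$boundaries); want <- inner(oracle)
    expect_equal(length(got), length(want), info = sprintf("rep %d", i))
    if (length(got)) expect_lt(max(abs(got - want)), 0.002)
  }
})

test_that("planted crossover cohort yields boundaries bracketing the truth", {
  cfg <- cohort_config(n_patients = 200, n_controls = 200, crossover_age = 25,
                       seed = 7)
  sim <- simulate_cohort(cfg)
  rm_ <- aggregate_regions(sim$thickness)
  fit <- fit_moderation(rm_[, "IV"], sim$cohort$group, sim$cohort$age,
                        sim$cohort[, c("sex", "education", "tiv")])
  jn <- jn_boundaries(fit)
  expect_length(jn$boundaries, 2)
  expect_lt(jn$boundaries[1], 25); expect_gt(jn$boundaries[2], 25)
  # pattern: thinner before the lower boundary, thicker after the upper
  expect_equal(jn$intervals$theta_sign, c(-1, -1, 1))
  expect_true(jn$intervals$significant[1])
  expect_true(jn$intervals$significant[3])
  expect_false(jn$intervals$significant[2])
  expect_lt(abs(crossover_age(fit) - 25), 2)
})

test_that("pointwise scan recovers the affected window and controls the rest", {
  cfg <- cohort_config(n_patients = 200, n_controls = 200, seed = 13)
  sim <- simulate_cohort(cfg)
  scan <- pointwise_scan(sim$thickness, sim$cohort)
  hits <- scan$node[scan$significant]
  planted <- cfg$affected_nodes
  expect_gte(length(intersect(hits, planted)), ceiling(length(planted) / 2))
  off <- setdiff(0:99, planted)
  expect_lte(length(intersect(hits, off)), 0.05 * length(off))
  # node-wise agreement with fit_moderation on a few nodes
  for (nd in c(0L, 17L, 63L)) {
    fit <- fit_moderation(sim$thickness[, nd + 1L], sim$cohort$group,
                          sim$cohort$age, sim$cohort[, c("sex", "education", "tiv")])
    i <- which(scan$node == nd)
    expect_equal(scan$b3[i], unname(fit$coef[4]), tolerance = 1e-8)
    expect_equal(scan$p[i],
                 unname(2 * pt(-abs(fit$coef[4] / sqrt(fit$vcov[4, 4])), fit$df)),
                 tolerance = 1e-8)
  }
})

test_that("identical p-values collapse to identical BH q-values", {
  p <- rep(0.031, 100)
  expect_equal(p.adjust(p, "BH"), p)
  scan_q <- bh_reference(p)
  expect_equal(scan_q, p)
})

test_that("BH q-values are monotone in sorted p order and bounded by 1", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- p.adjust(p, "BH")
    expect_equal(q, bh_reference(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q <= 1))
  }
})

test_that("region means follow the arithmetic of their windows", {
  prof <- matrix(5, 3, 100, dimnames = list(NULL, sprintf("node_%02d", 0:99)))
  rm_ <- aggregate_regions(prof)
  expect_true(all(rm_ == 5))
  # Region I over nodes 73..78 set to 1..6 -> mean 3.5
  prof[1, 74:79] <- 1:6
  expect_equal(unname(aggregate_regions(prof)[1, "I"]), 3.5)
  # window sizes: 6, 22, 9, 11 nodes
  w <- witelson_regions()
  expect_equal(w$end - w$start + 1L, c(6L, 22L, 9L, 11L))
  bad <- data.frame(region = "X", start = 95L, end = 110L, label = "")
  expect_error(aggregate_regions(prof, bad), "outside")
})
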