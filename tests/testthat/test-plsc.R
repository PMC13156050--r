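# PLSC: input assembly, SVD fit, permutation, bootstrap, behaviour scores.

make_inputs <- function(n = 80, seed = 1, strength = 0.8) {
  cfg <- cohort_config(n_patients = n, n_controls = 20,
                       symptom_latent_strength = strength, seed = seed)
  sim <- simulate_cohort(cfg)
  pat <- sim$cohort$group == "patient"
  rm_ <- aggregate_regions(sim$thickness)
  plsc_inputs(rm_[pat, "IV"], sim$cohort$age[pat], sim$symptoms)
}

test_that("input columns are z-scored and zero-variance columns excluded", {
  inp <- make_inputs()
  expect_equal(colMeans(inp$X), c(thickness = 0, age = 0, interaction = 0),
               tolerance = 1e-10)
  expect_equal(unname(apply(inp$X, 2, sd)), rep(1, 3), tolerance = 1e-10)
  expect_equal(unname(colMeans(inp$Y)), rep(0, ncol(inp$Y)), tolerance = 1e-10)
  expect_equal(unname(apply(inp$Y, 2, sd)), rep(1, ncol(inp$Y)), tolerance = 1e-10)
  # constant symptom column excluded with a warning
  sym <- data.frame(a = rnorm(30), b = rep(2, 30), c = rnorm(30))
  expect_warning(inp2 <- plsc_inputs(rnorm(30), runif(30, 11, 42), sym),
                 "zero-variance")
  expect_equal(colnames(inp2$Y), c("a", "c"))
})

test_that("row alignment invariance: a shared permutation leaves R unchanged", {
  inp <- make_inputs(seed = 6)
  set.seed(99)
  perm <- sample.int(inp$n)
  inp2 <- inp
  inp2$X <- inp$X[perm, ]; inp2$Y <- inp$Y[perm, ]
  expect_equal(plsc_fit(inp)$R, plsc_fit(inp2)$R, tolerance = 1e-12)
})

test_that("incomplete rows are dropped and tiny inputs rejected", {
  th <- c(rnorm(15), NA)
  expect_message(inp <- plsc_inputs(th, runif(16, 11, 42),
                                    data.frame(a = rnorm(16), b = rnorm(16))),
                 "dropped 1")
  expect_equal(inp$n, 15L)
  expect_error(plsc_inputs(rnorm(5), runif(5), data.frame(a = rnorm(5))),
               "fewer than 10")
})

test_that("self-covariance case: singular values equal correlation eigenvalues", {
  set.seed(8)
  X <- scale(matrix(rnorm(60 * 3), 60, 3))
  inp <- structure(list(X = X, Y = X, n = 60L, scale_y = TRUE), class = "plsc_inputs")
  mod <- plsc_fit(inp)
  ev <- sort(eigen(stats::cor(X) * (59 / 59), symmetric = TRUE)$values, decreasing = TRUE)
  Rc <- crossprod(X, X) / 59
  expect_equal(mod$S, sort(abs(eigen(Rc)$values), decreasing = TRUE), tolerance = 1e-10)
  expect_true(all(diff(mod$S) <= 1e-12))
  expect_equal(ev, mod$S, tolerance = 1e-10)
})

test_that("singular values match a characteristic-polynomial oracle on toy matrices", {
  set.seed(10)
  for (i in 1:10) {
    X <- scale(matrix(sample(-5:5, 4 * 3, replace = TRUE) + rnorm(12, 0, 1e-6), 4, 3))
    Y <- scale(matrix(sample(-5:5, 4 * 4, replace = TRUE) + rnorm(16, 0, 1e-6), 4, 4))
    R <- crossprod(X, Y) / 3
    got <- svd(R)$d
    want <- charpoly_singular_values(R)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("energy conservation: sum of squared singular values equals ||R||_F^2", {
  set.seed(12)
  for (i in 1:20) {
    inp <- structure(list(X = scale(matrix(rnorm(40 * 3), 40, 3)),
                          Y = scale(matrix(rnorm(40 * 12), 40, 12)),
                          n = 40L, scale_y = TRUE), class = "plsc_inputs")
    mod <- plsc_fit(inp)
    expect_lt(abs(sum(mod$S^2) - sum(mod$R^2)) / sum(mod$R^2), 1e-10)
    expect_true(all(diff(mod$S) <= 0))
    expect_true(all(mod$S >= 0))
    # orthonormal saliences
    expect_equal(crossprod(mod$U), diag(3), tolerance = 1e-10)
    expect_equal(crossprod(mod$V), diag(3), tolerance = 1e-10)
    # deterministic sign convention
    expect_true(all(apply(mod$U, 2, function(u) u[which.max(abs(u))] > 0)))
  }
})

test_that("rank-1 planted covariance is recovered in the first design salience", {
  inp <- make_inputs(n = 137, seed = 3, strength = 0.8)
  mod <- plsc_fit(inp)
  expect_gt(abs(mod$U[3, 1]), 0.9)  # interaction column dominates LV1
})

test_that("permutation p-values are seeded, add-one bounded and signal-sensitive", {
  inp <- make_inputs(n = 137, seed = 3, strength = 0.8)
  p1 <- plsc_permutation(inp, n_perm = 200, seed = 5)
  p2 <- plsc_permutation(inp, n_perm = 200, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0))
  expect_lte(p1[1], 0.05)
  pmax_mode <- plsc_permutation(inp, n_perm = 200, seed = 5, mode = "max")
  expect_true(all(pmax_mode >= p1 - 1e-12))  # max null is stochastically larger
  expect_error(plsc_permutation(inp, n_perm = 50), "at least 100")
})

test_that("bootstrap ratios are seeded and flag the planted salience elements", {
  inp <- make_inputs(n = 137, seed = 3, strength = 0.8)
  b1 <- plsc_bootstrap(inp, n_boot = 200, seed = 5)
  b2 <- plsc_bootstrap(inp, n_boot = 200, seed = 5)
  expect_identical(b1$bsr_v, b2$bsr_v)
  # planted positive items significant and positive; planted negative item negative
  expect_true(all(b1$bsr_v[c("G1", "G2", "G3", "G6"), 1] > 2))
  expect_lt(b1$bsr_v["N7", 1], -2)
  expect_gt(b1$bsr_u["interaction", 1], 2)
})

test_that("behaviour scores are the plain projection Y U", {
  set.seed(14)
  Y <- matrix(rnorm(50 * 6), 50, 6)
  expect_equal(behavior_scores(Y, diag(6)), Y)
  u <- rnorm(6); u <- u / sqrt(sum(u^2))
  Yu <- matrix(u, 50, 6, byrow = TRUE)
  expect_equal(unname(behavior_scores(Yu, matrix(u))), matrix(1, 50, 1),
               tolerance = 1e-12)
  expect_error(behavior_scores(Y, diag(5)), "non-conformable")
})

test_that("latent scores satisfy the SVD identity (XU)'(YV) = (n-1) diag(S)", {
  set.seed(15)
  for (i in 1:5) {
    X <- scale(matrix(rnorm(60 * 3), 60, 3))
    Y <- scale(matrix(rnorm(60 * 9), 60, 9))
    inp <- structure(list(X = X, Y = Y, n = 60L, scale_y = TRUE), class = "plsc_inputs")
    mod <- plsc_fit(inp)
    cross <- crossprod(X %*% mod$U, Y %*% mod$V)
    expect_equal(cross, diag(59 * mod$S), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("symptom JN follow-up recovers coupling above the crossover age", {
  inp <- make_inputs(n = 137, seed = 3, strength = 0.8)
  mod <- plsc_fit(inp)
  scores <- behavior_scores(inp$Y, mod$V)
  sjn <- symptom_jn(scores[, 1], inp$thickness_raw, inp$age_raw)
  expect_s3_class(sjn$jn, "jn_solution")
  expect_gte(length(sjn$jn$boundaries), 1)
  # a constant thickness column propagates a rank error
  expect_error(symptom_jn(scores[, 1], rep(3, inp$n), inp$age_raw),
               "rank|constant|degenerate")
})

test_that("FDR across regions follows BH arithmetic", {
  expect_equal(fdr_across_regions(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_across_regions(rep(0.2, 4)), rep(0.2, 4))
  set.seed(16)
  p <- runif(4)
  expect_equal(fdr_across_regions(p), bh_reference(p))
  expect_error(fdr_across_regions(c(0.1, 0.2)), "exactly 4")
})
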