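# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Dense grid scan of the conditional-effect t statistic: boundaries are the
# sign changes of |t(M)| - t_crit on a fine moderator grid.
grid_scan_boundaries <- function(fit, alpha = 0.05, moderator_range, step = 0.001) {
  b1 <- fit$coef[[2]]; b3 <- fit$coef[[4]]
  v11 <- fit$vcov[2, 2]; v13 <- fit$vcov[2, 4]; v33 <- fit$vcov[4, 4]
  tc <- qt(1 - alpha / 2, df = fit$df)
  M <- seq(moderator_range[1], moderator_range[2], by = step)
  h <- abs((b1 + b3 * M) / sqrt(v11 + 2 * M * v13 + M^2 * v33)) - tc
  flips <- which(diff(sign(h)) != 0)
  (M[flips] + M[flips + 1L]) / 2
}

# Textbook step-up BH: q_(i) = min_{j >= i} m p_(j) / j, computed by loop.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * ps[i] / i)
    q[i] <- running
  }
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Singular values of a small matrix via the characteristic polynomial of the
# smaller Gram matrix, solved with polyroot (cubic or smaller only).
charpoly_singular_values <- function(R) {
  G <- if (nrow(R) <= ncol(R)) R %*% t(R) else t(R) %*% R
  stopifnot(nrow(G) <= 3L)
  if (nrow(G) == 3L) {
    tr <- sum(diag(G))
    m2 <- det(G[1:2, 1:2]) + det(G[c(1, 3), c(1, 3)]) + det(G[2:3, 2:3])
    dt <- det(G)
    # lambda^3 - tr lambda^2 + m2 lambda - det = 0
    lam <- polyroot(c(-dt, m2, -tr, 1))
  } else if (nrow(G) == 2L) {
    lam <- polyroot(c(det(G), -sum(diag(G)), 1))
  } else {
    lam <- complex(real = G[1, 1])
  }
  sort(sqrt(pmax(Re(lam), 0)), decreasing = TRUE)
}

# Random moderation fit on a small simulated dataset with random coefficients.
random_jn_fit <- function() {
  n <- sample(30:60, 1)
  g <- rbinom(n, 1, 0.5)
  if (all(g == 0) || all(g == 1)) g[sample(n, 2)] <- c(0, 1)
  m <- runif(n, 11, 42)
  y <- rnorm(1, 0, 2) + rnorm(1, 0, 0.5) * g + rnorm(1, 0, 0.1) * m +
    rnorm(1, 0, 0.05) * g * m + rnorm(n, 0, runif(1, 0.3, 2))
  fit_moderation(y, g, m)
}

expect_profile_within <- function(profile, truth_mm, tol_frac) {
  expect_length(profile$thickness_mm, profile$n_nodes)
  expect_true(all(is.finite(profile$thickness_mm)))
  expect_true(all(profile$thickness_mm > 0))
  expect_lt(max(abs(profile$thickness_mm - truth_mm)) / truth_mm, tol_frac)
}
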