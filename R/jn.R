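# Moderation model, conditional effects and Johnson-Neyman boundaries.
#
# Model per outcome: y = b0 + b1*x + b2*m + b3*(x*m) + covariates + e, with x
# the group indicator (0 = control, 1 = patient; theta > 0 means patients
# higher) or a continuous predictor, and m the moderator (age in years,
# uncentred: boundaries are reported on the raw year scale). The conditional
# effect of x at moderator value M is theta(M) = b1 + b3*M with
# Var(theta) = v11 + 2*M*v13 + M^2*v33 from the coefficient covariance.

#' Fit the group-by-moderator interaction model
#'
#' Ordinary least squares of `outcome ~ x * m + covariates`. Rows with missing
#' values are dropped (with a message). The group variable may be a 0/1
#' numeric, logical, or a factor/character with exactly two levels (the
#' second level is coded 1); continuous predictors are accepted when
#' `require_binary = FALSE`.
#'
#' @param outcome numeric response (e.g. node or region thickness in mm).
#' @param group predictor of interest (group indicator, or continuous).
#' @param moderator numeric moderator (age in years).
#' @param covariates optional data.frame of nuisance covariates; character
#'   columns are converted to factors.
#' @param require_binary check that `group` is two-level (default TRUE).
#' @return object of class `jn_fit`: `coef` (b0, b1, b2, b3, covariates...),
#'   `vcov`, `df`, `n`, `sigma2`, `moderator_range`, `dropped`.
#' @export
fit_moderation <- function(outcome, group, moderator, covariates = NULL,
                           require_binary = TRUE) {
  n0 <- length(outcome)
  if (length(group) != n0 || length(moderator) != n0)
    stop_invalid("outcome, group and moderator must have equal length")
  if (is.factor(group) || is.character(group)) {
    lev <- unique(as.character(group[!is.na(group)]))
    if (length(lev) > 2L) stop_invalid("group has %d levels; expected 2", length(lev))
    group <- as.numeric(factor(as.character(group), levels = sort(lev))) - 1
  }
  group <- as.numeric(group)
  dat <- data.frame(.y = outcome, .x = group, .m = moderator)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (j in seq_along(covariates))
      if (is.character(covariates[[j]])) covariates[[j]] <- factor(covariates[[j]])
    dat <- cbind(dat, covariates)
  }
  keep <- complete.cases(dat)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("fit_moderation: dropped %d row(s) with missing values", dropped))
    dat <- dat[keep, , drop = FALSE]
  }
  ux <- unique(dat$.x)
  if (require_binary) {
    if (!all(ux %in% c(0, 1)))
      stop_invalid("group must be codable as 0/1 (got values %s)",
                   paste(utils::head(sort(ux), 4), collapse = ", "))
    if (length(ux) < 2L)
      stop_invalid("group has a single level; the design is rank deficient")
  }
  cov_terms <- setdiff(names(dat), c(".y", ".x", ".m"))
  fml <- stats::reformulate(c(".x * .m", cov_terms), response = ".y")
  fit <- lm(fml, data = dat)
  cf <- coef(fit)
  if (anyNA(cf))
    stop_invalid("design is rank deficient; aliased column(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", "))
  # reorder: intercept, x, m, x:m, then covariates
  main <- c("(Intercept)", ".x", ".m", ".x:.m")
  ord <- c(main, setdiff(names(cf), main))
  cf <- cf[ord]
  # suppressWarnings: summary.lm warns on (legitimate) perfect fits
  V <- suppressWarnings(vcov(fit))[ord, ord]
  structure(list(coef = cf, vcov = V, df = fit$df.residual,
                 n = nrow(dat), sigma2 = sum(fit$residuals^2) / fit$df.residual,
                 moderator_range = range(dat$.m), dropped = dropped),
            class = "jn_fit")
}

#' @export
print.jn_fit <- function(x, ...) {
  cat(sprintf("<jn_fit> n=%d df=%d  b1=%.4g  b3=%.4g  (crossover -b1/b3 = %.2f)\n",
              x$n, x$df, x$coef[2], x$coef[4], -x$coef[2] / x$coef[4]))
  invisible(x)
}

#' Conditional effect of the predictor at given moderator values
#'
#' Computes `theta(M) = b1 + b3 * M`, its standard error from the quadratic
#' form of the coefficient covariance, the t statistic against 0, the
#' two-tailed p (residual df), and the `1 - alpha` confidence band.
#'
#' @param fit a `jn_fit`.
#' @param M numeric vector of moderator values.
#' @param alpha significance level (two-tailed).
#' @return data.frame: `M`, `theta`, `se`, `t`, `p`, `ci_lower`, `ci_upper`.
#' @export
conditional_effect <- function(fit, M, alpha = 0.05) {
  stopifnot(inherits(fit, "jn_fit"))
  if (!all(is.finite(M))) stop_invalid("moderator values must be finite")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  b1 <- fit$coef[[2]]; b3 <- fit$coef[[4]]
  v11 <- fit$vcov[2, 2]; v13 <- fit$vcov[2, 4]; v33 <- fit$vcov[4, 4]
  theta <- b1 + b3 * M
  se <- sqrt(v11 + 2 * M * v13 + M^2 * v33)
  tt <- theta / se
  p <- 2 * pt(-abs(tt), df = fit$df)
  tc <- qt(1 - alpha / 2, df = fit$df)
  data.frame(M = M, theta = theta, se = se, t = tt, p = p,
             ci_lower = theta - tc * se, ci_upper = theta + tc * se)
}

#' Johnson-Neyman boundaries of the region of significance
#'
#' Solves `|theta(M)| = t_crit * SE(M)` in closed form: the boundary ages are
#' the real roots of
#' `(t^2 v33 - b3^2) M^2 + 2 (t^2 v13 - b1 b3) M + (t^2 v11 - b1^2) = 0`
#' inside the moderator range. Each interval between boundaries is labelled by
#' the sign and significance of the conditional effect at its midpoint.
#'
#' @param fit a `jn_fit`.
#' @param alpha significance level.
#' @param moderator_range numeric length-2; defaults to the observed range.
#' @return object of class `jn_solution`: `boundaries` (0, 1 or 2 ages),
#'   `intervals` (data.frame: lower, upper, theta_sign, significant),
#'   `alpha`, `t_crit`, `df`, `moderator_range`.
#' @export
jn_boundaries <- function(fit, alpha = 0.05, moderator_range = NULL) {
  stopifnot(inherits(fit, "jn_fit"))
  if (is.null(moderator_range)) moderator_range <- fit$moderator_range
  if (length(moderator_range) != 2L || moderator_range[1] >= moderator_range[2])
    stop_invalid("moderator_range must be (low, high) with low < high")
  b1 <- fit$coef[[2]]; b3 <- fit$coef[[4]]
  v11 <- fit$vcov[2, 2]; v13 <- fit$vcov[2, 4]; v33 <- fit$vcov[4, 4]
  tc <- qt(1 - alpha / 2, df = fit$df)
  A <- tc^2 * v33 - b3^2
  B <- 2 * (tc^2 * v13 - b1 * b3)
  C <- tc^2 * v11 - b1^2
  scale_ref <- max(abs(c(A, B / (2 * max(abs(moderator_range))), 1e-300)))
  roots <- numeric(0)
  if (abs(A) > 1e-14 * scale_ref) {
    disc <- B^2 - 4 * A * C
    if (disc > 0) {
      # numerically stable quadratic roots
      q <- -(B + sign(B + (B == 0)) * sqrt(disc)) / 2
      roots <- sort(c(q / A, if (abs(q) > 0) C / q else -B / (2 * A)))
    } else if (disc == 0) {
      roots <- -B / (2 * A)
    }
  } else if (abs(B) > 0) {
    roots <- -C / B
  }
  roots <- roots[is.finite(roots) & roots >= moderator_range[1] & roots <= moderator_range[2]]
  roots <- sort(unique(roots))
  edges <- c(moderator_range[1], roots, moderator_range[2])
  mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  ce <- conditional_effect(fit, mids, alpha = alpha)
  intervals <- data.frame(lower = utils::head(edges, -1),
                          upper = utils::tail(edges, -1),
                          theta_sign = sign(ce$theta),
                          significant = abs(ce$t) > tc)
  structure(list(boundaries = roots, intervals = intervals, alpha = alpha,
                 t_crit = tc, df = fit$df, moderator_range = moderator_range),
            class = "jn_solution")
}

#' @export
print.jn_solution <- function(x, ...) {
  if (length(x$boundaries) == 0L) {
    cat(sprintf("<jn_solution> no boundaries in [%.1f, %.1f]; effect %s throughout\n",
                x$moderator_range[1], x$moderator_range[2],
                if (x$intervals$significant[1])
                  sprintf("significant (theta %s)", if (x$intervals$theta_sign[1] > 0) ">0" else "<0")
                else "n.s."))
  } else {
    cat(sprintf("<jn_solution> boundaries at %s years (alpha = %g)\n",
                paste(sprintf("%.2f", x$boundaries), collapse = ", "), x$alpha))
    for (i in seq_len(nrow(x$intervals)))
      cat(sprintf("  [%.2f, %.2f] theta %s, %s\n", x$intervals$lower[i], x$intervals$upper[i],
                  if (x$intervals$theta_sign[i] > 0) ">0" else "<0",
                  if (x$intervals$significant[i]) "significant" else "n.s."))
  }
  invisible(x)
}

#' Crossover age implied by a moderation fit
#'
#' The age at which the fitted conditional effect changes sign: `-b1 / b3`.
#'
#' @param fit a `jn_fit`.
#' @return numeric scalar (years).
#' @export
crossover_age <- function(fit) {
  stopifnot(inherits(fit, "jn_fit"))
  -fit$coef[[2]] / fit$coef[[4]]
}

#' Pointwise interaction scan across profile nodes with FDR control
#'
#' Fits the moderation model at each of the 100 nodes (one multi-response
#' least-squares decomposition, identical to node-wise [fit_moderation()]),
#' collects the group-by-age interaction p-values, and applies
#' Benjamini-Hochberg FDR across nodes.
#'
#' @param profiles subjects-by-nodes thickness matrix (columns `node_00`...).
#' @param cohort cohort data.frame with `group`, `age` and the covariate
#'   columns; rows aligned with `profiles`.
#' @param alpha FDR level for the significance mask.
#' @param covariates character vector of covariate column names in `cohort`.
#' @return data.frame, one row per node: `node`, `b1`, `b3`, `se3`, `t3`,
#'   `p`, `q`, `significant`.
#' @export
pointwise_scan <- function(profiles, cohort, alpha = 0.05,
                           covariates = c("sex", "education", "tiv")) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != nrow(cohort))
    stop_invalid("profiles (%d rows) and cohort (%d rows) are misaligned",
                 nrow(profiles), nrow(cohort))
  g <- cohort$group
  if (is.factor(g) || is.character(g)) g <- as.numeric(factor(g)) - 1
  X <- cbind(1, g, cohort$age)
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (is.null(v)) stop_invalid("covariate '%s' not found in cohort", cv)
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
  }
  X <- cbind(X, g * cohort$age)
  colnames(X) <- c("(Intercept)", "group", "age", covariates, "group:age")
  keep <- complete.cases(X) & complete.cases(profiles)
  X <- X[keep, , drop = FALSE]; Y <- profiles[keep, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  # column-equilibrated normal equations for numerical stability
  cn <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, cn, `/`)
  qrX <- qr(Xs)
  if (qrX$rank < p)
    stop_invalid("scan design is rank deficient (rank %d < %d columns)", qrX$rank, p)
  beta_s <- qr.coef(qrX, Y)
  res <- Y - Xs %*% beta_s
  s2 <- colSums(res^2) / (n - p)
  XtXinv_s <- chol2inv(qr.R(qrX))
  ip <- order(qrX$pivot)
  XtXinv_s <- XtXinv_s[ip, ip, drop = FALSE]
  beta <- sweep(beta_s, 1, cn, `/`)
  i1 <- 2L; i3 <- p
  se3 <- sqrt(s2 * XtXinv_s[i3, i3]) / cn[i3]
  t3 <- beta[i3, ] / se3
  pv <- 2 * pt(-abs(t3), df = n - p)
  q <- p.adjust(pv, method = "BH")
  data.frame(node = 0:(ncol(Y) - 1L), b1 = beta[i1, ], b3 = beta[i3, ],
             se3 = se3, t3 = t3, p = pv, q = q, significant = q <= alpha)
}
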