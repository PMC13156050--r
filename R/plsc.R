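# Partial least squares correlation between the thickness/age design and
# symptom scores: SVD of the cross-block correlation matrix, permutation
# inference on singular values, bootstrap ratios on saliences.

#' Assemble PLSC input matrices
#'
#' Builds the design block X = [region thickness, age, thickness-by-age
#' interaction] and the symptom block Y. The interaction column is the product
#' of the z-scored components; all used columns are then z-scored (Y
#' optionally left on its raw scale, centred only). Incomplete rows are
#' dropped with a message; zero-variance symptom columns are excluded with a
#' warning.
#'
#' @param region_thickness numeric vector (mm), one value per patient.
#' @param age numeric vector (years).
#' @param symptoms data.frame or matrix of symptom columns (a `subject_id`
#'   column, if present, is ignored as data).
#' @param scale_y z-score Y columns (default TRUE); if FALSE they are centred
#'   but keep their raw scale.
#' @return object of class `plsc_inputs`: `X` (n x 3), `Y`, `n`, `dropped`,
#'   `excluded` (names of zero-variance columns).
#' @export
plsc_inputs <- function(region_thickness, age, symptoms, scale_y = TRUE) {
  symptoms <- as.data.frame(symptoms)
  symptoms$subject_id <- NULL
  Y <- as.matrix(symptoms)
  if (!is.numeric(Y)) stop_invalid("symptom columns must be numeric")
  n0 <- length(region_thickness)
  if (length(age) != n0 || nrow(Y) != n0)
    stop_invalid("region_thickness, age and symptoms must be row-aligned")
  keep <- is.finite(region_thickness) & is.finite(age) & complete.cases(Y)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(sprintf("plsc_inputs: dropped %d incomplete row(s)", dropped))
  if (sum(keep) < 10L)
    stop_invalid("fewer than 10 complete rows (%d); PLSC inputs unusable", sum(keep))
  th <- region_thickness[keep]; ag <- age[keep]; Y <- Y[keep, , drop = FALSE]
  sds <- apply(Y, 2, sd)
  excluded <- colnames(Y)[sds == 0]
  if (length(excluded) > 0L) {
    warning(sprintf("excluding %d zero-variance symptom column(s): %s",
                    length(excluded), paste(excluded, collapse = ", ")),
            call. = FALSE)
    Y <- Y[, sds > 0, drop = FALSE]
  }
  if (sd(th) == 0) stop_invalid("region thickness is constant; design is degenerate")
  inter <- as.numeric(scale(th)) * as.numeric(scale(ag))
  X <- cbind(thickness = as.numeric(scale(th)), age = as.numeric(scale(ag)),
             interaction = as.numeric(scale(inter)))
  Y <- if (scale_y) scale(Y) else scale(Y, scale = FALSE)
  structure(list(X = X, Y = as.matrix(Y), n = nrow(X),
                 thickness_raw = th, age_raw = ag, keep = which(keep),
                 dropped = dropped, excluded = excluded, scale_y = scale_y),
            class = "plsc_inputs")
}

#' @export
print.plsc_inputs <- function(x, ...) {
  cat(sprintf("<plsc_inputs> n=%d, X %d col, Y %d col (%d dropped rows, %d excluded cols)\n",
              x$n, ncol(x$X), ncol(x$Y), x$dropped, length(x$excluded)))
  invisible(x)
}

# cross-block matrix and its SVD with a deterministic sign convention: the
# largest-magnitude element of each design salience is made positive
plsc_decompose <- function(X, Y) {
  R <- crossprod(X, Y) / (nrow(X) - 1)
  sv <- svd(R)
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$u[, k]))
    if (sv$u[j, k] < 0) { sv$u[, k] <- -sv$u[, k]; sv$v[, k] <- -sv$v[, k] }
  }
  list(R = R, U = sv$u, V = sv$v, S = sv$d)
}

#' Fit the PLSC model (point estimate)
#'
#' Computes the cross-block matrix `R = X'Y / (n - 1)` and its singular value
#' decomposition `R = U S V'`. Saliences U (design side) and V (symptom side)
#' are column-orthonormal; each latent variable's sign is fixed by making the
#' largest-magnitude element of its design salience positive.
#'
#' @param inputs a `plsc_inputs`.
#' @return object of class `plsc_model`: `R`, `U`, `V`, `S` (non-increasing
#'   singular values), `n`, `x_names`, `y_names`.
#' @export
plsc_fit <- function(inputs) {
  stopifnot(inherits(inputs, "plsc_inputs"))
  dec <- plsc_decompose(inputs$X, inputs$Y)
  structure(list(R = dec$R, U = dec$U, V = dec$V, S = dec$S, n = inputs$n,
                 x_names = colnames(inputs$X), y_names = colnames(inputs$Y)),
            class = "plsc_model")
}

#' @export
print.plsc_model <- function(x, ...) {
  cat(sprintf("<plsc_model> n=%d, %d LVs; singular values: %s\n",
              x$n, length(x$S), paste(sprintf("%.3f", x$S), collapse = ", ")))
  invisible(x)
}

#' Permutation test on the singular values
#'
#' Rows of Y are permuted (X held fixed), the model refit per permutation, and
#' each latent variable's p-value computed with the add-one rule:
#' `p_k = (1 + #\{S_k^perm >= S_k^obs\}) / (1 + n_perm)`. By default the k-th
#' permuted singular value is compared with the k-th observed one
#' (`mode = "per_lv"`); `mode = "max"` compares every observed value against
#' the permutation distribution of the largest singular value.
#'
#' @param inputs a `plsc_inputs`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; identical seeds give identical p-values.
#' @param mode `"per_lv"` (default) or `"max"`.
#' @return numeric vector of p-values, one per latent variable.
#' @export
plsc_permutation <- function(inputs, n_perm = 10000L, seed = 1L,
                             mode = c("per_lv", "max")) {
  stopifnot(inherits(inputs, "plsc_inputs"))
  mode <- match.arg(mode)
  if (n_perm < 100L) stop_invalid("n_perm must be at least 100")
  obs <- plsc_decompose(inputs$X, inputs$Y)$S
  k <- length(obs)
  set.seed(derive_seed(seed, "permutation"))
  exceed <- numeric(k)
  for (b in seq_len(n_perm)) {
    Yp <- inputs$Y[sample.int(inputs$n), , drop = FALSE]
    Sp <- svd(crossprod(inputs$X, Yp) / (inputs$n - 1), nu = 0, nv = 0)$d
    if (mode == "per_lv") exceed <- exceed + (Sp >= obs)
    else exceed <- exceed + (max(Sp) >= obs)
  }
  (1 + exceed) / (1 + n_perm)
}

#' Bootstrap ratios for the saliences
#'
#' Patients are resampled with replacement; X and Y are re-standardized within
#' each bootstrap sample, the model refit, and each latent variable sign-
#' aligned to the observed saliences (flip so the inner product of the design
#' saliences is non-negative). The bootstrap ratio is the observed salience
#' element divided by its bootstrap standard error; `|BSR| > 2` is the
#' conventional significance mask. Degenerate resamples (any constant used
#' column) are redrawn and counted.
#'
#' @param inputs a `plsc_inputs`.
#' @param n_boot number of bootstrap samples (>= 100).
#' @param seed integer seed.
#' @return list: `bsr_u`, `bsr_v`, `se_u`, `se_v`, `sig_u`, `sig_v`
#'   (|BSR| > 2 masks), `redrawn` (count of degenerate resamples).
#' @export
plsc_bootstrap <- function(inputs, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(inputs, "plsc_inputs"))
  if (n_boot < 100L) stop_invalid("n_boot must be at least 100")
  obs <- plsc_decompose(inputs$X, inputs$Y)
  k <- length(obs$S)
  set.seed(derive_seed(seed, "bootstrap"))
  acc_u <- array(0, c(dim(obs$U), n_boot))
  acc_v <- array(0, c(dim(obs$V), n_boot))
  redrawn <- 0L
  b <- 1L
  while (b <= n_boot) {
    idx <- sample.int(inputs$n, replace = TRUE)
    Xb <- inputs$X[idx, , drop = FALSE]
    Yb <- inputs$Y[idx, , drop = FALSE]
    if (any(apply(Xb, 2, sd) == 0) || any(apply(Yb, 2, sd) == 0)) {
      redrawn <- redrawn + 1L
      if (redrawn > 100L * n_boot) stop_invalid("bootstrap resampling keeps degenerating")
      next
    }
    Xb <- scale(Xb)
    Yb <- if (inputs$scale_y) scale(Yb) else scale(Yb, scale = FALSE)
    dec <- plsc_decompose(Xb, Yb)
    for (j in seq_len(k)) {
      if (sum(dec$U[, j] * obs$U[, j]) < 0) {
        dec$U[, j] <- -dec$U[, j]; dec$V[, j] <- -dec$V[, j]
      }
    }
    acc_u[, , b] <- dec$U; acc_v[, , b] <- dec$V
    b <- b + 1L
  }
  se_u <- apply(acc_u, c(1, 2), sd)
  se_v <- apply(acc_v, c(1, 2), sd)
  bsr_u <- obs$U / pmax(se_u, 1e-12)
  bsr_v <- obs$V / pmax(se_v, 1e-12)
  rownames(bsr_v) <- rownames(se_v) <- colnames(inputs$Y)
  rownames(bsr_u) <- rownames(se_u) <- colnames(inputs$X)
  list(bsr_u = bsr_u, bsr_v = bsr_v, se_u = se_u, se_v = se_v,
       sig_u = abs(bsr_u) > 2, sig_v = abs(bsr_v) > 2, redrawn = redrawn)
}

#' Behaviour scores
#'
#' Projects each subject's symptom row onto the symptom-block saliences:
#' `scores = Y U`, one column per latent variable. In a fitted `plsc_model`
#' the symptom-block salience matrix is `V`, so region-level behaviour scores
#' are `behavior_scores(inputs$Y, model$V)`.
#'
#' @param Y symptom matrix (n x q).
#' @param U salience matrix with q rows (one per symptom column) and one
#'   column per latent variable.
#' @return n x k score matrix.
#' @export
behavior_scores <- function(Y, U) {
  Y <- as.matrix(Y); U <- as.matrix(U)
  if (ncol(Y) != nrow(U))
    stop_invalid("non-conformable: Y has %d columns but U has %d rows", ncol(Y), nrow(U))
  Y %*% U
}

#' Region-level symptom follow-up with the Johnson-Neyman technique
#'
#' Confirms a PLSC coupling by moderation analysis: the first-LV behaviour
#' score is regressed on region thickness, age and their interaction (plus
#' optional covariates), and the Johnson-Neyman boundaries of the conditional
#' thickness effect across age are solved.
#'
#' @param scores behaviour score vector (first LV) or matrix (first column used).
#' @param region_thickness numeric vector (mm).
#' @param age numeric vector (years).
#' @param covariates optional data.frame (e.g. illness duration, age of onset,
#'   sex, education for the sensitivity variant).
#' @param alpha significance level.
#' @return list: `fit` (`jn_fit`), `jn` (`jn_solution`).
#' @export
symptom_jn <- function(scores, region_thickness, age, covariates = NULL,
                       alpha = 0.05) {
  scores <- as.matrix(scores)[, 1]
  fit <- fit_moderation(scores, region_thickness, age, covariates,
                        require_binary = FALSE)
  list(fit = fit, jn = jn_boundaries(fit, alpha = alpha))
}

#' FDR across the four region-level PLSC analyses
#'
#' Benjamini-Hochberg adjustment of the four first-LV permutation p-values
#' (one per subregion).
#'
#' @param p numeric vector of exactly 4 p-values.
#' @return numeric vector of 4 q-values.
#' @export
fdr_across_regions <- function(p) {
  if (length(p) != 4L) stop_invalid("expected exactly 4 region-level p-values, got %d", length(p))
  p.adjust(p, method = "BH")
}
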