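# Synthetic case-control cohorts with a planted crossover group-by-age effect
# on the thickness profile and an optional planted latent brain-symptom
# covariance, so the moderation scan, Johnson-Neyman solver and PLSC stage can
# all be validated by parameter recovery.

# fixed PANSS-style item layout and four-factor map (uniform weights within
# factor; published factor loadings are not available, so factors are plain
# means of their items)
panss_items <- function() {
  c(sprintf("P%d", 1:7), sprintf("N%d", 1:7), sprintf("G%d", 1:16))
}

panss_factor_map <- function() {
  list(
    positive  = c("P1", "P3", "P5", "P6", "G9"),
    negative  = c("N1", "N2", "N3", "N4", "N6", "G7"),
    affective = c("G1", "G2", "G3", "G6"),
    cognitive = c("P2", "N5", "N7", "G5", "G10", "G11", "G13")
  )
}

# planted symptom salience: somatic concern / anxiety / guilt / depression
# load positively, stereotyped thinking negatively; unit norm over items
planted_salience <- function() {
  v <- stats::setNames(numeric(30), panss_items())
  v[c("G1", "G2")] <- 0.55
  v[c("G3", "G6")] <- 0.45
  v["N7"] <- -0.35
  v / sqrt(sum(v^2))
}

#' Smooth baseline thickness template
#'
#' A fixed, smooth, positive 100-node profile used as the population mean
#' thickness: thick splenium and genu, thinner isthmus, tapering ends. Values
#' are in mm and broadly match adult callosal thickness ranges.
#'
#' @return numeric vector of length 100 (node 0 posterior ... node 99 anterior).
#' @export
cc_baseline_profile <- function() {
  x <- (0:99) / 99
  5 +
    2.5 * exp(-((x - 0.15)^2) / (2 * 0.07^2)) +   # splenium bulge
    3.0 * exp(-((x - 0.90)^2) / (2 * 0.06^2)) -   # genu bulge
    1.8 * exp(-((x - 0.28)^2) / (2 * 0.05^2)) -   # isthmus waist
    1.5 * exp(-((x - 0.02)^2) / (2 * 0.04^2)) -   # posterior taper
    1.5 * exp(-((x - 1.00)^2) / (2 * 0.04^2))     # anterior taper
}

#' Configuration for a synthetic cohort
#'
#' Defines the generative conditions: group sizes, the age window, the planted
#' crossover age `a*` at which the group effect on thickness changes sign, the
#' effect slope (mm per year of distance from `a*`), which nodes carry the
#' effect, covariate effects, node noise, and the strength of the latent
#' coupling between the thickness-by-age interaction and symptom scores.
#'
#' Defaults mirror the reference case-control study conditions: 151 patients,
#' 278 controls, ages 11-42, education and intracranial volume marginals with
#' the published group means/SDs, and a splenium effect window (nodes 13-23).
#'
#' @param n_patients,n_controls group sizes.
#' @param age_range numeric length-2, years.
#' @param crossover_age the planted sign-change age `a*`, strictly inside
#'   `age_range`.
#' @param effect_slope group effect slope in mm/year: the patient-minus-control
#'   difference at age `a` is `effect_slope * (a - crossover_age)` on affected
#'   nodes.
#' @param affected_nodes 0-based node indices carrying the effect.
#' @param covariate_effects named numeric: mm per unit of `sex` (male = 1),
#'   `education` (years, centred), `tiv` (cm^3, centred).
#' @param noise_sd per-node Gaussian noise SD in mm.
#' @param symptom_latent_strength in `[0, 1]`: in-sample correlation between the
#'   latent symptom score and the thickness-by-age interaction among patients.
#' @param symptom_signal scale of the salience-weighted latent contribution to
#'   symptom items (item noise has SD 1).
#' @param seed integer RNG seed; sub-streams for demographics, thickness noise
#'   and symptoms are derived from it.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 151L, n_controls = 278L,
                          age_range = c(11, 42), crossover_age = 25,
                          effect_slope = 0.05, affected_nodes = 13:23,
                          covariate_effects = c(sex = 0.1, education = 0.01, tiv = 5e-4),
                          noise_sd = 0.5, symptom_latent_strength = 0.8,
                          symptom_signal = 2, seed = 1L) {
  n_cov <- 3L
  if (n_patients < n_cov + 3L || n_controls < n_cov + 3L)
    stop_invalid("each group needs at least %d subjects for the moderation model to be identifiable",
                 n_cov + 3L)
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop_invalid("age_range must be (low, high) with low < high")
  if (crossover_age <= age_range[1] || crossover_age >= age_range[2])
    stop_invalid("crossover_age must lie strictly inside age_range, else no sign change is observable")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop_invalid("noise_sd must be > 0")
  if (symptom_latent_strength < 0 || symptom_latent_strength > 1)
    stop_invalid("symptom_latent_strength must be in [0, 1]")
  if (length(affected_nodes) == 0L || any(affected_nodes < 0) || any(affected_nodes > 99))
    stop_invalid("affected_nodes must be a non-empty subset of 0..99")
  if (!all(c("sex", "education", "tiv") %in% names(covariate_effects)))
    stop_invalid("covariate_effects must name sex, education and tiv")
  structure(list(n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
                 age_range = age_range, crossover_age = crossover_age,
                 effect_slope = effect_slope, affected_nodes = as.integer(affected_nodes),
                 covariate_effects = covariate_effects, noise_sd = noise_sd,
                 symptom_latent_strength = symptom_latent_strength,
                 symptom_signal = symptom_signal, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a synthetic case-control cohort
#'
#' Generates a cohort table (demographics), a subjects-by-100-nodes thickness
#' matrix, a patient symptom table (30 PANSS-style items plus four factor
#' scores), and the generative truth. Ages are uniform over `age_range`, sex
#' is Bernoulli(0.5), education years are normal with group-specific means
#' (patients 11.27 +/- 2.81, controls 15.09 +/- 3.17) and intracranial volume
#' is normal (1446.47 +/- 123.79 cm^3) in both groups.
#'
#' Thickness at node j is `baseline[j] + covariate effects + group *
#' effect_slope * (age - crossover_age) * [j in affected_nodes] + N(0,
#' noise_sd^2)`. Patient symptoms are `item mean + symptom_signal * salience *
#' latent + N(0, 1)` where the latent score correlates with the in-sample
#' z(thickness) x z(age) interaction (region mean over affected nodes) at
#' exactly `symptom_latent_strength`.
#'
#' Identical configurations (including `seed`) give identical output; the
#' demographics, thickness-noise and symptom blocks use seeds derived from
#' `seed` so one block can change without perturbing the others.
#'
#' @param config a [cohort_config()].
#' @return list of class `cc_cohort`: `cohort` (data.frame), `thickness`
#'   (matrix, columns `node_00..node_99`), `symptoms` (data.frame, patients
#'   only), `truth` (list: `crossover_age`, `effect_slope`, `affected_nodes`,
#'   `theta_true` function of age, `u_design`, `v_items`, `latent_strength`).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  np <- config$n_patients; nc <- config$n_controls; n <- np + nc
  grp <- rep(c("patient", "control"), c(np, nc))

  set.seed(derive_seed(config$seed, "demographics"))
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(rbinom(n, 1L, 0.5) == 1L, "M", "F")
  education <- ifelse(grp == "patient",
                      rnorm(n, 11.27, 2.81), rnorm(n, 15.09, 3.17))
  education <- pmax(education, 1)
  tiv <- rnorm(n, 1446.47, 123.79)
  illness_duration <- ifelse(grp == "patient", runif(n, 0.1, 3), NA_real_)
  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = factor(grp, levels = c("control", "patient")),
    age = age, sex = sex, education = education, tiv = tiv,
    illness_duration = illness_duration,
    age_of_onset = age - illness_duration,
    stringsAsFactors = FALSE
  )

  set.seed(derive_seed(config$seed, "noise"))
  base <- cc_baseline_profile()
  ce <- config$covariate_effects
  subj_shift <- ce[["sex"]] * (sex == "M") +
    ce[["education"]] * (education - 13.5) +
    ce[["tiv"]] * (tiv - 1446.47)
  effect <- ifelse(grp == "patient",
                   config$effect_slope * (age - config$crossover_age), 0)
  aff <- config$affected_nodes + 1L
  thick <- matrix(rnorm(n * 100L, 0, config$noise_sd), n, 100L)
  thick <- thick + matrix(base, n, 100L, byrow = TRUE) + subj_shift
  thick[, aff] <- thick[, aff] + effect
  colnames(thick) <- sprintf("node_%02d", 0:99)
  rownames(thick) <- cohort$subject_id

  set.seed(derive_seed(config$seed, "symptoms"))
  pat <- which(grp == "patient")
  region_mean <- rowMeans(thick[pat, aff, drop = FALSE])
  inter <- as.numeric(scale(scale(region_mean) * scale(age[pat])))
  eta <- rnorm(np)
  # residualize so the in-sample correlation with the interaction is exact
  eta_perp <- eta - inter * sum(eta * inter) / sum(inter^2)
  eta_perp <- as.numeric(scale(eta_perp))
  rho <- config$symptom_latent_strength
  latent <- rho * inter + sqrt(1 - rho^2) * eta_perp
  v <- planted_salience()
  items <- panss_items()
  item_mean <- stats::setNames(rep(c(3, 3.5, 3), c(7, 7, 16)), items)
  sym <- outer(latent, config$symptom_signal * v) +
    matrix(rnorm(np * 30L), np, 30L) +
    matrix(item_mean, np, 30L, byrow = TRUE)
  colnames(sym) <- items
  fmap <- panss_factor_map()
  factors <- vapply(fmap, function(it) rowMeans(sym[, it, drop = FALSE]),
                    numeric(np))
  symptoms <- data.frame(subject_id = cohort$subject_id[pat], sym, factors,
                         stringsAsFactors = FALSE, check.names = FALSE)

  truth <- list(
    crossover_age = config$crossover_age,
    effect_slope = config$effect_slope,
    affected_nodes = config$affected_nodes,
    theta_true = function(a) config$effect_slope * (a - config$crossover_age),
    u_design = c(thickness = 0, age = 0, interaction = 1),
    v_items = v,
    latent_strength = rho
  )
  structure(list(cohort = cohort, thickness = thick, symptoms = symptoms,
                 truth = truth, config = config),
            class = "cc_cohort")
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat(sprintf("<cc_cohort> %d patients + %d controls; planted crossover %.1f y (slope %.3g mm/y) on %d nodes; latent strength %.2f\n",
              x$config$n_patients, x$config$n_controls, x$config$crossover_age,
              x$config$effect_slope, length(x$config$affected_nodes),
              x$config$symptom_latent_strength))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Writes `cohort.csv`, `thickness.csv` (subject_id + node_00..node_99) and
#' `symptoms.csv` into `dir`.
#'
#' @param sim a `cc_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sim$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  th <- data.frame(subject_id = rownames(sim$thickness), sim$thickness,
                   stringsAsFactors = FALSE)
  write.csv(th, file.path(dir, "thickness.csv"), row.names = FALSE)
  write.csv(sim$symptoms, file.path(dir, "symptoms.csv"), row.names = FALSE)
  invisible(dir)
}
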