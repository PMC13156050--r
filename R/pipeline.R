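# End-to-end orchestration: simulate (or load) -> demographics -> pointwise
# scan -> region aggregation and region-level JN -> per-region PLSC with
# permutation, bootstrap and symptom JN follow-up -> CSV/JSON report.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Default pipeline configuration
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param alpha significance / FDR level.
#' @param n_perm,n_boot PLSC permutation and bootstrap iterations.
#' @param covariates nuisance covariates for the thickness scan.
#' @param cohort a [cohort_config()] used when simulating.
#' @param cohort_dir directory with `cohort.csv` / `thickness.csv` /
#'   `symptoms.csv` to analyse instead of simulating (overrides `cohort`).
#' @param run_plsc run the PLSC stage (requires symptom data).
#' @return a config list.
#' @export
pipeline_config <- function(seed = 1L, alpha = 0.05, n_perm = 1000L,
                            n_boot = 500L,
                            covariates = c("sex", "education", "tiv"),
                            cohort = NULL, cohort_dir = NULL,
                            run_plsc = TRUE) {
  list(seed = as.integer(seed), alpha = alpha, n_perm = as.integer(n_perm),
       n_boot = as.integer(n_boot), covariates = covariates,
       cohort = cohort %||% cohort_config(seed = seed),
       cohort_dir = cohort_dir, run_plsc = isTRUE(run_plsc))
}

load_cohort_dir <- function(dir) {
  need <- file.path(dir, c("cohort.csv", "thickness.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop_invalid("missing input file(s): %s", paste(miss, collapse = ", "))
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  cohort$group <- factor(cohort$group, levels = c("control", "patient"))
  th <- utils::read.csv(file.path(dir, "thickness.csv"), stringsAsFactors = FALSE)
  thick <- as.matrix(th[, grep("^node_", names(th)), drop = FALSE])
  rownames(thick) <- th$subject_id
  sym_path <- file.path(dir, "symptoms.csv")
  symptoms <- if (file.exists(sym_path))
    utils::read.csv(sym_path, stringsAsFactors = FALSE, check.names = FALSE) else NULL
  list(cohort = cohort, thickness = thick, symptoms = symptoms)
}

#' Run the full analysis pipeline
#'
#' Executes the complete study replica on a simulated (or supplied) cohort and
#' writes every stage's tables plus a JSON report and run manifest under
#' `out_dir`. Deterministic given the seed: rerunning with the same
#' configuration reproduces the output byte for byte.
#'
#' Stages: cohort (simulate or load), demographics, pointwise interaction scan
#' with FDR, region aggregation + region-level Johnson-Neyman analysis, and —
#' when symptom data are present and `run_plsc` is TRUE — per-region PLSC with
#' permutation p-values, FDR across the four regions, bootstrap ratios and the
#' symptom-level JN follow-up.
#'
#' @param config list from [pipeline_config()] or a path to a YAML file with
#'   the same fields.
#' @param out_dir output directory.
#' @return (invisibly) a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    cfg_raw <- yaml::read_yaml(config)
    cohort_cfg <- if (!is.null(cfg_raw$cohort)) do.call(cohort_config, cfg_raw$cohort)
    config <- do.call(pipeline_config,
                      c(cfg_raw[setdiff(names(cfg_raw), "cohort")],
                        if (!is.null(cohort_cfg)) list(cohort = cohort_cfg)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dat <- run_stage("cohort", {
    if (!is.null(config$cohort_dir)) load_cohort_dir(config$cohort_dir)
    else {
      sim <- simulate_cohort(config$cohort)
      list(cohort = sim$cohort, thickness = sim$thickness,
           symptoms = sim$symptoms, truth = sim$truth)
    }
  })
  write.csv(dat$cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  write.csv(data.frame(subject_id = rownames(dat$thickness), dat$thickness),
            file.path(out_dir, "thickness.csv"), row.names = FALSE)
  if (!is.null(dat$symptoms))
    write.csv(dat$symptoms, file.path(out_dir, "symptoms.csv"), row.names = FALSE)

  demo <- run_stage("demographics", demographics(cohort = dat$cohort))
  write.csv(demo, file.path(out_dir, "demographics.csv"), row.names = FALSE)

  scan <- run_stage("scan",
                    pointwise_scan(dat$thickness, dat$cohort, alpha = config$alpha,
                                   covariates = config$covariates))
  write.csv(scan, file.path(out_dir, "scan.csv"), row.names = FALSE)

  regions <- witelson_regions()
  region_means <- run_stage("regions", aggregate_regions(dat$thickness, regions))
  write.csv(data.frame(subject_id = rownames(region_means), region_means,
                       check.names = FALSE),
            file.path(out_dir, "region_means.csv"), row.names = FALSE)

  covs <- dat$cohort[, config$covariates, drop = FALSE]
  region_jn <- run_stage("region_jn", lapply(seq_len(nrow(regions)), function(i) {
    fit <- fit_moderation(region_means[, i], dat$cohort$group, dat$cohort$age, covs)
    jn <- jn_boundaries(fit, alpha = config$alpha)
    list(region = regions$region[i], fit = fit, jn = jn,
         crossover = crossover_age(fit))
  }))
  jn_tab <- do.call(rbind, lapply(region_jn, function(r) {
    data.frame(region = r$region, crossover = r$crossover,
               n_boundaries = length(r$jn$boundaries),
               lower_boundary = if (length(r$jn$boundaries)) min(r$jn$boundaries) else NA,
               upper_boundary = if (length(r$jn$boundaries) > 1) max(r$jn$boundaries) else NA)
  }))
  write.csv(jn_tab, file.path(out_dir, "region_jn.csv"), row.names = FALSE)

  plsc_res <- NULL
  if (config$run_plsc) {
    if (is.null(dat$symptoms))
      stop("pipeline stage 'plsc' failed: no symptom table available", call. = FALSE)
    plsc_res <- run_stage("plsc", {
      pat <- dat$cohort$group == "patient"
      pat_ids <- dat$cohort$subject_id[pat]
      sy <- dat$symptoms[match(pat_ids, dat$symptoms$subject_id), , drop = FALSE]
      lapply(seq_len(nrow(regions)), function(i) {
        inp <- plsc_inputs(region_means[pat, i], dat$cohort$age[pat], sy)
        mod <- plsc_fit(inp)
        pperm <- plsc_permutation(inp, n_perm = config$n_perm,
                                  seed = config$seed + i)
        boot <- plsc_bootstrap(inp, n_boot = config$n_boot,
                               seed = config$seed + i)
        scores <- behavior_scores(inp$Y, mod$V)
        sjn <- symptom_jn(scores[, 1], inp$thickness_raw, inp$age_raw)
        list(region = regions$region[i], inputs = inp, model = mod,
             p_perm = pperm, bootstrap = boot, scores = scores, symptom_jn = sjn)
      })
    })
    p_lv1 <- vapply(plsc_res, function(r) r$p_perm[1], numeric(1))
    q_lv1 <- fdr_across_regions(p_lv1)
    plsc_tab <- data.frame(
      region = regions$region, p_lv1 = p_lv1, q_lv1 = q_lv1,
      s1 = vapply(plsc_res, function(r) r$model$S[1], numeric(1)),
      n_sig_items = vapply(plsc_res, function(r) sum(r$bootstrap$sig_v[, 1]), numeric(1)),
      sjn_boundaries = vapply(plsc_res, function(r)
        paste(sprintf("%.2f", r$symptom_jn$jn$boundaries), collapse = ";"), character(1))
    )
    write.csv(plsc_tab, file.path(out_dir, "plsc.csv"), row.names = FALSE)
    for (i in seq_along(plsc_res)) plsc_res[[i]]$q_lv1 <- q_lv1[i]
  }

  report <- list(
    demographics = demo,
    n_significant_nodes = sum(scan$significant),
    significant_nodes = scan$node[scan$significant],
    region_jn = jn_tab,
    plsc = if (!is.null(plsc_res)) data.frame(
      region = regions$region,
      p_lv1 = vapply(plsc_res, function(r) r$p_perm[1], numeric(1)),
      q_lv1 = vapply(plsc_res, function(r) r$q_lv1, numeric(1)))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "callothick",
    version = as.character(packageVersion("callothick")),
    seed = config$seed,
    alpha = config$alpha, n_perm = config$n_perm, n_boot = config$n_boot,
    covariates = config$covariates,
    cohort = if (is.null(config$cohort_dir))
      unclass(config$cohort)[c("n_patients", "n_controls", "age_range",
                               "crossover_age", "effect_slope", "affected_nodes",
                               "noise_sd", "symptom_latent_strength", "seed")]
      else list(cohort_dir = config$cohort_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = out_dir, demographics = demo, scan = scan,
                 region_means = region_means, region_jn = region_jn,
                 plsc = plsc_res, report = report))
}
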