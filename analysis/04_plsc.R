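#!/usr/bin/env Rscript
# Stage 4 -- partial least squares correlation between the [thickness, age,
# interaction] design and the PANSS-style symptom block, per Witelson region,
# with permutation inference, FDR across the four regions, bootstrap ratios
# and the symptom-level Johnson-Neyman follow-up.

library(callothick)

dir.create("results/plsc", recursive = TRUE, showWarnings = FALSE)
sim <- simulate_cohort(cohort_config(seed = 1))
pat <- sim$cohort$group == "patient"
region_means <- aggregate_regions(sim$thickness)

res <- list()
for (i in seq_len(4)) {
  rg <- colnames(region_means)[i]
  inp <- plsc_inputs(region_means[pat, rg], sim$cohort$age[pat], sim$symptoms)
  mod <- plsc_fit(inp)
  p <- plsc_permutation(inp, n_perm = 2000, seed = 100 + i)
  bt <- plsc_bootstrap(inp, n_boot = 1000, seed = 100 + i)
  scores <- behavior_scores(inp$Y, mod$V)
  sjn <- symptom_jn(scores[, 1], inp$thickness_raw, inp$age_raw)
  res[[rg]] <- list(inp = inp, mod = mod, p = p, bt = bt, sjn = sjn)
  cat(sprintf("\nRegion %s: S1 = %.3f, perm p(LV1) = %.4f\n", rg, mod$S[1], p[1]))
  sig_items <- rownames(bt$bsr_v)[bt$sig_v[, 1]]
  cat(sprintf("  |BSR| > 2 symptom elements: %s\n",
              if (length(sig_items)) paste(sig_items, collapse = ", ") else "none"))
  if (length(sjn$jn$boundaries))
    cat(sprintf("  symptom JN boundaries: %s y\n",
                paste(sprintf("%.2f", sjn$jn$boundaries), collapse = ", ")))
}

p_lv1 <- vapply(res, function(r) r$p[1], numeric(1))
q_lv1 <- fdr_across_regions(p_lv1)
tab <- data.frame(region = names(res), p_lv1 = p_lv1, q_lv1 = q_lv1,
                  s1 = vapply(res, function(r) r$mod$S[1], numeric(1)),
                  u_interaction = vapply(res, function(r) r$mod$U[3, 1], numeric(1)))
write.csv(tab, "results/plsc/region_plsc.csv", row.names = FALSE)
cat("\nFDR across regions (LV1):\n"); print(tab, row.names = FALSE)

# salience table for the region carrying the planted effect
bsr_iv <- res[["IV"]]$bt$bsr_v[, 1]
write.csv(data.frame(element = names(bsr_iv), bsr = bsr_iv,
                     significant = abs(bsr_iv) > 2),
          "results/plsc/region_IV_bsr.csv", row.names = FALSE)
cat("\nThe planted salience loads on G1, G2, G3, G6 (+) and N7 (-); region IV\n")
cat("should recover exactly this pattern plus the affective factor column.\n")
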