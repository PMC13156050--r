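---
title: "Callosal thickness profiling and age-moderated group analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Callosal thickness profiling and age-moderated group analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callothick)
```

# The scientific problem

Morphometric studies of the corpus callosum (CC) in schizophrenia disagree:
some cohorts show a thinner callosum in patients, others a thicker one. One
resolution is that the group difference is *age-dependent* — negative in
adolescence, positive in adulthood — so that a cohort's mean age decides the
sign it observes. Testing that hypothesis needs three ingredients, which this
package implements end to end:

1. a **high-resolution thickness profile** of the midsagittal CC (100 nodes
   along its arch) from a binary mask;
2. a **moderation analysis** with the Johnson–Neyman (JN) technique, which
   identifies the exact ages at which the group effect on thickness becomes
   significant, instead of probing a few hand-picked ages;
3. a **brain–symptom analysis** by partial least squares correlation (PLSC)
   with permutation and bootstrap inference.

Because no subject-level data are distributable, the package ships a
synthetic-cohort generator whose planted effects make every stage verifiable
by parameter recovery.

# Thickness model

## Laplace midline and streamlines

The mask's outer boundary is traced and split at its two *bottommost
extremities* — the lowest boundary pixel in the posterior third of the
bounding box and the lowest in the anterior third (ties broken towards the
respective extremity) — into a **superior** and an **inferior** contour. The
potential \(u\) solves Laplace's equation on the interior,

\[ \nabla^2 u = 0,\qquad u|_{\text{inferior}} = 0,\quad u|_{\text{superior}} = 1 , \]

discretized with the 5-point stencil and relaxed by red–black successive
over-relaxation (SOR). Convergence is declared when the maximum interior
residual falls below `tol` (default \(10^{-6}\)); the iteration cap scales
with the grid (`100 * max(dim)`), and non-convergence is an error carrying
the final residual — there is no silent fallback.

The **midline** is the ordered 0.5 level set of \(u\) (extracted with
marching-squares contouring and trimmed to the mask). It is resampled at 100
stations placed at the midpoints of 100 equal-arclength bins — a half-open
station rule, so no station sits exactly on a tip. From each station the
normalized gradient \(\pm\nabla u/\lVert\nabla u\rVert\) is integrated with
fixed-step RK2 (step 0.25 px, bilinear gradient interpolation) towards each
contour; **thickness is the summed length of the two traces**. Node 0 is
posterior; mirroring a mask left–right reverses the profile.

Thickness is deliberately the *streamline length*, not the chord between the
two intersection points: in high-curvature zones (genu, splenium) streamlines
are curved so the two definitions differ, and the streamline length is the
quantity the Laplace model actually defines. This is a known interpretive
caveat of the model, not an implementation detail.

## Numerical choices and why they matter

* **Sub-pixel termination.** Traces end where a Gaussian-smoothed mask
  indicator (\(\sigma = 2.5\) px, radius \(\lceil 3.2\sigma\rceil\)) crosses
  0.5, with the final partial step linearly interpolated. Terminating at
  boundary-*pixel centres* instead would bias every node by about one pixel
  (≈ 6 % at 0.25 mm on a 4 mm structure). The smoothing width is a plateau
  choice: wide enough to average the staircase quantization of a pixelated
  edge, while keeping the kernel's \(3\sigma\) reach below the thinnest
  validated cross-section (8 px), so opposite edges never interact. The
  curvature bias of a smoothed circular edge, \(\sigma^2\kappa/2\), is below
  0.1 px for all radii of interest.
* **Open (no-flux) end faces.** Validation fixtures are blunt: a rectangle
  band ends in vertical side walls, an annular arch in flat feet. Holding
  those lateral faces at a Dirichlet value would bend the equipotentials into
  the corners and collapse the end-node thickness, contradicting the closed
  forms the fixtures are built to test (linear potential in the band,
  \(\ln(r/r_1)/\ln(r_2/r_1)\) in the arch). The faces are therefore detected
  — a walk from each endpoint to the first sharp outline corner (turning
  angle ≥ 60° over a ±2 px chord window) — and left *free*: their stencil
  averages over foreground neighbours only, which is a homogeneous Neumann
  condition. For the termination indicator the mask is extruded through each
  face (tangential continuation, equivalent to mirror symmetry) so corner
  rounding cannot contaminate the end nodes. Anatomical masks taper to
  smooth tips without sharp corners, so both rules are inert on them.
* **Recovery achieved.** With these choices the band (6 mm) and the arch
  (4 mm) are recovered at 0.25 mm pixels with maximum node errors of about
  0.06 % and 1.1 %; at 0.5 mm, 0.4 % and 1.8 %. Errors shrink monotonically
  with pixel size, and 0.5 mm vs 0.25 mm profiles agree node-wise within 2 %.
* **Orientation equivariance** holds to ≈ \(10^{-6}\) mm rather than
  bit-exactly: red–black sweep colouring is not mirror-invariant for
  even-width grids, so the SOR iterates differ at the convergence tolerance.

# Moderation and the Johnson–Neyman solution

Per node (or region mean) the model is

\[ y = b_0 + b_1 x + b_2 m + b_3 (x\,m) + \gamma^\top c + \varepsilon , \]

with \(x\) the group indicator (0 = control, 1 = patient, so \(\theta > 0\)
means patients thicker), \(m\) age in years (uncentred — boundaries are then
on the raw year scale; centring would change \(b_1\)'s meaning but not the JN
solution), and \(c\) the nuisance covariates (sex, education years, total
intracranial volume; a sensitivity set swaps in illness duration and age of
onset). The conditional effect and its variance are

\[ \theta(m) = b_1 + b_3 m, \qquad
   \operatorname{Var}\,\theta(m) = v_{11} + 2 m\, v_{13} + m^2 v_{33} , \]

and the JN boundaries are the real roots of

\[ (t_c^2 v_{33} - b_3^2)\, m^2 + 2 (t_c^2 v_{13} - b_1 b_3)\, m +
   (t_c^2 v_{11} - b_1^2) = 0 \]

inside the observed age range, with \(t_c\) the two-tailed critical value at
the fit's own residual df. The quadratic is solved in the numerically stable
form (no catastrophic cancellation between \(-B\) and \(\sqrt{B^2-4AC}\));
a vanishing leading coefficient falls back to the linear root. Every fitted
model is cross-checked in the test suite against a brute-force scan of
\(|t(m)| - t_c\) sign changes on a 0.001-year grid.

The pointwise scan fits all 100 nodes through one multi-response
least-squares decomposition (identical, to numerical precision, to 100
separate fits — asserted in the tests) and applies **Benjamini–Hochberg**
FDR across the 100 interaction p-values. FDR is applied to the node-wise
interaction tests only; the conditional-effect p-values inside a JN curve
are a description of one fitted model and are not additionally corrected.
The region-level follow-up (means over the Witelson-anchored windows
I = 73–78, II = 51–72, III = 24–32, IV = 13–23) reports both raw and
FDR-adjusted versions where four parallel tests occur.

# PLSC

For each region, patients only: \(X = [\text{thickness}, \text{age},
\text{thickness} \times \text{age}]\) (interaction built from z-scored
components before the final z-scoring, which bounds its collinearity with
the main effects) and \(Y\) = 30 PANSS-style items plus the four factor
scores, z-scored by default (a `scale_y = FALSE` flag keeps raw scales). The
cross-block matrix \(R = X^\top Y/(n-1)\) — correlation-scaled; the scale
cancels in permutation p-values and bootstrap ratios — is decomposed as
\(R = U S V^\top\), with signs fixed by making the largest-magnitude element
of each design salience positive. Behaviour scores are the projection of
\(Y\) on its saliences.

*Permutation:* rows of \(Y\) are permuted and the k-th permuted singular
value is compared with the k-th observed one, with the add-one rule (p is
never exactly zero). Comparing instead against the permutation distribution
of the *largest* singular value is available via `mode = "max"`; the per-LV
null is the default because it is the simplest defensible reading of testing
"all singular values collectively", and the choice is explicit in the API.

*Bootstrap:* patients are resampled with replacement, blocks re-standardized
within each resample, the model refit, and each LV sign-aligned to the
observed saliences (reflection is the only indeterminacy that matters at the
planted rank; full Procrustes alignment is not implemented). BSR = observed
salience / bootstrap SE, with \(|\text{BSR}| > 2\) as the conventional mask.

# The synthetic cohort: what it emulates and what it does not

Defaults mirror the reference study conditions: 151 patients / 278 controls,
ages uniform on 11–42 y, education 11.27 ± 2.81 y (patients) vs
15.09 ± 3.17 y (controls), TIV 1446.47 ± 123.79 cm³, covariate effects of
0.1 mm (male sex), 0.01 mm/y (education) and 5·10⁻⁴ mm/cm³ (TIV) on
thickness. The baseline profile is a fixed smooth template (thick splenium
and genu, thinner isthmus, tapering ends; 3–8 mm). The planted group effect
is `effect_slope * (age - crossover_age)` on the affected nodes (defaults:
0.05 mm/y, crossover 25 y, splenium window 13–23); the published analysis
reports no effect sizes in mm, so the slope and the 0.5 mm node noise are
fixture choices giving realistic single-node t-statistics at the study's
sample size, chosen once and documented here. Patient symptoms carry a
rank-1 latent: a unit-norm salience over G1, G2, G3, G6 (positive) and N7
(negative), scaled by 2 relative to unit item noise, driven by a latent score
whose in-sample correlation with the z(thickness)·z(age) interaction is
exactly `symptom_latent_strength` (0.8 by default; factors are uniform-weight
means of fixed item sets, since published factor loadings are unavailable).

One RNG stream per purpose (demographics / node noise / symptoms) is derived
from the single seed, so changing one block leaves the others untouched.

What passing tests show: the implementation recovers planted crossovers,
saliences and null calibration under Gaussian node noise with a linear age
trend. What they cannot show: robustness to segmentation artefacts,
non-linear maturation, site effects, or non-Gaussian symptom scales — none
of which the generator emulates, by design (`Non-goals`).

# Calibration and recovery results the suite computes

* Null cohorts (zero slope): the pointwise scan flags ≈ 5 % of nodes before
  FDR (within binomial 99 % bounds over 200 replicates × 100 nodes) and
  essentially none after; PLSC LV1 permutation p is uniform (KS test) over
  100 replicate null cohorts at 500 permutations.
* Planted crossover at 25.0 y, n = 400: the mean estimated crossover over
  100 replicates lands within 0.05 y of the truth (tolerance 0.5 y).
* Planted rank-1 covariance (strength 0.8, n = 137): mean
  \(|\langle U_1, u_{\text{true}}\rangle| \approx 0.97\) and permutation
  power ≈ 100 % at 500 permutations.

The problem sizes above (replicate counts, permutation counts, 0.25 mm
validation grids) are the package's validation design: large enough for the
binomial/KS bounds quoted, small enough to run comfortably on a laptop.

# Demographics

Continuous variables use a two-sample t-test; the unequal-variance (Welch)
form is selected when the larger-to-smaller sample-variance ratio reaches
1.3, the pooled form otherwise, and the same code path serves raw rows and
printed summaries. The 1.3 gate is the smallest round threshold that
reproduces the reference table's own apparent convention (age row Welch at
ratio 1.36; education row pooled at ratio 1.27; TIV pooled at 1.06); it is a
documented inference from the printed statistics, not a reported choice, and
it is configurable. Sex uses Pearson's chi-square without continuity
correction, which reproduces the printed χ² = 1.534 exactly.

# Known limitations

* The thickness stage starts from a supplied 2-D binary mask; mid-sagittal
  plane identification, template segmentation, topology repair and vessel
  exclusion are upstream, out of scope.
* Streamline length over-reads "thickness" where the midline curvature is
  high relative to local thickness (genu/splenium caveat above).
* The JN model is linear in age; non-linear maturation would need spline or
  mixed-effects extensions (deliberately out of scope).
* Blunt-end handling (open faces) is designed for validation fixtures;
  segmentations with genuinely sharp 90° corners at a tapering tip would
  have a few boundary pixels reclassified as no-flux, a local O(h) effect.
* PLSC bootstrap alignment is sign-only; with closely spaced singular values
  LV rotation (not just reflection) could inflate bootstrap SEs — BSRs are
  then conservative.
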