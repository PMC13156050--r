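Package: callothick
Title: Corpus Callosum Thickness Profiles and Age-Moderated Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streamline-based thickness profiling of the corpus callosum from
    2-D binary midsagittal masks, together with the statistical pipeline used
    to study age-dependent group differences in thickness. The midline of the
    callosum is modelled as an equipotential of Laplace's equation between the
    superior and inferior boundaries, and 100 orthogonal streamlines yield a
    node-wise thickness profile. Group-by-age moderation is analysed with the
    Johnson-Neyman technique and Benjamini-Hochberg FDR control over the
    pointwise scan, significant nodes are aggregated into Witelson-anchored
    subregions, and brain-symptom coupling is assessed by partial least
    squares correlation with permutation and bootstrap inference. A synthetic
    cohort generator with planted crossover interactions and latent
    brain-symptom covariance makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
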