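Package: camroad
Title: Layer-Wise Class Activation Maps and ROAD Faithfulness Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end, layer-wise class activation mapping (CAM) for
    image classifiers, paired with a per-layer quantitative faithfulness
    series built on the combined Remove-and-Debias (ROAD) perturbation
    metric with noisy linear imputation. Computes CAMs at every spatial
    layer of a network under eleven weighting schemes (GradCAM, GradCAM++,
    XGradCAM, HiResCAM, element-wise and layer-wise variants, EigenCAM,
    EigenGradCAM, ScoreCAM, AblationCAM, RandomCAM), normalizes them
    locally (per layer) or globally (across all layers), renders heatmap
    overlays and animations, and scores each layer by the change in class
    confidence after imputing least- versus most-relevant pixels. The
    per-layer ROAD series ("yellow brick ROAD", ybROAD) identifies the
    most faithful explanatory layer. Ships a compact, exactly
    differentiated CNN engine and a synthetic two-class lesion-image
    generator (speckle background, elliptical lesions with ground-truth
    masks) so the whole pipeline is testable end to end, plus
    parameter-census profiles of standard image-classification
    architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
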