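# camroad

Layer-wise class activation maps (CAMs) with a per-layer quantitative
faithfulness series for image classifiers.

## The problem

CAM methods explain an image classifier's prediction by weighting a layer's
channel activation maps into a single heatmap,

```
L^c(A^l) = ReLU( sum_k  alpha^c_k  A^l_k ),     A^l = f^l(x)
```

but in practice only one arbitrarily chosen late layer is ever visualized,
and nothing says it is the *right* layer. `camroad` computes the CAM at
**every** spatial layer `l = 0..N` of a network, renders the sequence as an
animation (locally normalized per layer, or globally normalized across all
layers so attenuated layers stay visibly attenuated), and scores every
frame with the combined Remove-and-Debias (ROAD) perturbation metric:

```
ROAD(L^c(A^l)) = mean_p ( C_LRP(p) - C_MRP(p) ) / 2
```

where `C` is the change in post-softmax target confidence after replacing a
fraction `p` (20/40/60/80 %) of the least- or most-relevant pixels by noisy
linear imputation (each imputed pixel solves a sparse neighbor-mean linear
system, plus small seeded Gaussian noise). The per-layer series — the
"yellow brick ROAD", ybROAD — and its `max`/`mean` summaries identify the
most faithful explanatory layer, turning layer choice from a convention
into a measurement. It is aimed at people auditing CNN classifiers —
particularly medical-imaging models, where the explanation matters as much
as the label.

The package is self-contained: it ships a compact, exactly differentiated
CNN engine, a synthetic lesion-image generator (speckled ultrasound-like
background, elliptical lesions with ground-truth masks) and a small
trainable CNN, so the full pipeline runs and is tested without any
download, plus parameter-census profiles of eight standard architectures
(AlexNet, SqueezeNet-1.0, DenseNet161, ResNet50/152, ConvNeXt-Base,
EfficientNet-B7, MaxViT-T).

## Worked example

```r
library(camroad)

split <- make_dataset(n = 400, contrast = 0.4, seed = 1)   # 80-10-10 split
fit   <- train_fixture(make_tiny_cnn(seed = 1), split, epochs = 10, seed = 1)
fit$test_accuracy
#> [1] 1

img <- Filter(function(s) s$label == 1, split$test)[[1]]$image
yb  <- ybroad(fit$model, img, scheme = "gradcam", target = 2,
              config = road_config(seed = 1))
yb
#> <ybroad_series> tiny_cnn, gradcam, class 2: 12 layers; mean 0.4054,
#>   max 0.4857 at layer 4 (conv2)
```

The 12 scored layers are the model's `spatial2d` layers (1-D layers such as
the pooled features and the classifier head are filtered out). A mean
combined score of 0.41 says that, averaged over layers, imputing the pixels
the maps call relevant costs the model far more confidence than imputing
the pixels they call irrelevant; the argmax layer (here `conv2`) is the
single most faithful frame to show a reader. `tidy(yb)` returns the
per-layer tibble,
`glance(yb)` the one-row summary and `autoplot(yb)` the series plot.

Render the animation and run everything end to end:

```r
cfg <- run_config(model = fit$model, image = img, scheme = "gradcam",
                  normalization = "both", out_dir = "run1", seed = 1)
run_animate(cfg)   # frames/, animation_local + animation_global, index CSV
run_ybroad(cfg)    # ybroad.csv, ybroad_summary.json, best_layer.png
```

Profile a benchmark architecture:

```r
profile("alexnet")
#> <model_profile> alexnet: 61,100,840 parameters across 8 target layers
```

A thin CLI wraps the same functions:
`Rscript inst/scripts/camroad.R animate --config run.yaml`.

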