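# Parameter-census generators for standard image-classification
# architectures. Each generator enumerates the parameter-bearing leaf modules
# of the published 1000-class ImageNet architecture definition and attributes
# an exact parameter count to each, so that profiles (total and per-layer
# counts) are reproducible without instantiating any weights.
#
# Conventions mirror the reference implementations: convolutions followed by
# a normalization layer carry no bias; squeeze-excitation convolutions and
# stand-alone convolutions do; batch-norm and layer-norm contribute 2*C.

.zoo_env <- new.env(parent = emptyenv())

zl <- function(name, count, shape = "spatial2d", kind = "conv") {
  list(name = name, param_count = as.numeric(count), shape_class = shape,
       kind = kind)
}

zoo_conv <- function(name, cin, cout, k, bias = TRUE, groups = 1L,
                     shape = "spatial2d") {
  zl(name, (cin / groups) * k * k * cout + if (bias) cout else 0,
     shape, "conv2d")
}
zoo_bn <- function(name, ch, shape = "spatial2d") zl(name, 2 * ch, shape, "batchnorm2d")
zoo_ln <- function(name, ch, shape = "spatial2d") zl(name, 2 * ch, shape, "layernorm")
zoo_fc <- function(name, cin, cout, bias = TRUE) {
  zl(name, cin * cout + if (bias) cout else 0, "vector1d", "linear")
}

## ---- individual architectures ---------------------------------------------

.zoo_env$alexnet <- function() {
  c(list(
    zoo_conv("features.0", 3, 64, 11),
    zoo_conv("features.3", 64, 192, 5),
    zoo_conv("features.6", 192, 384, 3),
    zoo_conv("features.8", 384, 256, 3),
    zoo_conv("features.10", 256, 256, 3)),
    list(
    zoo_fc("classifier.1", 256 * 6 * 6, 4096),
    zoo_fc("classifier.4", 4096, 4096),
    zoo_fc("classifier.6", 4096, 1000)))
}

.zoo_env$squeezenet1_0 <- function() {
  fire <- function(id, cin, s, e) {
    list(zoo_conv(paste0(id, ".squeeze"), cin, s, 1),
         zoo_conv(paste0(id, ".expand1x1"), s, e, 1),
         zoo_conv(paste0(id, ".expand3x3"), s, e, 3))
  }
  c(list(zoo_conv("features.0", 3, 96, 7)),
    fire("features.3", 96, 16, 64),
    fire("features.4", 128, 16, 64),
    fire("features.5", 128, 32, 128),
    fire("features.7", 256, 32, 128),
    fire("features.8", 256, 48, 192),
    fire("features.9", 384, 48, 192),
    fire("features.10", 384, 64, 256),
    fire("features.12", 512, 64, 256),
    list(zoo_conv("classifier.1", 512, 1000, 1)))
}

.zoo_env$densenet161 <- function() {
  growth <- 48L; bn_size <- 4L
  layers <- list(
    zoo_conv("features.conv0", 3, 96, 7, bias = FALSE),
    zoo_bn("features.norm0", 96))
  nin <- 96L
  blocks <- c(6L, 12L, 36L, 24L)
  for (b in seq_along(blocks)) {
    for (i in seq_len(blocks[b])) {
      id <- sprintf("features.denseblock%d.denselayer%d", b, i)
      mid <- bn_size * growth
      layers <- c(layers, list(
        zoo_bn(paste0(id, ".norm1"), nin),
        zoo_conv(paste0(id, ".conv1"), nin, mid, 1, bias = FALSE),
        zoo_bn(paste0(id, ".norm2"), mid),
        zoo_conv(paste0(id, ".conv2"), mid, growth, 3, bias = FALSE)))
      nin <- nin + growth
    }
    if (b < length(blocks)) {
      id <- sprintf("features.transition%d", b)
      layers <- c(layers, list(
        zoo_bn(paste0(id, ".norm"), nin),
        zoo_conv(paste0(id, ".conv"), nin, nin %/% 2L, 1, bias = FALSE)))
      nin <- nin %/% 2L
    }
  }
  c(layers, list(zoo_bn("features.norm5", nin),
                 zoo_fc("classifier", nin, 1000)))
}

zoo_resnet_bottleneck <- function(layers_per_stage) {
  out <- list(
    zoo_conv("conv1", 3, 64, 7, bias = FALSE),
    zoo_bn("bn1", 64))
  nin <- 64L
  widths <- c(64L, 128L, 256L, 512L)
  for (s in seq_along(widths)) {
    w <- widths[s]
    for (i in seq_len(layers_per_stage[s])) {
      id <- sprintf("layer%d.%d", s, i - 1L)
      out <- c(out, list(
        zoo_conv(paste0(id, ".conv1"), nin, w, 1, bias = FALSE),
        zoo_bn(paste0(id, ".bn1"), w),
        zoo_conv(paste0(id, ".conv2"), w, w, 3, bias = FALSE),
        zoo_bn(paste0(id, ".bn2"), w),
        zoo_conv(paste0(id, ".conv3"), w, 4L * w, 1, bias = FALSE),
        zoo_bn(paste0(id, ".bn3"), 4L * w)))
      if (i == 1L) {
        out <- c(out, list(
          zoo_conv(paste0(id, ".downsample.0"), nin, 4L * w, 1, bias = FALSE),
          zoo_bn(paste0(id, ".downsample.1"), 4L * w)))
      }
      nin <- 4L * w
    }
  }
  c(out, list(zoo_fc("fc", 2048, 1000)))
}

.zoo_env$resnet50 <- function() zoo_resnet_bottleneck(c(3L, 4L, 6L, 3L))
.zoo_env$resnet152 <- function() zoo_resnet_bottleneck(c(3L, 8L, 36L, 3L))

.zoo_env$convnext_base <- function() {
  dims <- c(128L, 256L, 512L, 1024L)
  depths <- c(3L, 3L, 27L, 3L)
  layers <- list(
    zoo_conv("features.0.0", 3, dims[1], 4),
    zoo_ln("features.0.1", dims[1]))
  for (s in seq_len(4L)) {
    d <- dims[s]
    for (i in seq_len(depths[s])) {
      id <- sprintf("features.%d.%d.block", 2L * s - 1L, i - 1L)
      layers <- c(layers, list(
        zoo_conv(paste0(id, ".0"), d, d, 7, groups = d),    # depthwise
        zoo_ln(paste0(id, ".2"), d),
        zoo_fc(paste0(id, ".3"), d, 4L * d),                # pointwise mlp
        zoo_fc(paste0(id, ".5"), 4L * d, d),
        zl(paste0(id, ".layer_scale"), d, "spatial2d", "scale")))
    }
    if (s < 4L) {
      id <- sprintf("features.%d", 2L * s)
      layers <- c(layers, list(
        zoo_ln(paste0(id, ".0"), d),
        zoo_conv(paste0(id, ".1"), d, dims[s + 1L], 2)))
    }
  }
  c(layers, list(zoo_ln("classifier.0", 1024, shape = "vector1d"),
                 zoo_fc("classifier.2", 1024, 1000)))
}

.zoo_env$efficientnet_b7 <- function() {
  # compound-scaled from the baseline configuration: width x2.0 (divisor 8),
  # depth x3.1 (ceil); squeeze channels = input channels %/% 4
  stem <- 64L; head <- 2560L
  cfg <- list( # expand, kernel, in, out, repeats (already scaled)
    list(e = 1L, k = 3L, cin = 64L,  cout = 32L,  n = 4L),
    list(e = 6L, k = 3L, cin = 32L,  cout = 48L,  n = 7L),
    list(e = 6L, k = 5L, cin = 48L,  cout = 80L,  n = 7L),
    list(e = 6L, k = 3L, cin = 80L,  cout = 160L, n = 10L),
    list(e = 6L, k = 5L, cin = 160L, cout = 224L, n = 10L),
    list(e = 6L, k = 5L, cin = 224L, cout = 384L, n = 13L),
    list(e = 6L, k = 3L, cin = 384L, cout = 640L, n = 4L))
  layers <- list(zoo_conv("features.0.0", 3, stem, 3, bias = FALSE),
                 zoo_bn("features.0.1", stem))
  for (s in seq_along(cfg)) {
    st <- cfg[[s]]
    cin <- st$cin
    for (i in seq_len(st$n)) {
      id <- sprintf("features.%d.%d.block", s, i - 1L)
      mid <- cin * st$e
      sq <- max(1L, cin %/% 4L)
      if (st$e != 1L) {
        layers <- c(layers, list(
          zoo_conv(paste0(id, ".expand"), cin, mid, 1, bias = FALSE),
          zoo_bn(paste0(id, ".expand_bn"), mid)))
      }
      layers <- c(layers, list(
        zoo_conv(paste0(id, ".dwconv"), mid, mid, st$k, bias = FALSE,
                 groups = mid),
        zoo_bn(paste0(id, ".dwconv_bn"), mid),
        zoo_conv(paste0(id, ".se.fc1"), mid, sq, 1),
        zoo_conv(paste0(id, ".se.fc2"), sq, mid, 1),
        zoo_conv(paste0(id, ".project"), mid, st$cout, 1, bias = FALSE),
        zoo_bn(paste0(id, ".project_bn"), st$cout)))
      cin <- st$cout
    }
  }
  c(layers, list(
    zoo_conv("features.8.0", 640, head, 1, bias = FALSE),
    zoo_bn("features.8.1", head),
    zoo_fc("classifier.1", head, 1000)))
}

.zoo_env$maxvit_t <- function() {
  block_channels <- c(64L, 128L, 256L, 512L)
  block_layers <- c(2L, 2L, 5L, 2L)
  head_dim <- 32L; psize <- 7L
  layers <- list(
    zoo_conv("stem.0.0", 3, 64, 3, bias = FALSE),
    zoo_bn("stem.0.1", 64),
    zoo_conv("stem.1.0", 64, 64, 3))
  attn <- function(id, d) {
    h <- d %/% head_dim
    list(
      zoo_ln(paste0(id, ".attn_layer.0"), d, shape = "token_sequence"),
      zl(paste0(id, ".attn_layer.1.rel_pos_bias"),
         (2L * psize - 1L)^2 * h, "token_sequence", "bias_table"),
      zl(paste0(id, ".attn_layer.1.to_qkv"), d * 3L * d + 3L * d,
         "token_sequence", "linear"),
      zl(paste0(id, ".attn_layer.1.merge"), d * d + d,
         "token_sequence", "linear"),
      zoo_ln(paste0(id, ".mlp_layer.0"), d, shape = "token_sequence"),
      zl(paste0(id, ".mlp_layer.1"), d * 4L * d + 4L * d,
         "token_sequence", "linear"),
      zl(paste0(id, ".mlp_layer.3"), 4L * d * d + d,
         "token_sequence", "linear"))
  }
  cin <- 64L
  for (s in seq_along(block_channels)) {
    d <- block_channels[s]
    mid <- 4L * d; sq <- d %/% 4L
    for (i in seq_len(block_layers[s])) {
      id <- sprintf("blocks.%d.layers.%d", s - 1L, i - 1L)
      mb <- list()
      if (i == 1L) mb <- list(zoo_conv(paste0(id, ".mbconv.proj"), cin, d, 1))
      mb <- c(mb, list(
        zoo_bn(paste0(id, ".mbconv.pre_norm"), cin),
        zoo_conv(paste0(id, ".mbconv.conv_a"), cin, mid, 1, bias = FALSE),
        zoo_bn(paste0(id, ".mbconv.conv_a_bn"), mid),
        zoo_conv(paste0(id, ".mbconv.conv_b"), mid, mid, 3, bias = FALSE,
                 groups = mid),
        zoo_bn(paste0(id, ".mbconv.conv_b_bn"), mid),
        zoo_conv(paste0(id, ".mbconv.se.fc1"), mid, sq, 1),
        zoo_conv(paste0(id, ".mbconv.se.fc2"), sq, mid, 1),
        zoo_conv(paste0(id, ".mbconv.conv_c"), mid, d, 1)))
      layers <- c(layers, mb,
                  attn(paste0(id, ".window_attn"), d),
                  attn(paste0(id, ".grid_attn"), d))
      cin <- d
    }
  }
  c(layers, list(
    zoo_ln("classifier.2", 512, shape = "vector1d"),
    zoo_fc("classifier.3", 512, 512),
    zoo_fc("classifier.5", 512, 1000, bias = FALSE)))
}

## ---- public surface --------------------------------------------------------

#' List the architectures known to the zoo registry
#' @return character vector of model names accepted by [zoo_model()].
#' @export
list_zoo_models <- function() sort(ls(.zoo_env))

#' Build a zoo architecture census
#'
#' Returns the layer-by-layer parameter census of a standard 1000-class
#' image-classification architecture (the published definition; no weights
#' are instantiated). Supported names: alexnet, convnext_base, densenet161,
#' efficientnet_b7, maxvit_t, resnet50, resnet152, squeezenet1_0.
#'
#' @param name architecture name.
#' @return an object of class `cr_zoo_model` with a `layers` tibble
#'   (`name`, `kind`, `shape_class`, `param_count`).
#' @export
zoo_model <- function(name) {
  gen <- .zoo_env[[name]]
  if (is.null(gen)) {
    stop("unknown zoo model '", name, "'; available: ",
         paste(list_zoo_models(), collapse = ", "), call. = FALSE)
  }
  ll <- gen()
  layers <- tibble::tibble(
    index = seq_along(ll) - 1L,
    name = vapply(ll, `[[`, "", "name"),
    kind = vapply(ll, `[[`, "", "kind"),
    shape_class = vapply(ll, `[[`, "", "shape_class"),
    param_count = vapply(ll, `[[`, 1.0, "param_count")
  )
  structure(list(name = name, layers = layers), class = "cr_zoo_model")
}

#' @rdname profile-methods
#' @export
profile.cr_zoo_model <- function(fitted, ...) {
  structure(list(model = fitted$name,
                 total_params = sum(fitted$layers$param_count),
                 n_target_layers = nrow(fitted$layers),
                 layers = fitted$layers[c("index", "name", "shape_class",
                                          "param_count")]),
            class = "model_profile")
}

#' @export
print.cr_zoo_model <- function(x, ...) {
  cat("<cr_zoo_model> ", x$name, ": ", nrow(x$layers),
      " parameterized leaf layers, ",
      format(sum(x$layers$param_count), big.mark = ","), " parameters\n",
      sep = "")
  invisible(x)
}
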