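# Class activation maps at a single layer. A CAM is a weighted combination of
# a layer's channel activation maps, rectified and bilinearly upsampled to
# input resolution:
#
#   L^c(A^l) = upsample( max( combine_k(alpha^c_k, A^l_k), 0 ) )
#
# The weighting scheme decides alpha: gradient schemes use spatially averaged
# or element-wise gradients of the pre-softmax class score, perturbation
# schemes (ScoreCAM, AblationCAM) probe the model with modified inputs or
# activations, EigenCAM takes the leading principal component of the
# activations, and RandomCAM draws channel weights uniformly from [-1, 1].

.cr_eps <- 1e-8

#' Supported CAM weighting schemes
#' @return character vector of scheme names accepted by [compute_cam()].
#' @export
cam_schemes <- function() {
  c("gradcam", "gradcampp", "xgradcam", "hirescam", "gradcam_elementwise",
    "layercam", "eigencam", "eigengradcam", "scorecam", "ablationcam",
    "randomcam")
}

cr_scheme_traits <- function(scheme) {
  scheme <- match.arg(scheme, cam_schemes())
  list(name = scheme,
       requires_gradients = scheme %in% c("gradcam", "gradcampp", "xgradcam",
                                          "hirescam", "gradcam_elementwise",
                                          "layercam", "eigengradcam"),
       requires_forward_evals = scheme %in% c("scorecam", "ablationcam"),
       class_discriminative = !(scheme %in% c("eigencam", "randomcam")))
}

#' Bilinear upsampling of a 2-D map
#'
#' Corner-aligned bilinear interpolation: the four corner values of the
#' input are preserved at the output corners, constant maps stay constant,
#' and resampling to the input's own shape is the identity.
#'
#' @param m numeric matrix.
#' @param out_h,out_w positive output extents.
#' @return `out_h x out_w` matrix.
#' @export
upsample_bilinear <- function(m, out_h, out_w) {
  m <- as.matrix(m)
  if (out_h < 1L || out_w < 1L) stop("output shape must be positive",
                                     call. = FALSE)
  in_h <- nrow(m); in_w <- ncol(m)
  src <- function(n_out, n_in) {
    if (n_out == 1L || n_in == 1L) rep(0, n_out)
    else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  sy <- src(out_h, in_h); sx <- src(out_w, in_w)
  y0 <- pmin(floor(sy), in_h - 1L); fy <- sy - y0
  x0 <- pmin(floor(sx), in_w - 1L); fx <- sx - x0
  y1 <- pmin(y0 + 1, in_h - 1)
  x1 <- pmin(x0 + 1, in_w - 1)
  top <- m[y0 + 1L, , drop = FALSE] * (1 - fy) + m[y1 + 1L, , drop = FALSE] * fy
  out <- top[, x0 + 1L, drop = FALSE] * rep(1 - fx, each = out_h) +
    top[, x1 + 1L, drop = FALSE] * rep(fx, each = out_h)
  out
}

# min-max normalize a matrix to [0,1]; constant maps become all-zero
cr_unit_scale <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Channel weights (or pixel weights) for a CAM scheme
#'
#' Computes the weight structure the scheme applies to the activation
#' channels. Depending on the scheme the result is a per-channel scalar
#' vector, a per-pixel weight tensor, or a directly combined pre-ReLU map.
#'
#' @param scheme scheme name, see [cam_schemes()].
#' @param A activation array `(h, w, k)` at the layer.
#' @param G matching gradient array `dy^c/dA`, required by gradient schemes.
#' @param oracle for `scorecam`/`ablationcam`: a function
#'   `function(kind, ...)` implementing the forward-evaluation probes (see
#'   [compute_cam()], which wires it up automatically).
#' @param seed RNG seed, used by `randomcam` only.
#' @return a list with `type` (`"channel"`, `"pixel"` or `"direct"`) and
#'   `value`: per-channel weights, a per-pixel weight array, or the combined
#'   pre-ReLU map.
#' @export
channel_weights <- function(scheme, A, G = NULL, oracle = NULL, seed = NULL) {
  tr <- cr_scheme_traits(scheme)
  if (length(dim(A)) == 2L) dim(A) <- c(dim(A), 1L)
  k <- dim(A)[3]
  if (tr$requires_gradients) {
    if (is.null(G)) stop("scheme '", scheme, "' requires gradients",
                         call. = FALSE)
    if (length(dim(G)) == 2L) dim(G) <- c(dim(G), 1L)
    stopifnot(identical(dim(G), dim(A)))
  }
  ch_sum <- function(x) apply(x, 3, sum)
  switch(scheme,
    gradcam = list(type = "channel", value = apply(G, 3, mean)),
    gradcampp = {
      g2 <- G^2
      denom <- 2 * g2 + rep(ch_sum(A * G^3), each = prod(dim(A)[1:2])) + .cr_eps
      w <- g2 / denom
      list(type = "channel", value = ch_sum(w * pmax(G, 0)))
    },
    xgradcam = {
      asum <- ch_sum(A)
      an <- A / rep(asum + .cr_eps, each = prod(dim(A)[1:2]))
      list(type = "channel", value = ch_sum(an * G))
    },
    hirescam = list(type = "pixel", value = G),
    gradcam_elementwise = {
      list(type = "direct", value = apply(pmax(G * A, 0), c(1, 2), sum))
    },
    layercam = list(type = "pixel", value = pmax(G, 0)),
    eigencam = list(type = "direct", value = cr_eigen_map(A)),
    eigengradcam = list(type = "direct", value = cr_eigen_map(G * A)),
    scorecam = {
      if (is.null(oracle)) stop("scorecam needs a forward-eval oracle",
                                call. = FALSE)
      usable <- vapply(seq_len(k), function(j) diff(range(A[, , j])) > 0, TRUE)
      alpha <- numeric(k)
      if (any(usable)) {
        srcs <- lapply(which(usable), function(j) A[, , j])
        scores <- oracle("masked_scores", mask_sources = srcs)
        e <- exp(scores - max(scores))
        alpha[usable] <- e / sum(e)
      }
      list(type = "channel", value = alpha)
    },
    ablationcam = {
      if (is.null(oracle)) stop("ablationcam needs a forward-eval oracle",
                                call. = FALSE)
      y <- oracle("base_score")
      alpha <- vapply(seq_len(k), function(j) {
        (y - oracle("ablated_score", channel = j)) / (abs(y) + .cr_eps)
      }, 1.0)
      list(type = "channel", value = alpha)
    },
    randomcam = {
      if (is.null(seed)) stop("randomcam needs a seed", call. = FALSE)
      list(type = "channel",
           value = withr::with_seed(seed, stats::runif(k, -1, 1)))
    }
  )
}

# leading right singular vector of the (k x hw) channel matrix, reshaped to
# (h, w); sign fixed so the map sums to >= 0
cr_eigen_map <- function(A) {
  d <- dim(A)
  M <- t(matrix(A, d[1] * d[2], d[3]))     # k x hw
  sv <- svd(M, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (sum(v) < 0) v <- -v
  matrix(v, d[1], d[2])
}

cr_combine_map <- function(w, A) {
  if (length(dim(A)) == 2L) dim(A) <- c(dim(A), 1L)
  switch(w$type,
    direct = w$value,
    pixel = apply(w$value * A, c(1, 2), sum),
    channel = {
      d <- dim(A)
      matrix(matrix(A, d[1] * d[2], d[3]) %*% w$value, d[1], d[2])
    })
}

#' Compute a class activation map at one layer
#'
#' Captures the layer's activations (and gradients where the scheme needs
#' them), combines the channels per the selected weighting scheme, applies
#' the ReLU rectification and bilinearly upsamples the result to input
#' resolution.
#'
#' @param model a `cr_model`.
#' @param image input image array matching the model input shape.
#' @param layer layer selector: name, 0-based index, or a one-row
#'   enumeration tibble. The layer must have a `spatial2d` output.
#' @param target `"argmax"` or 1-based class index. Recorded but unused for
#'   the class-agnostic schemes (`eigencam`, `randomcam`).
#' @param scheme weighting scheme name, see [cam_schemes()].
#' @param seed RNG seed for `randomcam`.
#' @param scorecam_batch number of channel masks evaluated per internal
#'   batch for `scorecam` (memory/speed trade-off only).
#' @return an object of class `cam_frame`: fields `layer_index` (0-based),
#'   `layer_name`, `method`, `target_class`, `shape_class`, `pre_relu_map`
#'   (signed, at layer resolution), and `raw_map` (non-negative, at input
#'   resolution).
#' @export
compute_cam <- function(model, image, layer, target = "argmax",
                        scheme = "gradcam", seed = NULL,
                        scorecam_batch = 16L) {
  tr <- cr_scheme_traits(scheme)
  pos <- cr_resolve_layer(model, layer)
  x <- cr_as_batch(image)
  fwd <- cr_forward(model, x)
  logits <- drop(fwd$logits)
  tc <- cr_resolve_target(target, logits)
  out <- fwd$outs[[pos]]
  shp <- classify_output_shape(cr_canonical_shape(out))
  if (shp != "spatial2d") {
    stop("layer '", model$layers[[pos]]$name, "' has a ", shp,
         " output; 1-D representations are filtered out of CAM rendering",
         call. = FALSE)
  }
  d <- dim(out)
  A <- array(out, d[1:3])
  G <- NULL
  if (tr$requires_gradients) {
    sgrad <- matrix(0, length(logits), 1L)
    sgrad[tc, 1L] <- 1
    bk <- cr_backward(model, fwd, sgrad)
    G <- array(bk$grad_acts[[pos]], d[1:3])
  }
  oracle <- NULL
  if (tr$requires_forward_evals) {
    in_h <- model$input_shape[1]; in_w <- model$input_shape[2]
    oracle <- function(kind, ...) {
      args <- list(...)
      switch(kind,
        base_score = logits[tc],
        masked_scores = {
          srcs <- args$mask_sources
          scores <- numeric(length(srcs))
          for (b0 in seq(1L, length(srcs), by = scorecam_batch)) {
            bi <- b0:min(b0 + scorecam_batch - 1L, length(srcs))
            xb <- array(0, c(dim(x)[1:3], length(bi)))
            for (m_i in seq_along(bi)) {
              mk <- cr_unit_scale(
                upsample_bilinear(srcs[[bi[m_i]]], in_h, in_w))
              xb[, , , m_i] <- x[, , , 1L] * as.vector(mk)
            }
            lg <- cr_forward(model, xb)$logits
            scores[bi] <- lg[tc, ]
          }
          scores
        },
        ablated_score = {
          oa <- out
          oa[, , args$channel, ] <- 0
          drop(cr_forward_from(model, pos + 1L, oa))[tc]
        })
    }
  }
  w <- channel_weights(scheme, A, G, oracle = oracle, seed = seed)
  pre <- cr_combine_map(w, A)
  raw <- upsample_bilinear(pmax(pre, 0), model$input_shape[1],
                           model$input_shape[2])
  structure(list(layer_index = pos - 1L,
                 layer_name = model$layers[[pos]]$name,
                 method = scheme,
                 target_class = tc,
                 shape_class = shp,
                 pre_relu_map = pre,
                 raw_map = raw),
            class = "cam_frame")
}

#' @export
print.cam_frame <- function(x, ...) {
  cat("<cam_frame> layer ", x$layer_index, " (", x$layer_name, "), ",
      x$method, ", class ", x$target_class, ", map ",
      nrow(x$raw_map), "x", ncol(x$raw_map), "\n", sep = "")
  invisible(x)
}

#' Heatmap of a single CAM frame
#' @param object a `cam_frame`.
#' @param ... unused.
#' @export
autoplot.cam_frame <- function(object, ...) {
  df <- cr_map_df(object$raw_map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "activation") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s @ layer %d (%s), class %d",
                                  object$method, object$layer_index,
                                  object$layer_name, object$target_class))
}

cr_map_df <- function(m) {
  tibble::tibble(
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    y = rep(seq_len(nrow(m)), ncol(m)),
    value = as.vector(m)
  )
}
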