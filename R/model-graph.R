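# Layer enumeration, activation/gradient capture and shape classification.
# A "target layer" is any leaf layer of the network whose forward output is a
# numeric tensor; its output-shape class decides whether it can be rendered
# as a 2-D activation map or must be filtered out (1-D representations).

#' Classify a layer output shape
#'
#' Decides how a layer's output can be visualized. Shapes follow the
#' batch-first convention `(N, C, H, W)` for convolutional outputs,
#' `(N, features)` for flattened/linear outputs and
#' `(N, tokens, embedding)` for attention-style token sequences.
#'
#' Outputs of rank 2 or less, and spatial outputs whose every spatial extent
#' is 1, are `vector1d`: heatmaps of such layers merely draw 1-D vectors as
#' stripes, so they are excluded from CAM rendering by default. Rank-4
#' outputs with both trailing spatial extents above 1 are `spatial2d`;
#' rank-3 outputs are `token_sequence`.
#'
#' @param shape integer vector of positive extents.
#' @return one of `"spatial2d"`, `"vector1d"`, `"token_sequence"`.
#' @examples
#' classify_output_shape(c(1, 256, 14, 14)) # spatial2d
#' classify_output_shape(c(1, 1000))        # vector1d
#' classify_output_shape(c(1, 49, 768))     # token_sequence
#' @export
classify_output_shape <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) == 0L || any(is.na(shape)) || any(shape <= 0L)) {
    stop("shape must be a non-empty tuple of positive integers", call. = FALSE)
  }
  r <- length(shape)
  if (r <= 2L) return("vector1d")
  if (r == 3L) return("token_sequence")
  sp <- shape[(r - 1L):r]
  if (all(sp > 1L)) "spatial2d" else "vector1d"
}

# canonical (N, C, H, W)-style tuple for an engine activation
cr_canonical_shape <- function(out) {
  d <- dim(out)
  if (is.null(d)) return(c(1L, length(out)))
  if (length(d) == 2L) return(c(d[2], d[1]))          # (features, N) matrix
  if (length(d) == 4L) return(c(d[4], d[3], d[1], d[2]))
  stop("unexpected activation rank: ", length(d), call. = FALSE)
}

#' Enumerate a model's target layers in forward order
#'
#' Runs a probe forward pass with a zero image and lists every leaf layer in
#' forward execution order, together with its output-shape class and
#' parameter count. Enumeration is deterministic for a fixed model.
#'
#' @param model a `cr_model` handle.
#' @param include_filter optional predicate `function(layer) -> logical`
#'   applied to each engine layer (e.g. drop activations); layers failing it
#'   are omitted and the remaining indices stay consecutive.
#' @return a tibble with columns `index` (0-based forward position), `name`,
#'   `kind`, `shape_class`, `param_count` and `out_shape` (list-column of
#'   canonical `(N, C, H, W)` tuples).
#' @export
enumerate_target_layers <- function(model, include_filter = NULL) {
  stopifnot(inherits(model, "cr_model"))
  probe <- array(0, c(model$input_shape, 1L))
  fwd <- cr_forward(model, probe)
  keep <- rep(TRUE, length(model$layers))
  if (!is.null(include_filter)) {
    keep <- vapply(model$layers, function(l) isTRUE(include_filter(l)), TRUE)
  }
  numeric_out <- vapply(fwd$outs, function(o) is.numeric(o), TRUE)
  keep <- keep & numeric_out
  if (!any(keep)) {
    stop("model has no qualifying target layers", call. = FALSE)
  }
  sel <- which(keep)
  shapes <- lapply(fwd$outs[sel], cr_canonical_shape)
  tibble::tibble(
    index = seq_along(sel) - 1L,
    name = vapply(model$layers[sel], `[[`, "", "name"),
    kind = vapply(model$layers[sel], `[[`, "", "kind"),
    shape_class = vapply(shapes, classify_output_shape, ""),
    param_count = vapply(model$layers[sel], cr_layer_param_count, 1L),
    out_shape = shapes
  )
}

# resolve a layer argument (row tibble, name or 0-based index) to the model's
# internal 1-based layer position
cr_resolve_layer <- function(model, layer) {
  nms <- vapply(model$layers, `[[`, "", "name")
  if (is.data.frame(layer)) {
    stopifnot(nrow(layer) == 1L)
    layer <- layer$name
  }
  if (is.character(layer)) {
    pos <- match(layer, nms)
    if (is.na(pos)) stop("unknown layer name: ", layer, call. = FALSE)
    return(pos)
  }
  pos <- as.integer(layer) + 1L
  if (pos < 1L || pos > length(nms)) {
    stop("layer index out of range (model has ", length(nms), " layers)",
         call. = FALSE)
  }
  pos
}

# resolve a target-class spec ("argmax" or 1-based integer) against logits
cr_resolve_target <- function(target, logits) {
  n_class <- length(logits)
  if (identical(target, "argmax")) return(which.max(as.vector(logits)))
  target <- as.integer(target)
  if (is.na(target) || target < 1L || target > n_class) {
    stop("target class out of range: model has ", n_class, " classes",
         call. = FALSE)
  }
  target
}

#' Capture activations (and class-score gradients) at chosen layers
#'
#' Performs one forward pass in inference mode and, when gradients are
#' requested, one backward pass of the pre-softmax class score \eqn{y^c}
#' with respect to every layer output. The model itself is left unmodified.
#'
#' @param model a `cr_model`.
#' @param image single image array `(H, W)` or `(H, W, C)` matching the
#'   model's input shape.
#' @param layers layer selection: `NULL` for all layers, or a vector of
#'   names / 0-based indices / an enumeration tibble subset.
#' @param target class spec: `"argmax"` (default) or a 1-based class index.
#' @param need_gradients capture `dy^c/dA^l` alongside activations?
#' @return an object of class `cr_activation_set`: named lists
#'   `activations` and (optionally) `gradients` of per-layer arrays with the
#'   batch axis dropped, plus `logits`, `probs` and the resolved
#'   `target_class`.
#' @export
capture <- function(model, image, layers = NULL, target = "argmax",
                    need_gradients = FALSE) {
  stopifnot(inherits(model, "cr_model"))
  x <- cr_as_batch(image)
  din <- dim(x)
  if (!identical(din[1:3], as.integer(model$input_shape))) {
    stop("image shape ", paste(din[1:3], collapse = "x"),
         " does not match model input ",
         paste(model$input_shape, collapse = "x"), call. = FALSE)
  }
  nms <- vapply(model$layers, `[[`, "", "name")
  pos <- if (is.null(layers)) seq_along(nms)
         else vapply(if (is.data.frame(layers)) layers$name else layers,
                     function(l) cr_resolve_layer(model, l), 1L)
  fwd <- cr_forward(model, x)
  logits <- drop(fwd$logits)
  tc <- cr_resolve_target(target, logits)
  drop_batch <- function(a) {
    d <- dim(a)
    if (length(d) == 4L) array(a, d[1:3]) else as.vector(a)
  }
  acts <- lapply(fwd$outs[pos], drop_batch)
  names(acts) <- nms[pos]
  grads <- NULL
  if (isTRUE(need_gradients)) {
    seed <- matrix(0, length(logits), 1L)
    seed[tc, 1L] <- 1
    bk <- cr_backward(model, fwd, seed)
    grads <- lapply(bk$grad_acts[pos], drop_batch)
    names(grads) <- nms[pos]
  }
  structure(list(activations = acts, gradients = grads,
                 logits = as.vector(logits),
                 probs = cr_softmax(as.vector(logits)),
                 target_class = tc,
                 layer_names = nms[pos]),
            class = "cr_activation_set")
}

#' @export
print.cr_activation_set <- function(x, ...) {
  cat("<cr_activation_set> ", length(x$activations), " layers, target class ",
      x$target_class,
      if (is.null(x$gradients)) " (no gradients)" else " (with gradients)",
      "\n", sep = "")
  invisible(x)
}

## ---- profiling -------------------------------------------------------------

#' @importFrom stats profile
#' @export
stats::profile

#' Profile a model's parameter census
#'
#' Counts parameters per leaf layer and in total. For engine models the
#' census comes from the live object; for zoo architectures (see
#' [zoo_model()]) it is generated from the published architecture
#' definition.
#'
#' @param fitted a `cr_model`, a `cr_zoo_model`, or a zoo architecture name
#'   such as `"alexnet"`.
#' @param ... unused.
#' @return an object of class `model_profile` with fields `model`,
#'   `total_params`, `n_target_layers` and a `layers` tibble.
#' @examples
#' profile("alexnet")$total_params # 61100840
#' @name profile-methods
NULL

#' @rdname profile-methods
#' @export
profile.cr_model <- function(fitted, ...) {
  layers <- enumerate_target_layers(fitted)
  structure(list(model = fitted$name,
                 total_params = sum(layers$param_count),
                 n_target_layers = nrow(layers),
                 layers = layers[c("index", "name", "shape_class",
                                   "param_count")]),
            class = "model_profile")
}

#' @rdname profile-methods
#' @export
profile.character <- function(fitted, ...) {
  profile(zoo_model(fitted), ...)
}

#' @export
print.model_profile <- function(x, ...) {
  cat("<model_profile> ", x$model, ": ",
      format(x$total_params, big.mark = ","), " parameters across ",
      x$n_target_layers, " target layers\n", sep = "")
  invisible(x)
}

#' Serialize a model profile to JSON
#'
#' @param p a `model_profile`.
#' @return a JSON string with fields `model`, `total_params`,
#'   `n_target_layers` and `layers`.
#' @export
profile_json <- function(p) {
  stopifnot(inherits(p, "model_profile"))
  jsonlite::toJSON(list(
    model = p$model,
    total_params = p$total_params,
    n_target_layers = p$n_target_layers,
    layers = p$layers
  ), auto_unbox = TRUE, digits = NA)
}

#' @export
tidy.model_profile <- function(x, ...) x$layers

#' @export
glance.model_profile <- function(x, ...) {
  tibble::tibble(model = x$model, total_params = x$total_params,
                 n_target_layers = x$n_target_layers)
}
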