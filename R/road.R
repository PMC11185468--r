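# Combined Remove-and-Debias (ROAD) faithfulness scoring with noisy linear
# imputation, and the per-layer series ("yellow brick ROAD", ybROAD).
#
# For a unit-normalized saliency map, a fraction p of pixels is selected
# either most-relevant-first (MRP) or least-relevant-first (LRP); the
# selected pixels are replaced by the solution of a neighbor-averaging
# linear system plus small Gaussian noise, and the change in post-softmax
# target confidence is recorded. The combined score averages
# (C_LRP - C_MRP) / 2 over fractions: higher means the map better
# identifies the evidence the model actually uses.

#' ROAD configuration
#'
#' @param fractions strictly increasing perturbation fractions in (0, 1).
#' @param noise_sd Gaussian noise sd added to imputed pixels (unit-scaled
#'   images).
#' @param aggregate `"mean"` (default; combined score bounded in \[-1, 1\]) or
#'   `"sum"` over fractions.
#' @param seed integer seed for the imputation noise.
#' @return a `road_config` list.
#' @export
road_config <- function(fractions = c(0.2, 0.4, 0.6, 0.8), noise_sd = 0.01,
                        aggregate = c("mean", "sum"), seed = 1L) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(fractions) >= 1L, all(fractions > 0), all(fractions < 1),
            !is.unsorted(fractions, strictly = TRUE), noise_sd >= 0)
  structure(list(fractions = fractions, noise_sd = noise_sd,
                 aggregate = aggregate, seed = as.integer(seed)),
            class = "road_config")
}

#' Select the most- or least-relevant pixels of a saliency map
#'
#' Picks exactly `round(fraction * H * W)` pixels by saliency rank, ties
#' broken by ascending flat (column-major) index for determinism.
#'
#' @param unit_map numeric matrix in \[0, 1\].
#' @param fraction fraction of pixels in (0, 1).
#' @param order `"most_relevant"` or `"least_relevant"`.
#' @return logical matrix of the same shape.
#' @export
select_pixels <- function(unit_map, fraction,
                          order = c("most_relevant", "least_relevant")) {
  order <- match.arg(order)
  stopifnot(fraction > 0, fraction < 1)
  n_sel <- round(fraction * length(unit_map))
  v <- as.vector(unit_map)
  rk <- if (order == "most_relevant") order(-v, seq_along(v))
        else order(v, seq_along(v))
  mask <- logical(length(v))
  mask[rk[seq_len(n_sel)]] <- TRUE
  matrix(mask, nrow(unit_map), ncol(unit_map))
}

#' Noisy linear imputation of masked pixels
#'
#' Replaces each masked pixel by the solution of the linear system in which
#' it equals the mean of its 4-neighbors (unmasked neighbors enter as
#' constants; image boundaries shrink the neighbor set), solved per channel
#' with a sparse solver, then adds independent Gaussian noise (seeded) to
#' the imputed pixels only. Unmasked pixels are returned bit-unchanged.
#'
#' @param image matrix `(H, W)` or array `(H, W, C)`.
#' @param mask logical matrix `(H, W)`; `TRUE` pixels are imputed.
#' @param noise_sd Gaussian sd of the post-solve noise.
#' @param seed RNG seed for the noise.
#' @return imputed image of the original shape.
#' @export
noisy_linear_impute <- function(image, mask, noise_sd = 0.01, seed = 1L) {
  d <- dim(image)
  is_mat <- length(d) == 2L
  if (is_mat) { dim(image) <- c(d, 1L); d <- dim(image) }
  stopifnot(is.logical(mask), identical(dim(mask), d[1:2]))
  h <- d[1]; w <- d[2]; nch <- d[3]
  n_mask <- sum(mask)
  if (n_mask == 0L) {
    if (is_mat) dim(image) <- d[1:2]
    return(image)
  }
  if (n_mask == h * w) {
    warning("fully masked image: diffusion system is ill-posed; ",
            "using channel-mean fill", call. = FALSE)
    out <- image
    for (ch in seq_len(nch)) out[, , ch] <- mean(image[, , ch])
    out <- cr_impute_noise(out, mask, noise_sd, seed, nch)
    if (is_mat) dim(out) <- d[1:2]
    return(out)
  }
  # unknown ordering: column-major flat index over masked pixels
  uidx <- which(mask)                      # flat indices
  umap <- integer(h * w); umap[uidx] <- seq_along(uidx)
  ui <- (uidx - 1L) %% h + 1L
  uj <- (uidx - 1L) %/% h + 1L
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rhs_idx <- integer(0); rhs_nb <- integer(0)
  deg <- integer(n_mask)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (s in shifts) {
    ni <- ui + s[1]; nj <- uj + s[2]
    ok <- ni >= 1L & ni <= h & nj >= 1L & nj <= w
    deg <- deg + as.integer(ok)
    nb_flat <- (nj[ok] - 1L) * h + ni[ok]
    nb_unknown <- umap[nb_flat]
    kn <- nb_unknown > 0L
    trip_i <- c(trip_i, which(ok)[kn])
    trip_j <- c(trip_j, nb_unknown[kn])
    trip_x <- c(trip_x, rep(-1, sum(kn)))
    rhs_idx <- c(rhs_idx, which(ok)[!kn])
    rhs_nb <- c(rhs_nb, nb_flat[!kn])
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_len(n_mask), trip_i),
    j = c(seq_len(n_mask), trip_j),
    x = c(as.numeric(deg), trip_x),
    dims = c(n_mask, n_mask))
  out <- image
  for (ch in seq_len(nch)) {
    chan <- image[, , ch]
    b <- numeric(n_mask)
    if (length(rhs_idx)) {
      contrib <- chan[rhs_nb]
      b <- as.numeric(tapply(contrib, factor(rhs_idx,
                                             levels = seq_len(n_mask)), sum))
      b[is.na(b)] <- 0
    }
    sol <- as.numeric(Matrix::solve(A, b))
    chan[uidx] <- sol
    out[, , ch] <- chan
  }
  out <- cr_impute_noise(out, mask, noise_sd, seed, nch)
  if (is_mat) dim(out) <- d[1:2]
  out
}

cr_impute_noise <- function(image, mask, noise_sd, seed, nch) {
  if (noise_sd <= 0) return(image)
  n_mask <- sum(mask)
  noise <- withr::with_seed(seed,
                            stats::rnorm(n_mask * nch, 0, noise_sd))
  for (ch in seq_len(nch)) {
    sl <- image[, , ch]
    sl[mask] <- sl[mask] + noise[(ch - 1L) * n_mask + seq_len(n_mask)]
    image[, , ch] <- sl
  }
  image
}

#' ROAD score of one CAM frame
#'
#' For each perturbation fraction and each ordering, evaluates the change in
#' post-softmax target probability between the imputed and the original
#' image, then combines per the aggregate rule:
#' `combined = aggregate_p[(C_LRP,p - C_MRP,p)] / 2`.
#'
#' Noise seeds are derived from `(config$seed, fraction)` only, so swapping
#' the order labels negates the combined score exactly.
#'
#' @param model a `cr_model`.
#' @param image input image.
#' @param frame a `cam_frame`, or a unit-normalized saliency matrix.
#' @param target 1-based class index (fixed; resolve argmax beforehand).
#' @param config a [road_config()].
#' @param orders which pixel ordering plays the LRP and the MRP role;
#'   swapping the two labels negates the combined score exactly (the noise
#'   seeds are shared per fraction).
#' @return a `road_result`: tibble `per_fraction` (fraction, C_LRP, C_MRP)
#'   plus `combined`, `layer_index`, `layer_name`.
#' @export
road_score <- function(model, image, frame, target, config = road_config(),
                       orders = c("least_relevant", "most_relevant")) {
  stopifnot(length(orders) == 2L,
            all(orders %in% c("least_relevant", "most_relevant")),
            orders[1] != orders[2])
  stopifnot(inherits(config, "road_config"))
  if (inherits(frame, "cam_frame")) {
    sal <- suppressWarnings(normalize_local(frame))
    layer_index <- frame$layer_index
    layer_name <- frame$layer_name
  } else {
    sal <- as.matrix(frame)
    stopifnot(min(sal) >= 0, max(sal) <= 1)
    layer_index <- NA_integer_
    layer_name <- NA_character_
  }
  target <- as.integer(target)
  base_prob <- cr_probs(model, image)[target]
  conf_change <- function(mask, seed) {
    imp <- noisy_linear_impute(image, mask, config$noise_sd, seed)
    cr_probs(model, imp)[target] - base_prob
  }
  n_f <- length(config$fractions)
  c_lrp <- numeric(n_f); c_mrp <- numeric(n_f)
  for (i in seq_len(n_f)) {
    f <- config$fractions[i]
    seed_f <- config$seed + 7919L * i
    c_lrp[i] <- conf_change(select_pixels(sal, f, orders[1]), seed_f)
    c_mrp[i] <- conf_change(select_pixels(sal, f, orders[2]), seed_f)
  }
  diff2 <- (c_lrp - c_mrp) / 2
  combined <- if (config$aggregate == "mean") mean(diff2) else sum(diff2)
  structure(list(
    per_fraction = tibble::tibble(fraction = config$fractions,
                                  C_LRP = c_lrp, C_MRP = c_mrp),
    combined = combined,
    layer_index = layer_index,
    layer_name = layer_name,
    target_class = target,
    aggregate = config$aggregate),
    class = "road_result")
}

#' @export
print.road_result <- function(x, ...) {
  cat("<road_result> layer ", x$layer_index, " (", x$layer_name,
      "): combined ", signif(x$combined, 4), "\n", sep = "")
  invisible(x)
}

#' Per-layer ROAD series (ybROAD)
#'
#' Computes one CAM + ROAD score per `spatial2d` layer in forward order and
#' assembles the series with its mean, max and argmax layer. The argmax
#' layer is the most faithful explanatory layer of the network for this
#' image/class/scheme.
#'
#' @inheritParams cam_stack
#' @param config a [road_config()].
#' @return a `ybroad_series`: `series` tibble (`layer_index`, `layer_name`,
#'   per-fraction confidence changes, `combined`), `skipped` tibble,
#'   summaries `mean_score`, `max_score`, `argmax_layer_index`,
#'   `argmax_layer_name`, and provenance.
#' @export
ybroad <- function(model, image, scheme = "gradcam", target = "argmax",
                   config = road_config(), seed = NULL, quiet = TRUE) {
  layers <- enumerate_target_layers(model)
  spat <- layers[layers$shape_class == "spatial2d", ]
  if (nrow(spat) == 0L) stop("no scorable spatial2d layers", call. = FALSE)
  if (!quiet && any(layers$shape_class != "spatial2d")) {
    message("skipping non-spatial layer(s): ",
            paste(layers$name[layers$shape_class != "spatial2d"],
                  collapse = ", "))
  }
  # resolve the target once from the unperturbed image; hold it fixed
  tc <- cr_resolve_target(target, cr_logits(model, image))
  rows <- vector("list", nrow(spat))
  for (i in seq_len(nrow(spat))) {
    fr <- compute_cam(model, image, spat$name[i], target = tc,
                      scheme = scheme,
                      seed = if (is.null(seed)) NULL else seed + i)
    rs <- road_score(model, image, fr, target = tc, config = config)
    pf <- rs$per_fraction
    row <- tibble::tibble(layer_index = fr$layer_index,
                          layer_name = fr$layer_name)
    for (j in seq_len(nrow(pf))) {
      row[[sprintf("C_LRP_%g", pf$fraction[j])]] <- pf$C_LRP[j]
      row[[sprintf("C_MRP_%g", pf$fraction[j])]] <- pf$C_MRP[j]
    }
    row$combined <- rs$combined
    rows[[i]] <- row
  }
  series <- dplyr::bind_rows(rows)
  amax <- which.max(series$combined)
  structure(list(
    series = series,
    skipped = layers[layers$shape_class != "spatial2d",
                     c("index", "name", "shape_class")],
    mean_score = mean(series$combined),
    max_score = series$combined[amax],
    argmax_layer_index = series$layer_index[amax],
    argmax_layer_name = series$layer_name[amax],
    scheme = scheme,
    target_class = tc,
    config = config,
    model_name = model$name),
    class = "ybroad_series")
}

#' @export
print.ybroad_series <- function(x, ...) {
  cat("<ybroad_series> ", x$model_name, ", ", x$scheme, ", class ",
      x$target_class, ": ", nrow(x$series), " layers; mean ",
      signif(x$mean_score, 4), ", max ", signif(x$max_score, 4),
      " at layer ", x$argmax_layer_index, " (", x$argmax_layer_name, ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.ybroad_series <- function(x, ...) x$series

#' @export
glance.ybroad_series <- function(x, ...) {
  tibble::tibble(model = x$model_name, scheme = x$scheme,
                 target_class = x$target_class, n_layers = nrow(x$series),
                 mean_score = x$mean_score, max_score = x$max_score,
                 argmax_layer_index = x$argmax_layer_index,
                 argmax_layer_name = x$argmax_layer_name)
}

#' Line plot of a per-layer ROAD series
#' @param object a `ybroad_series`.
#' @param ... unused.
#' @export
autoplot.ybroad_series <- function(object, ...) {
  df <- object$series
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer_index,
                                   y = .data$combined)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::annotate("point", x = object$argmax_layer_index,
                      y = object$max_score, color = "goldenrod", size = 3) +
    ggplot2::labs(x = "layer index", y = "combined ROAD score",
                  title = sprintf("%s / %s: mean %.3f, max %.3f at layer %d",
                                  object$model_name, object$scheme,
                                  object$mean_score, object$max_score,
                                  object$argmax_layer_index))
}
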