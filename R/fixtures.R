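# Synthetic two-class lesion imagery and a small trainable CNN, emulating a
# malignant-vs-normal ultrasound classification task: speckle-textured
# background (Gaussian-smoothed multiplicative noise) with or without a
# brighter elliptical lesion, plus the ground-truth lesion mask for
# localization checks. Everything is reproducible from (parameters, seed).

#' Generate a synthetic lesion image dataset with an 80-10-10 split
#'
#' Each sample is a 64x64 single-channel image in \[0, 1\]. Class 1 ("lesion")
#' images contain one filled ellipse of random center/axes whose intensity
#' exceeds the background by `contrast` before speckle; class 0 ("normal")
#' images are background only. The speckle is multiplicative:
#' `image = (base + contrast * mask) * (1 + noise_level * smooth_field)`,
#' so at `noise_level = 0` lesion pixels sit exactly at background +
#' contrast.
#'
#' @param n total number of samples (>= 20), class-balanced.
#' @param contrast additive lesion contrast (> 0).
#' @param noise_level speckle strength (multiplicative, >= 0).
#' @param seed RNG seed; the dataset is a pure function of the arguments.
#' @param size image side length in pixels.
#' @param base background base intensity.
#' @return a `fixture_split`: lists `train`, `val`, `test` of samples
#'   (`image`, `label`, `truth_mask`), in 80-10-10 proportions.
#' @export
make_dataset <- function(n = 400L, contrast = 0.4, noise_level = 0.15,
                         seed = 1L, size = 64L, base = 0.3) {
  if (n < 20L) stop("n must be at least 20", call. = FALSE)
  if (contrast <= 0) stop("contrast must be positive", call. = FALSE)
  samples <- withr::with_seed(seed, {
    labels <- rep(c(0L, 1L), length.out = n)
    lapply(seq_len(n), function(i) {
      cr_make_sample(labels[i], contrast, noise_level, size, base)
    })
  })
  n_test <- round(0.1 * n)
  n_val <- round(0.1 * n)
  n_train <- n - n_val - n_test
  ord <- withr::with_seed(seed + 1L, sample.int(n))
  structure(list(
    train = samples[ord[seq_len(n_train)]],
    val = samples[ord[n_train + seq_len(n_val)]],
    test = samples[ord[n_train + n_val + seq_len(n_test)]],
    seed = seed, n = n, contrast = contrast, noise_level = noise_level,
    size = size),
    class = "fixture_split")
}

#' @export
print.fixture_split <- function(x, ...) {
  cat("<fixture_split> train/val/test = ", length(x$train), "/",
      length(x$val), "/", length(x$test), ", ", x$size, "x", x$size,
      ", contrast ", x$contrast, ", speckle ", x$noise_level, "\n", sep = "")
  invisible(x)
}

cr_make_sample <- function(label, contrast, noise_level, size, base) {
  clean <- matrix(base, size, size)
  mask <- matrix(FALSE, size, size)
  if (label == 1L) {
    cx <- stats::runif(1, 0.3 * size, 0.7 * size)
    cy <- stats::runif(1, 0.3 * size, 0.7 * size)
    ax <- stats::runif(1, 0.12 * size, 0.25 * size)
    ay <- stats::runif(1, 0.12 * size, 0.25 * size)
    th <- stats::runif(1, 0, pi)
    xs <- matrix(rep(seq_len(size), each = size), size, size)  # column index
    ys <- matrix(rep(seq_len(size), size), size, size)         # row index
    xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    mask <- (xr / ax)^2 + (yr / ay)^2 <= 1
    clean[mask] <- base + contrast
  }
  img <- clean
  if (noise_level > 0) {
    field <- cr_smooth_field(size)
    img <- clean * (1 + noise_level * field)
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, label = label, truth_mask = mask)
}

# zero-mean, unit-scale smooth Gaussian field (speckle carrier); separable
# zero-padded convolution by shifted sums
cr_smooth_field <- function(size, kernel_sd = 1.5, kernel_size = 9L) {
  raw <- matrix(stats::rnorm(size * size), size, size)
  half <- (kernel_size - 1L) %/% 2L
  g <- stats::dnorm(seq(-half, half), sd = kernel_sd)
  g <- g / sum(g)
  conv_rows <- function(m) {
    padded <- rbind(matrix(0, half, size), m, matrix(0, half, size))
    out <- matrix(0, size, size)
    for (d in seq_len(kernel_size)) {
      out <- out + g[d] * padded[(d - 1L) + seq_len(size), , drop = FALSE]
    }
    out
  }
  sm <- t(conv_rows(t(conv_rows(raw))))
  sm / stats::sd(sm)
}

#' Build the stock small CNN fixture
#'
#' Three conv(3x3) + batch-norm + ReLU + max-pool blocks (8, 16, 32
#' channels) followed by global average pooling and a 2-class linear head:
#' 14 enumerable leaf layers, 6,066 parameters. Weights use seeded He
#' initialization.
#'
#' @param seed RNG seed for the initialization.
#' @param input_size image side length (default 64).
#' @param in_channels input channel count.
#' @return a `cr_model`.
#' @export
make_tiny_cnn <- function(seed = 1L, input_size = 64L, in_channels = 1L) {
  chans <- c(8L, 16L, 32L)
  layers <- list()
  cin <- in_channels
  for (b in seq_along(chans)) {
    cout <- chans[b]
    layers <- c(layers, list(
      cr_conv2d(cin, cout, 3L, name = sprintf("conv%d", b)),
      cr_batchnorm2d(cout, name = sprintf("norm%d", b)),
      cr_relu(sprintf("relu%d", b)),
      cr_maxpool2d(sprintf("pool%d", b))))
    cin <- cout
  }
  layers <- c(layers, list(cr_gap("gap"),
                           cr_linear(chans[3], 2L, name = "fc")))
  model <- cr_sequential(layers, c(input_size, input_size, in_channels),
                         name = "tiny_cnn")
  withr::with_seed(seed, {
    for (i in seq_along(model$layers)) {
      l <- model$layers[[i]]
      if (l$kind == "conv2d") {
        fan_in <- nrow(l$params$weight)
        model$layers[[i]]$params$weight[] <-
          stats::rnorm(length(l$params$weight), 0, sqrt(2 / fan_in))
      } else if (l$kind == "linear") {
        fan_in <- ncol(l$params$weight)
        model$layers[[i]]$params$weight[] <-
          stats::rnorm(length(l$params$weight), 0, sqrt(2 / fan_in))
      }
    }
    model
  })
}

#' Train the fixture CNN
#'
#' Seeded mini-batch Adam on softmax cross-entropy. Deterministic for fixed
#' arguments. If the validation accuracy stays below 0.6 after the last
#' epoch the run is flagged as diverged (not an error).
#'
#' @param model a `cr_model` (see [make_tiny_cnn()]).
#' @param split a [make_dataset()] fixture split.
#' @param epochs training epochs; 0 returns the model unchanged.
#' @param lr Adam learning rate.
#' @param seed shuffling seed.
#' @param batch_size mini-batch size.
#' @return list with `model` (trained), `history` tibble (epoch, loss,
#'   val_accuracy), `val_accuracy`, `test_accuracy`, `diverged`.
#' @export
train_fixture <- function(model, split, epochs = 10L, lr = 0.01, seed = 1L,
                          batch_size = 32L) {
  stopifnot(inherits(split, "fixture_split"))
  if (epochs == 0L) {
    return(list(model = model, history = tibble::tibble(),
                val_accuracy = cr_eval_accuracy(model, split$val),
                test_accuracy = cr_eval_accuracy(model, split$test),
                diverged = FALSE))
  }
  tr <- split$train
  n <- length(tr)
  sz <- dim(tr[[1]]$image)
  # Adam state
  flat <- cr_param_vector(model)
  m1 <- numeric(length(flat)); m2 <- numeric(length(flat))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  hist <- vector("list", epochs)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (b0 in seq(1L, n, by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1L, n)]
        nb <- length(bi)
        x <- array(0, c(sz[1], sz[2], 1L, nb))
        y <- integer(nb)
        for (k in seq_len(nb)) {
          x[, , 1L, k] <- tr[[bi[k]]]$image
          y[k] <- tr[[bi[k]]]$label + 1L
        }
        fwd <- cr_forward(model, x, training = TRUE)
        model <- fwd$model                    # updated batch-norm buffers
        probs <- cr_softmax(fwd$logits)
        loss <- -mean(log(pmax(probs[cbind(y, seq_len(nb))], 1e-12)))
        gl <- probs
        gl[cbind(y, seq_len(nb))] <- gl[cbind(y, seq_len(nb))] - 1
        gl <- gl / nb
        bk <- cr_backward(model, fwd, gl)
        grad <- unlist(lapply(bk$grad_params,
                              function(g) lapply(g, as.vector)),
                       use.names = FALSE)
        flat <- cr_param_vector(model)
        step <- step + 1L
        m1 <- beta1 * m1 + (1 - beta1) * grad
        m2 <- beta2 * m2 + (1 - beta2) * grad^2
        mhat <- m1 / (1 - beta1^step)
        vhat <- m2 / (1 - beta2^step)
        flat <- flat - lr * mhat / (sqrt(vhat) + eps)
        model <- cr_set_params(model, flat)
        ep_loss <- ep_loss + loss; n_batches <- n_batches + 1L
      }
      hist[[ep]] <- tibble::tibble(
        epoch = ep, loss = ep_loss / n_batches,
        val_accuracy = cr_eval_accuracy(model, split$val))
    }
  })
  model <- cr_calibrate_bn(model, tr, batch_size)
  history <- dplyr::bind_rows(hist)
  history$val_accuracy[epochs] <- cr_eval_accuracy(model, split$val)
  val_acc <- history$val_accuracy[epochs]
  list(model = model, history = history, val_accuracy = val_acc,
       test_accuracy = cr_eval_accuracy(model, split$test),
       diverged = val_acc < 0.6)
}

# batch-norm recalibration: one pass over the training set with the final
# weights, replacing the lagging training-time EMA with the cumulative
# average of the batch statistics (the usual update-BN pass)
cr_calibrate_bn <- function(model, samples, batch_size) {
  bn_pos <- which(vapply(model$layers, `[[`, "", "kind") == "batchnorm2d")
  if (length(bn_pos) == 0L) return(model)
  for (p in bn_pos) {
    model$layers[[p]]$buffers$running_mean[] <- 0
    model$layers[[p]]$buffers$running_var[] <- 0
  }
  sz <- dim(samples[[1]]$image)
  j <- 0L
  for (b0 in seq(1L, length(samples), by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, length(samples))
    x <- array(0, c(sz[1], sz[2], 1L, length(bi)))
    for (k in seq_along(bi)) x[, , 1L, k] <- samples[[bi[k]]]$image
    j <- j + 1L
    for (p in bn_pos) model$layers[[p]]$config$momentum <- 1 / j
    model <- cr_forward(model, x, training = TRUE)$model
  }
  for (p in bn_pos) model$layers[[p]]$config$momentum <- 0.1
  model
}

cr_eval_accuracy <- function(model, samples) {
  if (length(samples) == 0L) return(NA_real_)
  sz <- dim(samples[[1]]$image)
  x <- array(0, c(sz[1], sz[2], 1L, length(samples)))
  for (k in seq_along(samples)) x[, , 1L, k] <- samples[[k]]$image
  logits <- cr_forward(model, x)$logits
  pred <- apply(logits, 2, which.max) - 1L
  truth <- vapply(samples, `[[`, 1L, "label")
  mean(pred == truth)
}

#' Localization IoU of a CAM frame against the ground-truth lesion mask
#'
#' Thresholds the unit-normalized map and computes the intersection-over-
#' union with the truth mask.
#'
#' @param frame a `cam_frame` or a unit-scaled matrix.
#' @param truth_mask logical matrix; must contain at least one TRUE pixel.
#' @param threshold map threshold in (0, 1).
#' @return scalar IoU in \[0, 1\].
#' @export
localization_iou <- function(frame, truth_mask, threshold = 0.5) {
  m <- if (inherits(frame, "cam_frame"))
    suppressWarnings(normalize_local(frame)) else as.matrix(frame)
  if (!any(truth_mask)) {
    stop("empty truth mask (normal-class sample has no lesion)",
         call. = FALSE)
  }
  stopifnot(identical(dim(m), dim(truth_mask)))
  pred <- m >= threshold
  inter <- sum(pred & truth_mask)
  union <- sum(pred | truth_mask)
  inter / union
}

#' Spatial entropy of a non-negative saliency map
#'
#' Shannon entropy of the map normalized to a probability distribution over
#' pixels; higher values mean more diffuse activation.
#'
#' @param m non-negative matrix.
#' @return entropy in nats (0 for a one-hot map; `log(H*W)` for uniform).
#' @export
map_entropy <- function(m) {
  v <- as.vector(m)
  stopifnot(all(v >= 0))
  s <- sum(v)
  if (s <= 0) return(log(length(v)))
  p <- v[v > 0] / s
  -sum(p * log(p))
}

#' Export a fixture split as PNG files plus a labels CSV
#'
#' @param split a `fixture_split`.
#' @param out_dir output directory.
#' @return invisibly, the path of the written labels CSV.
#' @export
export_fixture_png <- function(split, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (part in c("train", "val", "test")) {
    for (i in seq_along(split[[part]])) {
      s <- split[[part]][[i]]
      fn <- sprintf("%s_%04d_label%d.png", part, i, s$label)
      png::writePNG(s$image, file.path(out_dir, fn))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        file = fn, split = part, label = s$label)
    }
  }
  csv <- file.path(out_dir, "labels.csv")
  utils::write.csv(dplyr::bind_rows(rows), csv, row.names = FALSE)
  invisible(csv)
}
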