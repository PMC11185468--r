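# Compact feed-forward CNN engine: exact forward/backward for the handful of
# layer types the package needs (conv2d, batchnorm2d, relu, maxpool2d, global
# average pooling, linear). Tensors are plain R arrays laid out (H, W, C, N);
# convolutions run through cached im2col index tables and BLAS matmuls.

# cache of im2col index tables keyed by geometry
.cr_idx_cache <- new.env(parent = emptyenv())

#' @noRd
cr_as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input image must be a matrix or array", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("input must have 2-4 dims", call. = FALSE)
  x
}

# index table mapping im2col patch elements to flat positions in the padded
# input; rows are output pixels stacked over the batch, columns are (di,dj,c)
cr_im2col_idx <- function(h, w, c, n, k, pad) {
  key <- paste(h, w, c, n, k, pad, sep = "x")
  hit <- .cr_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  hw <- h * w
  # base table for one image
  oh <- rep.int(seq_len(h), w)            # output row, h fastest
  ow <- rep(seq_len(w), each = h)         # output col
  k2c <- k * k * c
  idx1 <- matrix(0L, hw, k2c)
  col <- 0L
  for (cc in seq_len(c)) {
    choff <- (cc - 1L) * hp * wp
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col <- col + 1L
        idx1[, col] <- (oh + di - 1L) + hp * (ow + dj - 2L) + choff
      }
    }
  }
  stride_img <- hp * wp * c
  idx <- idx1[rep.int(seq_len(hw), n), , drop = FALSE] +
    rep(0:(n - 1L), each = hw) * stride_img
  .cr_idx_cache[[key]] <- idx
  idx
}

cr_pad <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

## ---- layer constructors ----------------------------------------------------

cr_layer <- function(kind, name, params = list(), buffers = list(),
                     config = list()) {
  structure(list(kind = kind, name = name, params = params,
                 buffers = buffers, config = config),
            class = c(paste0("cr_", kind), "cr_layer"))
}

#' @noRd
cr_conv2d <- function(in_ch, out_ch, kernel = 3L, pad = (kernel - 1L) %/% 2L,
                      name = "conv") {
  k2c <- kernel * kernel * in_ch
  cr_layer("conv2d", name,
           params = list(weight = matrix(0, k2c, out_ch), bias = numeric(out_ch)),
           config = list(in_ch = in_ch, out_ch = out_ch, kernel = kernel,
                         pad = pad))
}

cr_batchnorm2d <- function(ch, eps = 1e-5, momentum = 0.1, name = "norm") {
  cr_layer("batchnorm2d", name,
           params = list(gamma = rep(1, ch), beta = numeric(ch)),
           buffers = list(running_mean = numeric(ch), running_var = rep(1, ch)),
           config = list(ch = ch, eps = eps, momentum = momentum))
}

cr_relu <- function(name = "relu") cr_layer("relu", name)

cr_maxpool2d <- function(name = "pool") cr_layer("maxpool2d", name)

cr_gap <- function(name = "gap") cr_layer("gap", name)

cr_linear <- function(in_features, out_features, name = "fc") {
  cr_layer("linear", name,
           params = list(weight = matrix(0, out_features, in_features),
                         bias = numeric(out_features)),
           config = list(in_features = in_features,
                         out_features = out_features))
}

## ---- forward ---------------------------------------------------------------

cr_forward_layer <- function(layer, x, training = FALSE) {
  switch(layer$kind,
    conv2d = {
      cf <- layer$config
      d <- dim(x)
      xp <- cr_pad(x, cf$pad)
      idx <- cr_im2col_idx(d[1], d[2], cf$in_ch, d[4], cf$kernel, cf$pad)
      P <- matrix(xp[idx], nrow(idx), ncol(idx))
      out_mat <- P %*% layer$params$weight
      out_mat <- out_mat + rep(layer$params$bias, each = nrow(out_mat))
      # rows of out_mat are (h,w) stacked over n; restore (h, w, ch, n)
      out <- aperm(array(out_mat, c(d[1], d[2], d[4], cf$out_ch)),
                   c(1, 2, 4, 3))
      list(out = out, cache = list(P = P, idx = idx, in_dim = d), layer = layer)
    },
    batchnorm2d = {
      cf <- layer$config
      d <- dim(x)
      m_ <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
      if (training) {
        mu <- colMeans(m_)
        va <- colMeans(m_^2) - mu^2
        n_el <- nrow(m_)
        ub <- va * n_el / max(1, n_el - 1)
        layer$buffers$running_mean <-
          (1 - cf$momentum) * layer$buffers$running_mean + cf$momentum * mu
        layer$buffers$running_var <-
          (1 - cf$momentum) * layer$buffers$running_var + cf$momentum * ub
      } else {
        mu <- layer$buffers$running_mean
        va <- layer$buffers$running_var
      }
      istd <- 1 / sqrt(va + cf$eps)
      xhat <- sweep(sweep(m_, 2, mu, "-"), 2, istd, "*")
      outm <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2,
                    layer$params$beta, "+")
      out <- aperm(array(outm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(out = out,
           cache = list(xhat = xhat, istd = istd, dims = d,
                        training = training),
           layer = layer)
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0), layer = layer),
    maxpool2d = {
      d <- dim(x)
      io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
      a <- x[io, jo, , , drop = FALSE]
      b <- x[io + 1L, jo, , , drop = FALSE]
      cc <- x[io, jo + 1L, , , drop = FALSE]
      dd <- x[io + 1L, jo + 1L, , , drop = FALSE]
      out <- pmax(a, b, cc, dd)
      list(out = out, cache = list(a = a, b = b, cc = cc, dd = dd, out = out,
                                   in_dim = d), layer = layer)
    },
    gap = {
      d <- dim(x)
      cm <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
      out <- array(cm, c(1L, 1L, d[3], d[4]))
      list(out = out, cache = list(in_dim = d), layer = layer)
    },
    linear = {
      cf <- layer$config
      d <- dim(x)
      n <- if (length(d) == 4L) d[4] else d[2]
      xm <- matrix(x, cf$in_features, n)
      out <- layer$params$weight %*% xm + layer$params$bias
      list(out = out, cache = list(xm = xm, in_dim = d), layer = layer)
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

## ---- backward --------------------------------------------------------------

# returns list(grad_in, grads) where grads matches layer$params
cr_backward_layer <- function(layer, grad_out, cache) {
  switch(layer$kind,
    conv2d = {
      cf <- layer$config
      d <- cache$in_dim
      g_mat <- matrix(aperm(grad_out, c(1, 2, 4, 3)),
                      d[1] * d[2] * d[4], cf$out_ch)
      g_w <- crossprod(cache$P, g_mat)
      g_b <- colSums(g_mat)
      g_patch <- tcrossprod(g_mat, layer$params$weight)
      hp <- d[1] + 2L * cf$pad; wp <- d[2] + 2L * cf$pad
      gxp <- numeric(hp * wp * cf$in_ch * d[4])
      idx <- cache$idx
      for (j in seq_len(ncol(idx))) {
        jj <- idx[, j]
        gxp[jj] <- gxp[jj] + g_patch[, j]
      }
      gxp <- array(gxp, c(hp, wp, cf$in_ch, d[4]))
      gx <- if (cf$pad > 0L)
        gxp[cf$pad + seq_len(d[1]), cf$pad + seq_len(d[2]), , , drop = FALSE]
      else gxp
      list(grad_in = gx, grads = list(weight = g_w, bias = g_b))
    },
    batchnorm2d = {
      d <- cache$dims
      gm <- matrix(aperm(grad_out, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
      g_gamma <- colSums(gm * cache$xhat)
      g_beta <- colSums(gm)
      gxhat <- sweep(gm, 2, layer$params$gamma, "*")
      if (isTRUE(cache$training)) {
        m_el <- nrow(gm)
        t1 <- sweep(gxhat, 2, colMeans(gxhat), "-")
        t2 <- sweep(cache$xhat, 2, colMeans(gxhat * cache$xhat), "*")
        gxm <- sweep(t1 - t2, 2, cache$istd, "*")
      } else {
        gxm <- sweep(gxhat, 2, cache$istd, "*")
      }
      gx <- aperm(array(gxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(grad_in = gx, grads = list(gamma = g_gamma, beta = g_beta))
    },
    relu = list(grad_in = grad_out * cache$mask, grads = list()),
    maxpool2d = {
      d <- cache$in_dim
      io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
      ma <- cache$a == cache$out
      mb <- (cache$b == cache$out) & !ma
      mc <- (cache$cc == cache$out) & !ma & !mb
      md <- !ma & !mb & !mc
      gx <- array(0, d)
      gx[io, jo, , ] <- grad_out * ma
      gx[io + 1L, jo, , ] <- grad_out * mb
      gx[io, jo + 1L, , ] <- grad_out * mc
      gx[io + 1L, jo + 1L, , ] <- grad_out * md
      list(grad_in = gx, grads = list())
    },
    gap = {
      d <- cache$in_dim
      per <- as.vector(grad_out) / (d[1] * d[2])
      gx <- array(rep(per, each = d[1] * d[2]), d)
      list(grad_in = gx, grads = list())
    },
    linear = {
      g <- grad_out
      if (is.null(dim(g))) g <- matrix(g, ncol = 1L)
      g_w <- tcrossprod(g, cache$xm)
      g_b <- rowSums(g)
      gx <- array(crossprod(layer$params$weight, g), cache$in_dim)
      list(grad_in = gx, grads = list(weight = g_w, bias = g_b))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

## ---- sequential model ------------------------------------------------------

#' Assemble a sequential CNN from engine layers
#'
#' Builds the plain sequential model container used throughout the package:
#' an ordered list of engine layers plus the expected single-image input
#' shape. All capture, CAM and faithfulness machinery operates on these
#' handles (or on anything that implements the same small S3 contract).
#'
#' @param layers list of engine layers (see [make_tiny_cnn()] for the stock
#'   fixture architecture).
#' @param input_shape integer vector `c(H, W, C)` of a single input image.
#' @param name model label used in provenance output.
#' @return an object of class `cr_model`.
#' @keywords internal
cr_sequential <- function(layers, input_shape, name = "model") {
  stopifnot(length(layers) >= 1L, length(input_shape) == 3L)
  nms <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("layer names must be unique", call. = FALSE)
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 name = name),
            class = "cr_model")
}

#' @export
print.cr_model <- function(x, ...) {
  cat("<cr_model> ", x$name, ": ", length(x$layers), " layers, input ",
      paste(x$input_shape, collapse = "x"), "\n", sep = "")
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%02d] %-10s %s (%d params)\n", i - 1L, l$kind, l$name,
                cr_layer_param_count(l)))
  }
  invisible(x)
}

cr_layer_param_count <- function(layer) {
  sum(vapply(layer$params, length, 1L))
}

# full forward pass; records every layer output and cache
cr_forward <- function(model, x, training = FALSE, from = 1L) {
  x <- cr_as_batch(x)
  outs <- vector("list", length(model$layers))
  caches <- vector("list", length(model$layers))
  for (i in seq(from, length(model$layers))) {
    st <- cr_forward_layer(model$layers[[i]], x, training = training)
    outs[[i]] <- st$out
    caches[[i]] <- st$cache
    model$layers[[i]] <- st$layer
    x <- st$out
  }
  list(outs = outs, caches = caches, logits = x, model = model)
}

# forward from layer `from` given that layer's *input*; no recording
cr_forward_from <- function(model, from, x) {
  for (i in seq(from, length(model$layers))) {
    x <- cr_forward_layer(model$layers[[i]], x, training = FALSE)$out
  }
  x
}

cr_logits <- function(model, x) {
  lg <- cr_forward(model, x)$logits
  if (is.matrix(lg) && ncol(lg) == 1L) drop(lg) else lg
}

cr_softmax <- function(z) {
  if (is.matrix(z)) {
    z <- sweep(z, 2, apply(z, 2, max), "-")
    e <- exp(z)
    sweep(e, 2, colSums(e), "/")
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

cr_probs <- function(model, x) cr_softmax(cr_logits(model, x))

# backward pass from an arbitrary gradient at the logits; returns gradients of
# every layer *output* plus parameter gradients
cr_backward <- function(model, fwd, grad_logits) {
  n <- length(model$layers)
  grad_acts <- vector("list", n)
  grad_params <- vector("list", n)
  g <- grad_logits
  lgdim <- dim(fwd$outs[[n]])
  if (is.null(dim(g))) dim(g) <- lgdim
  for (i in seq(n, 1L)) {
    grad_acts[[i]] <- g
    bk <- cr_backward_layer(model$layers[[i]], g, fwd$caches[[i]])
    grad_params[[i]] <- bk$grads
    g <- bk$grad_in
  }
  list(grad_acts = grad_acts, grad_params = grad_params, grad_input = g)
}

## ---- parameter utilities ---------------------------------------------------

cr_param_count <- function(model) {
  sum(vapply(model$layers, cr_layer_param_count, 1L))
}

cr_param_vector <- function(model) {
  unlist(lapply(model$layers, function(l) lapply(l$params, as.vector)),
         use.names = FALSE)
}

cr_param_checksum <- function(model) {
  v <- cr_param_vector(model)
  c(sum = sum(v), sumsq = sum(v^2))
}

cr_set_params <- function(model, flat) {
  pos <- 1L
  for (i in seq_along(model$layers)) {
    for (p in names(model$layers[[i]]$params)) {
      cur <- model$layers[[i]]$params[[p]]
      len <- length(cur)
      seg <- flat[pos:(pos + len - 1L)]
      if (is.matrix(cur)) dim(seg) <- dim(cur)
      model$layers[[i]]$params[[p]] <- seg
      pos <- pos + len
    }
  }
  stopifnot(pos - 1L == length(flat))
  model
}
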