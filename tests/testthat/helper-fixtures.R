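# Shared fixtures. The trained CNN and its dataset take ~1 minute to build,
# so they are memoized for the whole test run. Everything is seeded.

.fixture_cache <- new.env(parent = emptyenv())

default_split <- function() {
  if (is.null(.fixture_cache$split)) {
    .fixture_cache$split <- make_dataset(n = 400L, contrast = 0.4, seed = 1L)
  }
  .fixture_cache$split
}

trained_fixture <- function() {
  if (is.null(.fixture_cache$trained)) {
    fit <- train_fixture(make_tiny_cnn(seed = 1L), default_split(),
                         epochs = 10L, seed = 1L)
    .fixture_cache$trained <- fit
  }
  .fixture_cache$trained
}

lesion_test_samples <- function(n = 10L) {
  les <- Filter(function(s) s$label == 1L, default_split()$test)
  les[seq_len(min(n, length(les)))]
}

# hand-built one-layer model y = w * GAP(A) used by closed-form CAM oracles:
# identity 1x1 conv -> global average pool -> linear(weight w, no bias shift)
gap_linear_model <- function(h = 6L, w_out = 1, n_class = 1L) {
  conv <- camroad:::cr_conv2d(1L, 1L, kernel = 1L, pad = 0L, name = "conv")
  conv$params$weight[1, 1] <- 1
  fc <- camroad:::cr_linear(1L, n_class, name = "fc")
  fc$params$weight[] <- w_out
  camroad:::cr_sequential(list(conv, camroad:::cr_gap("gap"), fc),
                          c(h, h, 1L), name = "gap_linear")
}

# two-logit model with spatially disjoint class evidence: 1x1 conv with
# channel weights (+1, -1), ReLU, GAP, identity linear head. On an image
# that is positive in the left half and negative in the right half, class 1
# evidence lives left and class 2 evidence lives right.
two_half_model <- function(h = 8L) {
  conv <- camroad:::cr_conv2d(1L, 2L, kernel = 1L, pad = 0L, name = "conv")
  conv$params$weight[1, ] <- c(1, -1)
  fc <- camroad:::cr_linear(2L, 2L, name = "fc")
  fc$params$weight[] <- diag(2)
  camroad:::cr_sequential(
    list(conv, camroad:::cr_relu("relu"), camroad:::cr_gap("gap"), fc),
    c(h, h, 1L), name = "two_half")
}

two_half_image <- function(h = 8L) {
  img <- matrix(-1, h, h)
  img[, seq_len(h %/% 2L)] <- 1
  img
}

# dense brute-force oracle for the neighbor-mean imputation linear system
dense_impute_oracle <- function(image, mask) {
  h <- nrow(image); w <- ncol(image)
  idx <- which(mask)
  n <- length(idx)
  A <- matrix(0, n, n); b <- numeric(n)
  for (r in seq_len(n)) {
    i <- (idx[r] - 1L) %% h + 1L
    j <- (idx[r] - 1L) %/% h + 1L
    for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
      if (nb[1] < 1L || nb[1] > h || nb[2] < 1L || nb[2] > w) next
      A[r, r] <- A[r, r] + 1
      fl <- (nb[2] - 1L) * h + nb[1]
      pos <- match(fl, idx)
      if (!is.na(pos)) A[r, pos] <- A[r, pos] - 1 else b[r] <- b[r] + image[fl]
    }
  }
  out <- image
  out[idx] <- solve(A, b)
  out
}
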