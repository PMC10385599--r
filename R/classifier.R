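#' Classifier training specification
#'
#' Hyperparameters for the pluggable binary nodule classifier used by the
#' pruning harness.  Defaults follow the study protocol: base training at a
#' learning rate of 5e-4 for 50 epochs, then 10 fine-tuning epochs at 1e-5,
#' binary cross-entropy loss, and checkpointing at minimum validation loss
#' across both phases.
#'
#' Two architectures are available.  `tiny_cnn` is a small fixed
#' convolutional feature extractor (mean pooling of the resized image plus
#' a difference-of-Gaussians blob channel that responds to nodule-scale
#' bright spots) followed by a trained logistic head.  `pretrained_backbone`
#' mimics a frozen-backbone transfer setup: a fixed, seeded 5x5 filter bank
#' with ReLU and global pooling feeds the same trained head (pooling ->
#' dense sigmoid).
#'
#' @param architecture `"tiny_cnn"` or `"pretrained_backbone"`.
#' @param learning_rate base-phase Adam step size (> 0).
#' @param epochs base training epochs (>= 1).
#' @param fine_tune_epochs fine-tuning epochs at `fine_tune_learning_rate`.
#' @param fine_tune_learning_rate fine-tuning Adam step size (> 0).
#' @param batch_size minibatch size (default 8; the tiny head sees small
#'   datasets and needs several updates per epoch).
#' @param seed integer RNG seed.
#' @param decision_threshold probability cut separating nodule calls, in
#'   `(0, 1)`.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(architecture = c("tiny_cnn", "pretrained_backbone"),
                            learning_rate = 0.0005, epochs = 50L,
                            fine_tune_epochs = 10L,
                            fine_tune_learning_rate = 0.00001,
                            batch_size = 8L, seed = 1L,
                            decision_threshold = 0.5) {
  architecture <- match.arg(architecture)
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  if (learning_rate <= 0 || fine_tune_learning_rate <= 0) {
    stop("learning rates must be positive", call. = FALSE)
  }
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop("`decision_threshold` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(architecture = architecture, learning_rate = learning_rate,
         epochs = as.integer(epochs),
         fine_tune_epochs = as.integer(fine_tune_epochs),
         fine_tune_learning_rate = fine_tune_learning_rate,
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         decision_threshold = decision_threshold),
    class = "classifier_spec"
  )
}

# Fixed "pretrained" 5x5 filter bank shared by every pretrained_backbone
# model (seeded once, constant across the package).
backbone_filters <- function(n = 6L, k = 5L) {
  withr::with_seed(424243L, {
    lapply(seq_len(n), function(i) {
      f <- matrix(stats::rnorm(k * k), k, k)
      f - mean(f)
    })
  })
}

#' Extract classifier features from a processed image
#'
#' Images of any size are bilinearly resized to a 64x64 working grid (the
#' phantom's nodule diameter is 3/32 of the image side, so nodules land at
#' a fixed ~6 px scale there).  `tiny_cnn` features are the 8x8
#' mean-pooled image (64), a 4x4 pooled bright-blob channel (16) and five
#' global statistics.  The blob channel is a determinant-of-Hessian
#' detector at the nodule scale, zeroed where either principal curvature is
#' non-negative: it responds to isotropic bright blobs but not to edges
#' (one-directional curvature) or rib-like ridges (near-zero determinant),
#' which is what a convolutional nodule classifier learns to do.
#' `pretrained_backbone` features are global mean/max ReLU responses of a
#' fixed seeded filter bank plus the same global statistics.
#'
#' @param image matrix in `[0,1]` or `radiograph`.
#' @param architecture as in [classifier_spec()].
#' @return numeric feature vector.
#' @export
classifier_features <- function(image, architecture = "tiny_cnn") {
  m <- rg_normalize(image)
  if (length(m) == 0L || any(dim(m) == 0L)) stop("empty image", call. = FALSE)
  z <- resize_bilinear(m, 64L, 64L)
  doh <- blob_response(z, sigma = 1.5)
  ctr <- doh[7:58, 7:58]
  glob <- c(mean(z), stats::sd(z), max(ctr), stats::quantile(ctr, 0.999),
            mean(ctr))
  if (architecture == "tiny_cnn") {
    c(as.vector(pool_mean(z, 8L)), as.vector(pool_mean(doh, 4L)), glob)
  } else {
    z32 <- resize_bilinear(m, 32L, 32L)
    resp <- unlist(lapply(backbone_filters(), function(f) {
      a <- pmax(filter2_same(z32, f, pad = "replicate"), 0)
      c(mean(a), max(a))
    }))
    c(resp, glob)
  }
}

pool_mean <- function(x, g) {
  f <- nrow(x) / g
  out <- matrix(0, g, g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    out[i, j] <- mean(x[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  }
  out
}

# Bright-blob response map: determinant of the Hessian of the
# Gaussian-smoothed image, kept only where both principal curvatures are
# negative (a bright, locally isotropic maximum).  Responses are further
# restricted to the eroded non-black support so that the hard boundary of a
# masked lung field (background exactly 0) cannot fire the detector; a
# blob is only counted where its whole neighborhood is visible.
blob_response <- function(z, sigma = 1.5) {
  b <- blur_gauss(z, sigma)
  dxx <- filter2_same(b, matrix(c(1, -2, 1), 1, 3), pad = "replicate")
  dyy <- filter2_same(b, matrix(c(1, -2, 1), 3, 1), pad = "replicate")
  dxy <- filter2_same(b, matrix(c(0.25, 0, -0.25, 0, 0, 0, -0.25, 0, 0.25), 3, 3),
                      pad = "replicate")
  doh <- ifelse(dxx < 0 & dyy < 0, dxx * dyy - dxy^2, 0)
  support <- erode_box((z > 0) + 0L, 9L)
  support[c(1:5, (nrow(z) - 4):nrow(z)), ] <- 0L
  support[, c(1:5, (ncol(z) - 4):ncol(z))] <- 0L
  doh * support
}

#' Train the binary nodule classifier head
#'
#' Logistic head over [classifier_features()], trained with minibatch
#' stochastic gradient descent (momentum 0.9, zero-initialized weights)
#' under binary cross-entropy: `epochs` at `learning_rate`, then
#' `fine_tune_epochs` at `fine_tune_learning_rate`.  Validation loss is
#' computed after every epoch and the returned weights are the checkpoint
#' with minimum validation loss over both phases.  Fully deterministic
#' given `spec$seed` (+ `seed_offset`).
#'
#' @param X feature matrix (rows = images).
#' @param y numeric 0/1 labels (1 = nodule).
#' @param spec a `classifier_spec`.
#' @param val_X,val_y validation split (required; used for checkpointing).
#' @param seed_offset added to `spec$seed` for e.g. per-fold/per-round
#'   retraining schedules.
#' @return object of class `nodule_classifier` with weights, feature
#'   standardization, loss curves and checkpoint metadata.
#' @export
train_classifier <- function(X, y, spec, val_X, val_y, seed_offset = 0L) {
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("training data contain a single class", call. = FALSE)
  bce <- function(p, yy) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(yy * log(p) + (1 - yy) * log(1 - p))
  }
  withr::with_seed(derive_seed(spec$seed, 7919L + seed_offset), {
    mu <- colMeans(X); sdv <- pmax(apply(X, 2, stats::sd), 1e-8)
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    Vs <- sweep(sweep(val_X, 2, mu), 2, sdv, "/")
    p_dim <- ncol(Xs); n <- nrow(Xs)
    w <- numeric(p_dim); b <- 0
    uw <- numeric(p_dim); ub <- 0
    momentum <- 0.9
    schedule <- c(rep(spec$learning_rate, spec$epochs),
                  rep(spec$fine_tune_learning_rate, spec$fine_tune_epochs))
    train_curve <- val_curve <- numeric(length(schedule))
    best <- list(loss = Inf, w = w, b = b, epoch = 0L)
    for (ep in seq_along(schedule)) {
      lr <- schedule[ep]
      ord <- sample.int(n)
      starts <- seq(1L, n, by = spec$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + spec$batch_size - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]; yb <- y[idx]
        pr <- 1 / (1 + exp(-(drop(Xb %*% w) + b)))
        gw <- drop(crossprod(Xb, pr - yb)) / length(idx)
        gb <- mean(pr - yb)
        uw <- momentum * uw - lr * gw; ub <- momentum * ub - lr * gb
        w <- w + uw; b <- b + ub
      }
      train_curve[ep] <- bce(1 / (1 + exp(-(drop(Xs %*% w) + b))), y)
      vl <- bce(1 / (1 + exp(-(drop(Vs %*% w) + b))), val_y)
      val_curve[ep] <- vl
      if (vl < best$loss) best <- list(loss = vl, w = w, b = b, epoch = ep)
    }
    structure(
      list(weights = best$w, bias = best$b, center = mu, scale = sdv,
           spec = spec, train_curve = train_curve, val_curve = val_curve,
           best_epoch = best$epoch,
           decision_threshold = spec$decision_threshold),
      class = "nodule_classifier"
    )
  })
}

#' @export
print.nodule_classifier <- function(x, ...) {
  cat(sprintf("<nodule_classifier> %s head, %d features, min val BCE %.4f (epoch %d)\n",
              x$spec$architecture, length(x$weights),
              min(x$val_curve), x$best_epoch))
  invisible(x)
}

#' Nodule probability scores
#' @param model a `nodule_classifier`.
#' @param X feature matrix from [classifier_features()].
#' @return numeric vector of nodule-class probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  as.numeric(1 / (1 + exp(-(drop(Xs %*% model$weights) + model$bias))))
}
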