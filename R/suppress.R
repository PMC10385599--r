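#' Train the rib-suppression operator
#'
#' The default suppressor is a small learned convolution that predicts the
#' additive rib component of an image from its local neighbourhood and
#' subtracts it.  Two input channels feed a pair of 2-D kernels: the raw
#' image patch, and a horizontally smoothed copy that preserves elongated,
#' quasi-horizontal rib bands while diluting isotropic structure (nodules,
#' markers), which biases the predictor toward ribs.  The kernels are
#' fitted to matched (rib, rib-free) training pairs by conjugate-gradient
#' least squares, one iteration per epoch, from a zero start -- the
#' training loss decreases monotonically and the fit is exactly
#' reproducible given `seed` (which drives patch sampling).  At inference
#' the rib estimate is rectified at zero (the rib layer is non-negative)
#' before subtraction.
#'
#' Because the phantom's ribs are an exact additive layer, the regression
#' target is exact; on real radiographs the operator slot is pluggable.
#'
#' @param pairs list of `list(input =, target =)` matrices in `[0,1]` with
#'   equal shapes (>= 8 pairs).
#' @param epochs conjugate-gradient iterations (>= 1).
#' @param seed integer RNG seed (patch sampling).
#' @param kernel_size `c(rows, cols)` of each learned kernel; should span
#'   roughly one rib period vertically.
#' @param samples_per_image pixel positions sampled per training image.
#' @param smooth_halfwidth half-width of the horizontal smoothing window
#'   for the second input channel, pixels.
#' @return object of class `rib_suppressor` with elements `kernel`
#'   (raw-channel), `kernel_smooth`, `bias`, `smooth_halfwidth`,
#'   `loss_curve`, `epochs`, `seed`, `native_size`, `resample`.
#' @export
train_suppressor <- function(pairs, epochs = 30L, seed = 1L,
                             kernel_size = c(15L, 7L),
                             samples_per_image = 400L,
                             smooth_halfwidth = 6L) {
  if (length(pairs) == 0L) stop("empty training set", call. = FALSE)
  if (length(pairs) < 8L) stop("need at least 8 training pairs", call. = FALSE)
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  dims <- dim(pairs[[1]]$input)
  for (p in pairs) {
    if (!all(dim(p$input) == dims) || !all(dim(p$target) == dims)) {
      stop("all training pairs must share one shape", call. = FALSE)
    }
  }
  kr <- kernel_size[1]; kc <- kernel_size[2]
  ar <- kr %/% 2L; ac <- kc %/% 2L
  hsm <- function(m) {
    filter2_same(m, matrix(1 / (2 * smooth_halfwidth + 1), 1,
                           2 * smooth_halfwidth + 1), pad = "replicate")
  }
  withr::with_seed(derive_seed(seed, 77L), {
    X_list <- list(); y_list <- list()
    for (p in pairs) {
      nr <- nrow(p$input); nc <- ncol(p$input)
      rs <- sample((ar + 1L):(nr - (kr - 1L - ar)), samples_per_image,
                   replace = TRUE)
      cs <- sample((ac + 1L):(nc - (kc - 1L - ac)), samples_per_image,
                   replace = TRUE)
      H <- hsm(p$input)
      X <- matrix(0, samples_per_image, 2L * kr * kc)
      col <- 0L
      for (src in list(p$input, H)) {
        for (dv in (-ac):(kc - 1L - ac)) {
          for (du in (-ar):(kr - 1L - ar)) {
            col <- col + 1L
            X[, col] <- src[cbind(rs + du, cs + dv)]
          }
        }
      }
      X_list[[length(X_list) + 1L]] <- X
      y_list[[length(y_list) + 1L]] <- (p$input - p$target)[cbind(rs, cs)]
    }
    X <- cbind(1, do.call(rbind, X_list))
    y <- unlist(y_list)
    n <- nrow(X); p_dim <- ncol(X)
    G <- crossprod(X) / n + diag(1e-8, p_dim)
    v <- drop(crossprod(X, y)) / n
    w <- numeric(p_dim)
    r <- v - drop(G %*% w); d <- r
    loss_curve <- numeric(epochs)
    for (it in seq_len(epochs)) {
      loss_curve[it] <- mean((drop(X %*% w) - y)^2)
      rr <- drop(crossprod(r))
      if (rr < 1e-24) {
        if (it < epochs) loss_curve[(it + 1L):epochs] <- loss_curve[it]
        break
      }
      Gd <- drop(G %*% d)
      alpha <- rr / drop(crossprod(d, Gd))
      w <- w + alpha * d
      r2 <- r - alpha * Gd
      beta <- drop(crossprod(r2)) / rr
      d <- r2 + beta * d
      r <- r2
    }
    npx <- kr * kc
    structure(
      list(kernel = matrix(w[2:(npx + 1L)], kr, kc),
           kernel_smooth = matrix(w[(npx + 2L):(2L * npx + 1L)], kr, kc),
           bias = w[1], smooth_halfwidth = as.integer(smooth_halfwidth),
           loss_curve = loss_curve, epochs = as.integer(epochs),
           seed = as.integer(seed), native_size = dims, resample = FALSE),
      class = "rib_suppressor"
    )
  })
}

#' @export
print.rib_suppressor <- function(x, ...) {
  cat(sprintf("<rib_suppressor> 2x %dx%d learned kernels, %d epochs, final MSE %.2e\n",
              nrow(x$kernel), ncol(x$kernel), x$epochs,
              x$loss_curve[length(x$loss_curve)]))
  invisible(x)
}

rib_estimate <- function(m, model) {
  H <- filter2_same(m, matrix(1 / (2 * model$smooth_halfwidth + 1), 1,
                              2 * model$smooth_halfwidth + 1),
                    pad = "replicate")
  pmax(filter2_same(m, model$kernel, pad = "replicate") +
         filter2_same(H, model$kernel_smooth, pad = "replicate") +
         model$bias, 0)
}

#' Suppress ribs in a radiograph
#'
#' Subtracts the model's predicted rib component.  Output has the same
#' shape and range as the input; no label or mask information is consulted.
#' When the model's `resample` flag is set, images whose shape differs from
#' the model's native training size are bilinearly resampled to the native
#' size for prediction and back; otherwise any image at least as large as
#' the kernel is processed directly (the kernel is translation invariant).
#'
#' @param image `radiograph`, matrix in `[0,1]`, or a list of either (a
#'   batch; order is preserved).
#' @param model a trained `rib_suppressor`.
#' @return suppressed image(s), same type/order as the input.
#' @export
suppress_ribs <- function(image, model) {
  if (is.list(image) && !is_radiograph(image)) {
    return(lapply(image, suppress_ribs, model = model))
  }
  m <- rg_normalize(image)
  kdim <- dim(model$kernel)
  if (any(dim(m) < kdim)) {
    if (!isTRUE(model$resample)) {
      stop("image smaller than the suppression kernel and resampling is disabled",
           call. = FALSE)
    }
    orig <- dim(m)
    mn <- resize_bilinear(m, model$native_size[1], model$native_size[2])
    out <- clip01(mn - rib_estimate(mn, model))
    out <- resize_bilinear(out, orig[1], orig[2])
  } else {
    out <- clip01(m - rib_estimate(m, model))
  }
  if (is_radiograph(image)) {
    rg_rewrap(out * (2^image$bit_depth - 1), image)
  } else {
    out
  }
}
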