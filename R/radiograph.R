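#' Radiograph image container
#'
#' A `radiograph` wraps a 2-D grayscale pixel matrix together with its bit
#' depth, an acquisition-source identifier and an optional class label.
#' Pixels are stored in native units, i.e. within `[0, 2^bit_depth - 1]`;
#' they may be fractional after processing and are quantized only when
#' written to disk.  The pixel convention throughout the package is 0-based
#' row/column indexing with the origin at the top-left corner.
#'
#' @param pixels numeric matrix of intensities, at least 16x16.
#' @param bit_depth integer, one of 8, 12 or 16.
#' @param source_id optional character identifier of the acquisition source.
#' @param label optional class label, `"nodule"` or `"non-nodule"`.
#' @return an object of class `radiograph`.
#' @export
radiograph <- function(pixels, bit_depth = 8L, source_id = NA_character_,
                       label = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 16L || ncol(pixels) < 16L) {
    stop("radiograph must be at least 16x16 pixels", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    stop("`bit_depth` must be 8, 12 or 16", call. = FALSE)
  }
  L <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > L) {
    stop("pixel values must lie within [0, 2^bit_depth - 1]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         source_id = source_id, label = label),
    class = "radiograph"
  )
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %dx%d, %d-bit, source=%s, label=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              ifelse(is.na(x$source_id), "?", x$source_id),
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

is_radiograph <- function(x) inherits(x, "radiograph")

# Pull the pixel matrix out of a radiograph or pass a bare matrix through.
rg_pixels <- function(x) {
  if (is_radiograph(x)) x$pixels else x
}

# Rebuild an object of the same type as `template` around new pixels.
rg_rewrap <- function(pixels, template) {
  if (is_radiograph(template)) {
    out <- template
    out$pixels <- pixels
    out
  } else {
    pixels
  }
}

rg_bit_depth <- function(x, default = 8L) {
  if (is_radiograph(x)) x$bit_depth else as.integer(default)
}

#' Convert a radiograph to a normalized [0,1] matrix
#' @param x a `radiograph` or numeric matrix already in `[0,1]`.
#' @return numeric matrix with values in `[0,1]`.
#' @export
rg_normalize <- function(x) {
  if (is_radiograph(x)) x$pixels / (2^x$bit_depth - 1) else x
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Read a grayscale PNG as a radiograph
#'
#' 8- and 16-bit grayscale PNG files are supported.  Color PNGs are reduced
#' to their first channel.
#'
#' @param path file path.
#' @param bit_depth bit depth to interpret the file at (8 or 16).
#' @return a `radiograph`.
#' @export
read_png_radiograph <- function(path, bit_depth = 8L) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  L <- 2^bit_depth - 1
  radiograph(round(a * L), bit_depth = as.integer(bit_depth))
}

#' Write a radiograph (or [0,1] matrix) to an 8-bit grayscale PNG
#' @param x `radiograph` or numeric matrix in `[0,1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png_radiograph <- function(x, path) {
  m <- if (is_radiograph(x)) x$pixels / (2^x$bit_depth - 1) else x
  png::writePNG(clip01(m), path)
  invisible(path)
}

# ---- small numerical helpers shared across operators -----------------------

# Sliding-window box sums via a summed-area table.  The window for output
# pixel (i, j) covers rows i-a .. i+b and columns likewise, with
# a = floor(k/2) and b = k - 1 - a (OpenCV-style anchor for even k).
# `pad` is the value assumed outside the image.
box_sum <- function(m, k, pad = 0) {
  nr <- nrow(m); nc <- ncol(m)
  a <- k %/% 2L; b <- k - 1L - a
  p <- matrix(pad, nr + k - 1L, nc + k - 1L)
  p[(a + 1L):(a + nr), (a + 1L):(a + nc)] <- m
  s <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed SAT
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  i1 <- 1L:nr; j1 <- 1L:nc
  s[i1 + k, j1 + k, drop = FALSE] - s[i1, j1 + k, drop = FALSE] -
    s[i1 + k, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
}

# Binary box dilation / erosion with the anchor convention of box_sum().
dilate_box <- function(mask, k) (box_sum(mask, k, pad = 0) > 0.5) + 0L
erode_box  <- function(mask, k) (box_sum(mask, k, pad = 1) > k * k - 0.5) + 0L

# 2-D cross-correlation with `kern`, "same" output size, replicate or zero
# padding, computed by FFT.
filter2_same <- function(x, kern, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  kr <- nrow(kern); kc <- ncol(kern)
  ar <- kr %/% 2L; br <- kr - 1L - ar
  ac <- kc %/% 2L; bc <- kc - 1L - ac
  nr <- nrow(x); nc <- ncol(x)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  if (pad == "replicate") {
    src_r <- c(rep(1L, ar), 1L:nr, rep(nr, br))
    src_c <- c(rep(1L, ac), 1L:nc, rep(nc, bc))
    xp <- x[src_r, src_c, drop = FALSE]
  } else {
    xp <- matrix(0, pr, pc)
    xp[(ar + 1L):(ar + nr), (ac + 1L):(ac + nc)] <- x
  }
  # correlation = convolution with the flipped kernel
  kf <- kern[kr:1L, kc:1L, drop = FALSE]
  kp <- matrix(0, pr, pc)
  kp[1L:kr, 1L:kc] <- kf
  conv <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / (pr * pc)
  conv[(kr):(kr + nr - 1L), (kc):(kc + nc - 1L), drop = FALSE]
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate padding.
blur_gauss <- function(x, sigma) {
  k1 <- gauss_kernel1d(sigma)
  filter2_same(x, outer(k1, k1), pad = "replicate")
}

# Bilinear resize via separable interpolation-weight matrices.
bilinear_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  frac <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  w <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  w[cbind(idx, lo + 1)] <- w[cbind(idx, lo + 1)] + (1 - frac)
  w[cbind(idx, hi + 1)] <- w[cbind(idx, hi + 1)] + frac
  w
}

#' Bilinear image resize
#' @param x numeric matrix.
#' @param out_h,out_w output height and width in pixels.
#' @return numeric matrix of size `out_h` x `out_w`.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  wr <- bilinear_weights(nrow(x), out_h)
  wc <- bilinear_weights(ncol(x), out_w)
  wr %*% x %*% t(wc)
}

# Derive a per-task seed from a base seed and a counter, kept below 2^31.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %% 2147483629)
}
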