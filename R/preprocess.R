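#' Global histogram equalization
#'
#' Remaps gray levels through the empirical CDF over the full
#' `2^bit_depth`-bin histogram:
#' `v -> round((cdf(v) - cdf_min) / (1 - cdf_min) * (L - 1))` with
#' `L = 2^bit_depth`.  The mapping is monotone non-decreasing, so pixel
#' rank order is always preserved.  Constant images are returned unchanged
#' (the CDF is degenerate and the normalizer would be zero).
#'
#' Equalization is global and applied once, before any masking or cropping;
#' a masked image's black background would otherwise dominate the
#' histogram.
#'
#' @param image a `radiograph`, or a numeric matrix in `[0,1]` which is
#'   treated as `bit_depth`-bit data.
#' @param bit_depth bins to use when `image` is a bare matrix.
#' @return equalized image of the same type as the input.
#' @export
equalize_histogram <- function(image, bit_depth = 8L) {
  m <- rg_pixels(image)
  if (length(m) == 0L) stop("empty image", call. = FALSE)
  bd <- rg_bit_depth(image, bit_depth)
  L <- 2L^bd
  if (is_radiograph(image)) {
    v <- round(m)
  } else {
    v <- round(clip01(m) * (L - 1))
  }
  if (min(v) == max(v)) return(image)   # degenerate constant image
  counts <- tabulate(v + 1L, nbins = L)
  cdf <- cumsum(counts) / length(v)
  cdf_min <- cdf[min(v) + 1L]
  map <- round((cdf - cdf_min) / (1 - cdf_min) * (L - 1))
  out <- matrix(map[v + 1L], nrow(m), ncol(m))
  if (is_radiograph(image)) rg_rewrap(out, image) else out / (L - 1)
}

#' Apply a binary lung mask to an image
#'
#' Keeps pixels where the mask is foreground and zeroes everything else
#' (non-lung-field pixels carry no nodule signal and are a known source of
#' confounding bias).
#'
#' @param image `radiograph` or numeric matrix.
#' @param mask binary matrix of the same shape.
#' @return masked image, same type as `image`.
#' @export
apply_mask <- function(image, mask) {
  m <- rg_pixels(image)
  if (!all(dim(m) == dim(mask))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  rg_rewrap(m * (mask != 0), image)
}

#' Crop an image to its non-black content
#'
#' Returns the minimal axis-aligned bounding box of non-zero pixels, so the
#' first non-black pixel lies on the border of the output in every
#' direction.  Idempotent.
#'
#' @param image `radiograph` or numeric matrix with at least one non-zero
#'   pixel.
#' @return cropped image, same type as `image`.
#' @export
crop_to_content <- function(image) {
  m <- rg_pixels(image)
  nz_r <- which(rowSums(m != 0) > 0)
  nz_c <- which(colSums(m != 0) > 0)
  if (length(nz_r) == 0L) stop("image has no non-black content", call. = FALSE)
  out <- m[min(nz_r):max(nz_r), min(nz_c):max(nz_c), drop = FALSE]
  if (is_radiograph(image)) {
    x <- image; x$pixels <- out
    # cropped radiographs may fall below the 16 px floor; keep the raw list
    # shape without revalidating the size
    x
  } else {
    out
  }
}

#' Canonical per-image debiasing pipeline
#'
#' Applies the homogenization operators in the fixed canonical order
#' equalize -> segment (mask repair + apply) -> crop -> rib-suppress.
#' Ablation configurations toggle operator inclusion, never order.
#'
#' @param image numeric matrix in `[0,1]` (or `radiograph`).
#' @param mask binary lung mask matching `image` (required when
#'   `segmentation = TRUE`).
#' @param segmentation,cropping,rib_suppression operator toggles; cropping
#'   requires segmentation.
#' @param suppressor a trained [train_suppressor()] model (required when
#'   `rib_suppression = TRUE`).
#' @param repair repair the mask with [repair_mask()] before applying it.
#' @return processed numeric matrix in `[0,1]`.
#' @export
preprocess_image <- function(image, mask = NULL, segmentation = FALSE,
                             cropping = FALSE, rib_suppression = FALSE,
                             suppressor = NULL, repair = TRUE) {
  if (cropping && !segmentation) {
    stop("cropping is only applied in combination with segmentation", call. = FALSE)
  }
  m <- rg_normalize(image)
  m <- equalize_histogram(m)
  if (segmentation) {
    if (is.null(mask)) stop("segmentation requested but no mask supplied", call. = FALSE)
    if (repair) mask <- repair_mask(mask)
    m <- apply_mask(m, mask)
    if (cropping) m <- crop_to_content(m)
  }
  if (rib_suppression) {
    if (is.null(suppressor)) stop("rib suppression requested but no model supplied", call. = FALSE)
    m <- suppress_ribs(m, suppressor)
  }
  m
}
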