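#' Connected components of a binary mask
#'
#' Foreground components use 8-connectivity and holes (background
#' components not touching the image border) use 4-connectivity, the
#' standard duality that prevents diagonal leaks.
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background), with the
#'   number of components as attribute `n`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask != 0)
  if (length(fg) == 0L) {
    out <- matrix(0L, nr, nc); attr(out, "n") <- 0L; return(out)
  }
  id <- match(seq_len(nr * nc), fg)        # pixel -> vertex index or NA
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- !is.na(id[nb])
    if (any(keep)) {
      edges <- c(edges, rbind(id[fg[ok]][keep], id[nb][keep]))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  out <- matrix(0L, nr, nc)
  out[fg] <- as.integer(memb)
  attr(out, "n") <- max(memb)
  out
}

# Areas of each labelled component, ordered by label.
component_areas <- function(labels) {
  n <- attr(labels, "n")
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

# Hole inventory: background components (4-connectivity) not touching the
# image border.  Returns a list of (label matrix over background, hole
# labels, hole areas).
find_holes <- function(mask) {
  bg_labels <- label_components(1L - (mask != 0), connectivity = 4L)
  n <- attr(bg_labels, "n")
  if (n == 0L) return(list(labels = bg_labels, holes = integer(0), areas = integer(0)))
  border <- unique(c(bg_labels[1, ], bg_labels[nrow(bg_labels), ],
                     bg_labels[, 1], bg_labels[, ncol(bg_labels)]))
  holes <- setdiff(seq_len(n), border[border > 0L])
  areas <- component_areas(bg_labels)[holes]
  list(labels = bg_labels, holes = holes, areas = areas)
}

#' Repair a lung mask
#'
#' Morphological closing with an 8x8 square structuring element, followed
#' by filling of every interior hole (background component not touching the
#' border, 4-connectivity) whose area is below
#' `min_area_fraction * image_area`.  Holes at or above the threshold are
#' preserved.
#'
#' The operator repairs interior mask defects (the pinhole artifacts that
#' segmentation networks leave), so pixels added by the closing are
#' restricted to the input's interior background: the outer lung contour is
#' never dressed, and a clean gold-standard mask passes through unchanged.
#' The output foreground is always a superset of the input foreground.
#'
#' The default minimum-area fraction is 1/16 of the image area.
#'
#' @param mask binary matrix.
#' @param closing_kernel side of the square structuring element, pixels.
#' @param min_area_fraction hole-fill threshold as a fraction of image area,
#'   in `(0, 1]`.
#' @return repaired binary matrix.
#' @export
repair_mask <- function(mask, closing_kernel = 8L, min_area_fraction = 1 / 16) {
  if (min_area_fraction <= 0 || min_area_fraction > 1) {
    stop("`min_area_fraction` must lie in (0, 1]", call. = FALSE)
  }
  m <- (mask != 0) + 0L
  if (closing_kernel > 1L) {
    closed <- erode_box(dilate_box(m, closing_kernel), closing_kernel)
    h0 <- find_holes(m)
    interior <- matrix(0L, nrow(m), ncol(m))
    if (length(h0$holes)) interior[h0$labels %in% h0$holes] <- 1L
    m <- pmax(m, closed * interior)
  }
  h <- find_holes(m)
  thresh <- min_area_fraction * length(m)
  fill <- h$holes[h$areas < thresh]
  if (length(fill)) m[h$labels %in% fill] <- 1L
  m
}

#' Quality-control a repaired lung mask
#'
#' A mask fails QC if it has fewer than two foreground components
#' (8-connectivity) or if the second-largest component is poorly visible,
#' i.e. its area is below `min_minor_ratio` times the largest component's
#' area.  QC-failed images are meant to be excluded from downstream
#' manifests rather than repaired further.
#'
#' @param mask binary matrix (ideally already repaired).
#' @param min_minor_ratio visibility threshold on the second-largest /
#'   largest component area ratio.
#' @return list with `status` (`"pass"`, `"fail_contour_count"` or
#'   `"fail_visibility"`), `component_count` and `area_ratio`.
#' @export
qc_mask <- function(mask, min_minor_ratio = 0.25) {
  labels <- label_components(mask, connectivity = 8L)
  areas <- sort(component_areas(labels), decreasing = TRUE)
  if (length(areas) < 2L) {
    return(list(status = "fail_contour_count",
                component_count = length(areas),
                area_ratio = NA_real_))
  }
  ratio <- areas[2] / areas[1]
  status <- if (ratio < min_minor_ratio) "fail_visibility" else "pass"
  list(status = status, component_count = length(areas), area_ratio = ratio)
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`; by convention two empty masks score 1.
#'
#' @param a,b binary matrices of equal shape.
#' @return similarity in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}

# ---- trainable lung-field segmenter ----------------------------------------

# Per-pixel feature stack: raw intensity, two smoothing scales, relative
# darkness, and normalized coordinate terms that let the logistic boundary
# bend around the two lung fields.
segmenter_features <- function(img) {
  nr <- nrow(img); nc <- ncol(img); s <- max(nr, nc)
  b1 <- blur_gauss(img, max(1, s / 64))
  b2 <- blur_gauss(img, max(2, s / 16))
  R <- matrix(seq_len(nr) - 1, nr, nc) / (nr - 1)
  C <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) / (nc - 1)
  cbind(as.vector(img), as.vector(b1), as.vector(b2),
        as.vector(img - b2),
        as.vector(R), as.vector(R^2),
        as.vector(C), as.vector(C^2),
        as.vector((C - 0.5)^2), as.vector(abs(C - 0.5) * R))
}

#' Train the lung-field segmenter
#'
#' The default segmenter is a per-pixel logistic model over intensity,
#' multi-scale context and coordinate features, fitted by Adam gradient
#' descent on pixels subsampled from the training images each epoch.  It is
#' a pluggable stand-in slot for heavier encoder-decoder segmenters; on the
#' phantom's high-contrast lung fields it is accurate and fully
#' deterministic given `seed`.
#'
#' A validation split (last 25% of the supplied pairs) is scored with the
#' Dice coefficient after every epoch; the returned model is the checkpoint
#' with the best validation Dice.
#'
#' @param pairs list of `list(image =, mask =)` with images in `[0,1]` and
#'   binary gold masks (>= 8 pairs).
#' @param epochs training epochs.
#' @param seed integer RNG seed.
#' @param pixels_per_epoch pixels sampled per epoch across all images.
#' @param learning_rate Adam step size.
#' @param threshold probability cut for [predict_mask()] (ties map to
#'   foreground).
#' @return object of class `lung_segmenter` with the weight vector, the
#'   per-epoch validation `dice_curve`, `best_epoch` and `threshold`.
#' @export
train_segmenter <- function(pairs, epochs = 20L, seed = 1L,
                            pixels_per_epoch = 20000L,
                            learning_rate = 0.05, threshold = 0.5) {
  if (length(pairs) == 0L) stop("empty training set", call. = FALSE)
  if (length(pairs) < 8L) stop("need at least 8 training pairs", call. = FALSE)
  n_val <- max(1L, floor(length(pairs) * 0.25))
  val <- pairs[(length(pairs) - n_val + 1L):length(pairs)]
  trn <- pairs[1:(length(pairs) - n_val)]
  withr::with_seed(derive_seed(seed, 101L), {
    feats <- lapply(trn, function(p) segmenter_features(p$image))
    labs <- lapply(trn, function(p) as.numeric(p$mask != 0))
    X_all <- do.call(rbind, feats)
    y_all <- unlist(labs)
    mu <- colMeans(X_all); sdv <- pmax(apply(X_all, 2, stats::sd), 1e-8)
    Xs <- sweep(sweep(X_all, 2, mu), 2, sdv, "/")
    val_feats <- lapply(val, function(p) {
      sweep(sweep(segmenter_features(p$image), 2, mu), 2, sdv, "/")
    })
    p_dim <- ncol(Xs)
    w <- stats::rnorm(p_dim, sd = 0.01); b <- 0
    mw <- vw <- numeric(p_dim); mb <- vb <- 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
    dice_curve <- numeric(epochs)
    best <- list(dice = -Inf, w = w, b = b, epoch = 0L)
    n <- nrow(Xs)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n, min(pixels_per_epoch, n))
      Xb <- Xs[idx, , drop = FALSE]; yb <- y_all[idx]
      pr <- 1 / (1 + exp(-(drop(Xb %*% w) + b)))
      gw <- drop(crossprod(Xb, pr - yb)) / length(idx)
      gb <- mean(pr - yb)
      t <- t + 1L
      mw <- b1 * mw + (1 - b1) * gw; vw <- b2 * vw + (1 - b2) * gw^2
      mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
      corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
      w <- w - learning_rate * (mw / corr1) / (sqrt(vw / corr2) + eps)
      b <- b - learning_rate * (mb / corr1) / (sqrt(vb / corr2) + eps)
      d <- mean(vapply(seq_along(val), function(i) {
        pv <- 1 / (1 + exp(-(drop(val_feats[[i]] %*% w) + b)))
        pred <- matrix(pv >= threshold, nrow(val[[i]]$mask))
        dice(pred + 0L, val[[i]]$mask)
      }, numeric(1)))
      dice_curve[ep] <- d
      if (d > best$dice) best <- list(dice = d, w = w, b = b, epoch = ep)
    }
    structure(
      list(weights = best$w, bias = best$b, center = mu, scale = sdv,
           threshold = threshold, dice_curve = dice_curve,
           best_epoch = best$epoch, epochs = as.integer(epochs),
           seed = as.integer(seed)),
      class = "lung_segmenter"
    )
  })
}

#' @export
print.lung_segmenter <- function(x, ...) {
  cat(sprintf("<lung_segmenter> per-pixel logistic, best val Dice %.3f (epoch %d/%d)\n",
              max(x$dice_curve), x$best_epoch, x$epochs))
  invisible(x)
}

#' Predict a raw lung mask
#'
#' Applies the segmenter's probability map and threshold; ties at exactly
#' the threshold map to foreground.  The returned mask is unrepaired; run
#' [repair_mask()] and [qc_mask()] downstream.
#'
#' @param model a `lung_segmenter`.
#' @param image matrix in `[0,1]` or `radiograph`, or a list of them
#'   (batch; order preserved).
#' @return binary matrix (or list of them).
#' @export
predict_mask <- function(model, image) {
  if (is.list(image) && !is_radiograph(image)) {
    return(lapply(image, function(i) predict_mask(model, i)))
  }
  m <- rg_normalize(image)
  X <- sweep(sweep(segmenter_features(m), 2, model$center), 2, model$scale, "/")
  pv <- 1 / (1 + exp(-(drop(X %*% model$weights) + model$bias)))
  matrix(pv >= model$threshold, nrow(m), ncol(m)) + 0L
}

#' Mask QC report for a set of masks
#' @param masks named list of binary matrices (names used as image ids).
#' @param min_minor_ratio passed to [qc_mask()].
#' @return data.frame `image_path, component_count, area_ratio, qc_status`.
#' @export
qc_report <- function(masks, min_minor_ratio = 0.25) {
  rows <- lapply(names(masks), function(nm) {
    q <- qc_mask(masks[[nm]], min_minor_ratio)
    data.frame(image_path = nm, component_count = q$component_count,
               area_ratio = q$area_ratio, qc_status = q$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
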