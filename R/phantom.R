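#' Phantom radiograph specification
#'
#' Describes the synthetic chest-radiograph phantom: a bright torso with a
#' smooth vertical intensity gradient, two darker elliptical lung fields
#' (the ground-truth segmentation target), additive raised-cosine rib bands
#' along slanted sinusoidal paths, Gaussian bright nodule blobs, an optional
#' corner projection-label marker whose presence is correlated with the
#' image class, per-site brightness/contrast/gamma calibration profiles and
#' a controllable fraction of label noise.  Every signal and confounder is a
#' separable additive layer, so downstream suppression and debiasing
#' operators have exact oracles.
#'
#' Geometry defaults scale with `image_size`; the reference design is 256
#' pixels per side with a nodule diameter and rib period of 3/32 of the
#' image side.
#'
#' @param image_size pixels per side (square images).
#' @param lung_ellipses list of two ellipses, each
#'   `list(center = c(row, col), semi = c(a_row, a_col), rot = degrees)` in
#'   0-based pixel units.
#' @param rib_count number of rib bands.
#' @param rib_amplitude peak additive rib intensity, fraction of range in `[0,1]`.
#' @param rib_period vertical spacing between rib bands, pixels.
#' @param nodule_diameter_px nodule blob truncation diameter, pixels.
#' @param nodule_contrast peak additive nodule intensity in `[0,1]`.
#' @param marker_enabled render the corner projection-label marker at all?
#' @param marker_class_correlation `rho` = P(marker | nodule-content image);
#'   non-nodule images carry the marker with probability `1 - rho`, so 0.5
#'   makes the marker independent of class and 1.0 a perfect predictor.
#' @param site_profiles list of `c(brightness_offset, contrast_gain, gamma)`
#'   triples emulating per-source acquisition calibration.
#' @param mislabel_fraction fraction in `[0, 1)` of nodule-labelled images
#'   emitted with non-nodule content (planted label noise).
#' @param seed integer RNG seed; one stream per dataset, split per sample by
#'   counter so individual samples can be regenerated.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L,
                         lung_ellipses = NULL,
                         rib_count = 7L,
                         rib_amplitude = 0.08,
                         rib_period = NULL,
                         nodule_diameter_px = NULL,
                         nodule_contrast = 0.25,
                         marker_enabled = TRUE,
                         marker_class_correlation = 0.9,
                         site_profiles = list(c(0, 1, 1),
                                              c(0.08, 1.10, 0.90),
                                              c(-0.06, 0.90, 1.15)),
                         mislabel_fraction = 0,
                         seed = 1L) {
  s <- as.integer(image_size)
  if (is.null(rib_period)) rib_period <- max(6L, round(s * 3 / 32))
  if (is.null(nodule_diameter_px)) nodule_diameter_px <- max(6L, round(s * 3 / 32))
  if (is.null(lung_ellipses)) {
    # mediastinal gap is kept wider than the 8 px mask-closing kernel even
    # at desk-scale image sizes, so the two lung fields stay separable
    lung_ellipses <- list(
      list(center = c(0.56, 0.26) * (s - 1), semi = c(0.31, 0.14) * s, rot = 5),
      list(center = c(0.56, 0.74) * (s - 1), semi = c(0.31, 0.14) * s, rot = -5)
    )
  }
  spec <- structure(
    list(image_size = s, lung_ellipses = lung_ellipses,
         rib_count = as.integer(rib_count), rib_amplitude = rib_amplitude,
         rib_period = rib_period,
         nodule_diameter_px = as.integer(nodule_diameter_px),
         nodule_contrast = nodule_contrast,
         marker_enabled = isTRUE(marker_enabled),
         marker_class_correlation = marker_class_correlation,
         site_profiles = site_profiles,
         mislabel_fraction = mislabel_fraction,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  s <- spec$image_size
  fracs <- c(spec$rib_amplitude, spec$nodule_contrast,
             spec$marker_class_correlation)
  if (any(fracs < 0 | fracs > 1)) {
    stop("intensity fractions and probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (spec$mislabel_fraction < 0 || spec$mislabel_fraction >= 1) {
    stop("`mislabel_fraction` must lie in [0, 1)", call. = FALSE)
  }
  min_semi <- Inf
  for (e in spec$lung_ellipses) {
    cr <- e$center[1]; cc <- e$center[2]
    th <- e$rot * pi / 180
    # exact axis-aligned bounding half-widths of the rotated ellipse
    wr <- sqrt((e$semi[1] * cos(th))^2 + (e$semi[2] * sin(th))^2)
    wc <- sqrt((e$semi[1] * sin(th))^2 + (e$semi[2] * cos(th))^2)
    if (cr - wr < 0 || cr + wr > s - 1 || cc - wc < 0 || cc + wc > s - 1) {
      stop("lung ellipses must lie fully inside the image bounds", call. = FALSE)
    }
    min_semi <- min(min_semi, e$semi)
  }
  if (spec$nodule_diameter_px > min_semi) {
    stop("`nodule_diameter_px` exceeds the smaller lung semi-axis", call. = FALSE)
  }
  invisible(spec)
}

# Hard binary rasterization of one ellipse; 0-based pixel coordinates.
ellipse_mask <- function(s, center, semi, rot_deg) {
  th <- rot_deg * pi / 180
  R <- matrix(seq_len(s) - 1, s, s)          # row index (0-based)
  C <- matrix(seq_len(s) - 1, s, s, byrow = TRUE)
  dy <- R - center[1]; dx <- C - center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  ((u / semi[2])^2 + (v / semi[1])^2 <= 1) + 0L
}

# Soft-edged version of the same ellipse used for the anatomy layer; the
# 0.5 level set coincides with the hard mask boundary.
ellipse_soft <- function(s, center, semi, rot_deg, edge = 0.10) {
  th <- rot_deg * pi / 180
  R <- matrix(seq_len(s) - 1, s, s)
  C <- matrix(seq_len(s) - 1, s, s, byrow = TRUE)
  dy <- R - center[1]; dx <- C - center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  q <- (u / semi[2])^2 + (v / semi[1])^2
  clip01((1 + edge - q) / (2 * edge))
}

#' Ground-truth lung mask of a phantom spec
#' @param spec a `phantom_spec`.
#' @return binary matrix, union of the two rasterized lung ellipses.
#' @export
phantom_true_mask <- function(spec) {
  s <- spec$image_size
  m <- matrix(0L, s, s)
  for (e in spec$lung_ellipses) {
    m <- pmax(m, ellipse_mask(s, e$center, e$semi, e$rot))
  }
  m
}

phantom_anatomy <- function(spec) {
  s <- spec$image_size
  base <- matrix(seq(0.40, 0.80, length.out = s), s, s)  # vertical gradient
  soft <- matrix(0, s, s)
  for (e in spec$lung_ellipses) {
    soft <- pmax(soft, ellipse_soft(s, e$center, e$semi, e$rot))
  }
  base - 0.35 * soft
}

# Rib bands: raised cosine across slanted sinusoidal paths.  Phases/slopes
# are drawn from the supplied RNG stream (consumed even when amplitude = 0
# so layer toggles never shift downstream draws).
phantom_rib_layer <- function(spec) {
  s <- spec$image_size
  n <- spec$rib_count
  slopes <- stats::runif(n, -0.10, 0.10)
  phases <- stats::runif(n, 0, 2 * pi)
  layer <- matrix(0, s, s)
  if (n == 0L || spec$rib_amplitude == 0) return(layer)
  w <- 0.25 * spec$rib_period                     # half width of a band
  cols0 <- seq_len(s) - 1
  top <- 0.24 * s
  R <- matrix(seq_len(s) - 1, s, s)
  for (i in seq_len(n)) {
    path <- top + (i - 0.5) * spec$rib_period +
      slopes[i] * (cols0 - s / 2) +
      0.02 * s * sin(2 * pi * cols0 / (0.8 * s) + phases[i])
    D <- abs(R - matrix(path, s, s, byrow = TRUE))
    band <- ifelse(D <= w, 0.5 * spec$rib_amplitude * (1 + cos(pi * D / w)), 0)
    layer <- layer + band
  }
  layer
}

phantom_nodule_layer <- function(spec, mask, n_nodules = 1L) {
  s <- spec$image_size
  layer <- matrix(0, s, s)
  centers <- matrix(numeric(0), 0, 2)
  # centers are drawn from the mask interior (eroded by about the nodule
  # diameter) so the whole blob lies in the lung parenchyma away from the
  # pleural boundary; still a subset of the true-mask foreground
  er <- 2L * (spec$nodule_diameter_px %/% 2L) + 1L
  interior <- erode_box(mask, max(3L, er))
  fg <- which(interior == 1L)
  if (length(fg) == 0L) fg <- which(mask == 1L)
  for (i in seq_len(n_nodules)) {
    pick <- fg[sample.int(length(fg), 1L)]
    rr <- (pick - 1L) %% s           # 0-based row
    cc <- (pick - 1L) %/% s          # 0-based col
    centers <- rbind(centers, c(rr, cc))
    sig <- spec$nodule_diameter_px / 4
    rad <- spec$nodule_diameter_px / 2
    R <- matrix(seq_len(s) - 1, s, s)
    C <- matrix(seq_len(s) - 1, s, s, byrow = TRUE)
    d2 <- (R - rr)^2 + (C - cc)^2
    blob <- spec$nodule_contrast * exp(-d2 / (2 * sig^2)) * (d2 <= rad^2)
    layer <- layer + blob
  }
  list(layer = layer, centers = centers)
}

phantom_marker_layer <- function(spec, present) {
  s <- spec$image_size
  layer <- matrix(0, s, s)
  if (spec$marker_enabled && present) {
    h <- max(2L, round(s * 12 / 256)); wdt <- max(4L, round(s * 24 / 256))
    layer[1:h, 1:wdt] <- 0.6
  }
  layer
}

#' Generate one phantom sample
#'
#' Deterministic given `(spec, label, counter)`.  The stored image is the
#' clipped sum of the anatomy, rib, nodule and marker layers (no site bias;
#' site calibration is applied by [generate_dataset()] per manifest row).
#'
#' @param spec a `phantom_spec`.
#' @param label emitted class label, `"nodule"` or `"non-nodule"`.
#' @param counter per-sample counter splitting the dataset RNG stream.
#' @param mislabeled if `TRUE`, the emitted label is `label` but the content
#'   is generated from the opposite (true) class.
#' @return a `phantom_sample` list: `image` (matrix in `[0,1]`),
#'   `true_mask`, `anatomy`, `rib_layer`, `nodule_layer`, `marker_layer`,
#'   `nodule_centers` (0-based `(row, col)`), `true_label`, `emitted_label`,
#'   `mislabeled`.
#' @export
generate_sample <- function(spec, label = c("nodule", "non-nodule"),
                            counter = 1L, mislabeled = FALSE) {
  label <- match.arg(label)
  validate_phantom_spec(spec)
  true_label <- if (mislabeled) {
    if (label == "nodule") "non-nodule" else "nodule"
  } else label
  withr::with_seed(derive_seed(spec$seed, counter), {
    mask <- phantom_true_mask(spec)
    anatomy <- phantom_anatomy(spec)
    rib <- phantom_rib_layer(spec)
    has_marker <- stats::runif(1) < (
      if (true_label == "nodule") spec$marker_class_correlation
      else 1 - spec$marker_class_correlation
    )
    marker <- phantom_marker_layer(spec, has_marker)
    nod <- if (true_label == "nodule") {
      phantom_nodule_layer(spec, mask, 1L)
    } else {
      list(layer = matrix(0, spec$image_size, spec$image_size),
           centers = matrix(numeric(0), 0, 2))
    }
    structure(
      list(image = clip01(anatomy + rib + nod$layer + marker),
           true_mask = mask, anatomy = anatomy, rib_layer = rib,
           nodule_layer = nod$layer, marker_layer = marker,
           nodule_centers = nod$centers, true_label = true_label,
           emitted_label = label, mislabeled = mislabeled,
           counter = as.integer(counter)),
      class = "phantom_sample"
    )
  })
}

#' Apply a site calibration profile to an image
#'
#' Emulates per-source acquisition bias:
#' `out = clip((in^gamma) * contrast_gain + brightness_offset)` on the
#' normalized `[0,1]` scale, rescaled back to the input bit depth.
#'
#' @param image `radiograph` or matrix in `[0,1]`.
#' @param profile numeric `c(brightness_offset, contrast_gain, gamma)`.
#' @return same type as `image`.
#' @export
apply_site_bias <- function(image, profile) {
  if (length(profile) != 3L || profile[3] <= 0) {
    stop("site profile must be c(offset, gain, gamma) with gamma > 0", call. = FALSE)
  }
  m <- rg_normalize(image)
  out <- clip01((m^profile[3]) * profile[2] + profile[1])
  if (is_radiograph(image)) {
    rg_rewrap(out * (2^image$bit_depth - 1), image)
  } else {
    out
  }
}

#' Generate a phantom dataset on disk
#'
#' Writes 8-bit grayscale PNG images and ground-truth masks, a CSV manifest
#' and a JSON sidecar with the full spec.  Exactly
#' `round(mislabel_fraction * n_nodule)` of the nodule-labelled rows carry
#' non-nodule content (flagged in the `mislabeled` column); sites are
#' assigned round-robin over `spec$site_profiles` and the corresponding
#' calibration bias is applied to each written image.
#'
#' @param spec a `phantom_spec`.
#' @param n_nodule,n_normal emitted class counts (>= 0, not both 0).
#' @param dir output directory (created).
#' @return the manifest `data.frame`, invisibly carrying `dir` and `spec`
#'   as attributes.
#' @export
generate_dataset <- function(spec, n_nodule, n_normal, dir) {
  validate_phantom_spec(spec)
  if (n_nodule < 0 || n_normal < 0) stop("counts must be >= 0", call. = FALSE)
  if (n_nodule + n_normal == 0) stop("empty dataset requested", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_mis <- round(spec$mislabel_fraction * n_nodule)
  mis_idx <- withr::with_seed(derive_seed(spec$seed, 0L),
                              sample.int(n_nodule, n_mis))
  labels <- c(rep("nodule", n_nodule), rep("non-nodule", n_normal))
  rows <- vector("list", length(labels))
  n_sites <- length(spec$site_profiles)
  for (i in seq_along(labels)) {
    mis <- labels[i] == "nodule" && i %in% mis_idx
    smp <- generate_sample(spec, labels[i], counter = i, mislabeled = mis)
    site <- ((i - 1L) %% n_sites) + 1L
    img <- apply_site_bias(smp$image, spec$site_profiles[[site]])
    id <- sprintf("PH%04d", i)
    ipath <- file.path(dir, paste0(id, ".png"))
    mpath <- file.path(dir, paste0(id, "_mask.png"))
    write_png_radiograph(img, ipath)
    png::writePNG(smp$true_mask + 0, mpath)
    rows[[i]] <- data.frame(
      image_id = id,
      image_path = basename(ipath), mask_path = basename(mpath),
      emitted_label = smp$emitted_label, true_label = smp$true_label,
      patient_id = sprintf("PT%04d", i), site_id = site,
      mislabeled = mis, stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  manifest$active <- TRUE
  utils::write.csv(manifest[, c("image_id", "image_path", "mask_path",
                                "emitted_label", "true_label", "patient_id",
                                "site_id", "mislabeled")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(phantom_spec_json(spec),
                       file.path(dir, "phantom_spec.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest$image_path <- file.path(dir, manifest$image_path)
  manifest$mask_path <- file.path(dir, manifest$mask_path)
  attr(manifest, "dir") <- dir
  attr(manifest, "spec") <- spec
  invisible(manifest)
}

phantom_spec_json <- function(spec) {
  s <- unclass(spec)
  s$lung_ellipses <- lapply(s$lung_ellipses, function(e) {
    list(center = e$center, semi = e$semi, rot = e$rot)
  })
  s
}

#' Generate matched (rib, rib-free) phantom image pairs
#'
#' Training/evaluation material for the rib-suppression operator: each pair
#' is the composed phantom image and the same image with the stored rib
#' layer removed (no site bias so the layer arithmetic is exact).
#'
#' @param spec a `phantom_spec`.
#' @param n number of pairs.
#' @param counter_offset offset into the per-sample counter stream.
#' @param equalized if `TRUE`, both members of each pair are passed through
#'   [equalize_histogram()], so the pair lives in the intensity domain
#'   where the canonical pipeline applies the suppressor (equalization
#'   precedes suppression); if `FALSE`, raw composed intensities are
#'   returned, for which the stored `rib_layer` is an exact additive
#'   oracle.
#' @return list of `n` lists with elements `input`, `target`, `rib_layer`,
#'   `sample`.
#' @export
generate_rib_pairs <- function(spec, n, counter_offset = 10000L,
                               equalized = FALSE) {
  lapply(seq_len(n), function(i) {
    lab <- if (i %% 2L == 0L) "nodule" else "non-nodule"
    smp <- generate_sample(spec, lab, counter = counter_offset + i)
    input <- smp$image
    target <- clip01(smp$anatomy + smp$nodule_layer + smp$marker_layer)
    if (equalized) {
      input <- equalize_histogram(input)
      target <- equalize_histogram(target)
    }
    list(input = input, target = target,
         rib_layer = smp$rib_layer, sample = smp)
  })
}
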