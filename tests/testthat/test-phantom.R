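test_that("sample generation is deterministic and layer-decomposable", {
  spec <- desk_spec(seed = 3L)
  a <- generate_sample(spec, "nodule", counter = 2L)
  b <- generate_sample(spec, "nodule", counter = 2L)
  expect_identical(a$image, b$image)
  expect_identical(a$nodule_centers, b$nodule_centers)

  # image is exactly the clipped sum of the stored layers
  recomposed <- pmin(pmax(a$anatomy + a$rib_layer + a$nodule_layer +
                            a$marker_layer, 0), 1)
  expect_equal(a$image, recomposed, tolerance = 0)

  # nodule-class samples carry a blob, non-nodule samples none
  expect_gt(nrow(a$nodule_centers), 0)
  nn <- generate_sample(spec, "non-nodule", counter = 5L)
  expect_identical(sum(nn$nodule_layer), 0)
})

test_that("rib amplitude zero yields an all-zero rib layer", {
  s <- generate_sample(desk_spec(rib_amplitude = 0), "nodule", counter = 1L)
  expect_true(all(s$rib_layer == 0))
})

test_that("true mask equals brute-force per-pixel ellipse rasterization", {
  spec <- phantom_spec(
    image_size = 256L,
    lung_ellipses = list(
      list(center = c(120, 80), semi = c(60, 40), rot = 0),
      list(center = c(120, 176), semi = c(60, 40), rot = 0)
    )
  )
  mask <- phantom_true_mask(spec)
  # independent oracle: explicit double loop over 0-based pixel coordinates
  oracle <- matrix(0L, 256, 256)
  for (r in 0:255) {
    for (c in 0:255) {
      in1 <- ((c - 80) / 40)^2 + ((r - 120) / 60)^2 <= 1
      in2 <- ((c - 176) / 40)^2 + ((r - 120) / 60)^2 <= 1
      if (in1 || in2) oracle[r + 1, c + 1] <- 1L
    }
  }
  expect_identical(mask, oracle)
  expect_identical(sum(mask), sum(oracle))
})

test_that("nodule centers lie in the true-mask foreground", {
  spec <- desk_spec(seed = 9L)
  for (ct in 1:10) {
    s <- generate_sample(spec, "nodule", counter = ct)
    rc <- s$nodule_centers[1, ]
    expect_identical(s$true_mask[rc[1] + 1, rc[2] + 1], 1L)
  }
})

test_that("dataset manifests carry exact class and mislabel arithmetic", {
  spec <- desk_spec(seed = 4L)
  m <- make_dataset(spec, 154L, 93L)
  expect_identical(nrow(m), 247L)
  expect_identical(sum(m$emitted_label == "nodule"), 154L)
  expect_identical(sum(m$emitted_label == "non-nodule"), 93L)
  expect_true(all(m$emitted_label == m$true_label))  # mislabel_fraction = 0

  m2 <- make_dataset(desk_spec(seed = 4L, mislabel_fraction = 0.2), 20L, 10L)
  expect_identical(sum(m2$mislabeled), 4L)           # round(0.2 * 20)
  flipped <- m2$emitted_label != m2$true_label
  expect_identical(flipped, m2$mislabeled)
  expect_true(all(m2$emitted_label[m2$mislabeled] == "nodule"))
  expect_identical(sum(m2$emitted_label == "nodule"), 20L)

  expect_error(generate_dataset(spec, 0L, 0L, tempfile()), "empty")
})

test_that("datasets regenerate bit-identically from the same spec", {
  spec <- desk_spec(seed = 12L)
  m1 <- make_dataset(spec, 4L, 3L)
  m2 <- make_dataset(spec, 4L, 3L)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$image_path[i], "raw", 1e6),
                     readBin(m2$image_path[i], "raw", 1e6))
  }
})

test_that("site bias applies the stated brightness/contrast/gamma transform", {
  img <- matrix(0.5, 20, 20)
  expect_equal(apply_site_bias(img, c(0, 1, 1)), img)
  out <- apply_site_bias(img, c(0.1, 1, 1))
  expect_equal(out, matrix(0.6, 20, 20))
  # gamma = 2 on 0.5 gives 0.25 before gain/offset
  expect_equal(apply_site_bias(img, c(0, 1, 2))[1, 1], 0.25)
  expect_error(apply_site_bias(img, c(0, 1, 0)), "gamma")
})

test_that("marker presence tracks class correlation as specified", {
  # rho = 1: marker is a perfect predictor of the (true) class
  spec1 <- desk_spec(marker_class_correlation = 1, seed = 21L)
  labs <- rep(c("nodule", "non-nodule"), length.out = 60)
  for (i in seq_along(labs)) {
    s <- generate_sample(spec1, labs[i], counter = i)
    expect_identical(any(s$marker_layer > 0), s$true_label == "nodule")
  }
  # rho = 0.5: independence (chi-square on 500 samples)
  spec5 <- desk_spec(marker_class_correlation = 0.5, seed = 21L)
  labs <- rep(c("nodule", "non-nodule"), length.out = 500)
  has_marker <- logical(500); is_nodule <- logical(500)
  for (i in seq_along(labs)) {
    s <- generate_sample(spec5, labs[i], counter = i)
    has_marker[i] <- any(s$marker_layer > 0)
    is_nodule[i] <- s$true_label == "nodule"
  }
  p <- stats::chisq.test(table(has_marker, is_nodule))$p.value
  expect_gt(p, 0.01)
})

test_that("invalid phantom specs are rejected", {
  expect_error(desk_spec(nodule_diameter_px = 60L), "semi-axis")
  expect_error(desk_spec(rib_amplitude = 1.5), "fractions")
  expect_error(desk_spec(mislabel_fraction = 1), "mislabel_fraction")
  expect_error(
    phantom_spec(image_size = 64L, lung_ellipses = list(
      list(center = c(10, 10), semi = c(30, 20), rot = 0),
      list(center = c(40, 40), semi = c(10, 8), rot = 0)
    )),
    "inside the image bounds"
  )
})
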