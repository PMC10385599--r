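test_that("repair_mask fills pinholes below 1/16 of the image area", {
  expect_identical(formals(repair_mask)$min_area_fraction, quote(1 / 16))
  m <- matrix(0L, 64, 64)
  m[10:50, 10:50] <- 1L
  m[30:31, 30:31] <- 0L            # 4 px pinhole; threshold = 4096/16 = 256
  r <- repair_mask(m)
  expect_true(all(r[30:31, 30:31] == 1L))
  expect_true(all(r >= m))

  # a hole at or above the threshold is preserved
  big <- matrix(0L, 64, 64)
  big[5:60, 5:60] <- 1L
  big[20:40, 20:40] <- 0L          # 441 px > 256
  rb <- repair_mask(big)
  expect_true(all(rb[25:35, 25:35] == 0L))
  expect_error(repair_mask(m, min_area_fraction = 0), "min_area_fraction")
})

test_that("repair_mask is a no-op on clean gold masks", {
  for (size in c(64L, 96L)) {
    tm <- phantom_true_mask(phantom_spec(image_size = size))
    expect_true(all(repair_mask(tm) == tm))
  }
})

test_that("repair_mask is monotone and idempotent on random grids", {
  withr::with_seed(42, {
    for (i in 1:50) {
      g <- matrix(rbinom(1024, 1, runif(1, 0.3, 0.7)), 32, 32)
      r1 <- repair_mask(g)
      expect_true(all(r1 >= g))
      expect_identical(repair_mask(r1), r1)
    }
  })
})

test_that("hole filling agrees with a flood-fill-from-border oracle", {
  # oracle: BFS flood fill of background from the border; anything the
  # flood cannot reach is a hole, filled when below the area threshold
  flood_oracle <- function(g, frac = 1 / 16) {
    nr <- nrow(g); nc <- ncol(g)
    vis <- matrix(FALSE, nr, nc)
    q <- list()
    for (i in 1:nr) for (j in 1:nc) {
      if ((i == 1 || i == nr || j == 1 || j == nc) && g[i, j] == 0) {
        q[[length(q) + 1]] <- c(i, j); vis[i, j] <- TRUE
      }
    }
    while (length(q)) {
      p <- q[[1]]; q <- q[-1]
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        a <- p[1] + o[1]; b <- p[2] + o[2]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc && g[a, b] == 0 &&
            !vis[a, b]) {
          vis[a, b] <- TRUE; q[[length(q) + 1]] <- c(a, b)
        }
      }
    }
    out <- g
    hole <- !vis & g == 0
    lab <- label_components(hole + 0L, connectivity = 4L)
    for (lb in seq_len(attr(lab, "n"))) {
      px <- which(lab == lb)
      if (length(px) < frac * length(g)) out[px] <- 1L
    }
    out
  }
  withr::with_seed(7, {
    for (i in 1:100) {
      g <- matrix(rbinom(1024, 1, runif(1, 0.35, 0.65)), 32, 32)
      expect_identical(repair_mask(g, closing_kernel = 1L), flood_oracle(g))
    }
  })
})

test_that("mask QC applies the contour-count and visibility rules", {
  one <- matrix(0L, 64, 64); one[10:50, 10:50] <- 1L
  expect_identical(qc_mask(one)$status, "fail_contour_count")
  expect_identical(qc_mask(matrix(0L, 32, 32))$status, "fail_contour_count")

  two <- matrix(0L, 64, 64)
  two[10:50, 5:25] <- 1L; two[10:50, 40:60] <- 1L
  q <- qc_mask(two)
  expect_identical(q$status, "pass")
  expect_identical(q$component_count, 2L)
  expect_equal(q$area_ratio, 1)

  # second/largest area ratio 0.10 < 0.25 fails visibility
  lop <- matrix(0L, 64, 64)
  lop[10:49, 5:29] <- 1L          # 40 x 25 = 1000 px
  lop[10:19, 40:49] <- 1L         # 10 x 10 = 100 px
  ql <- qc_mask(lop)
  expect_identical(ql$status, "fail_visibility")
  expect_equal(ql$area_ratio, 0.1)
})

test_that("Dice follows its formula and conventions", {
  a <- matrix(0L, 8, 8); a[1:4, 1] <- 1L                   # |A| = 4
  b <- matrix(0L, 8, 8); b[2:7, 1] <- 1L                   # |B| = 6, overlap 3
  expect_equal(dice(a, b), 0.6)
  expect_equal(dice(a, a), 1)
  disj <- matrix(0L, 8, 8); disj[6:7, 6:7] <- 1L
  expect_equal(dice(a, disj), 0)
  expect_equal(dice(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_error(dice(a, matrix(0L, 4, 4)), "shapes")
})

test_that("the phantom-trained segmenter reaches high held-out Dice", {
  spec <- desk_spec(marker_class_correlation = 0.5, seed = 5L)
  seg <- train_segmenter(make_seg_pairs(spec, 64L), epochs = 20L, seed = 1L)
  expect_length(seg$dice_curve, 20L)
  held <- make_seg_pairs(spec, 16L, counter_offset = 100L)
  dc <- vapply(held, function(p) dice(predict_mask(seg, p$image), p$mask),
               numeric(1))
  expect_true(all(dc >= 0.95))

  seg2 <- train_segmenter(make_seg_pairs(spec, 64L), epochs = 20L, seed = 1L)
  expect_identical(seg$dice_curve, seg2$dice_curve)
  expect_error(train_segmenter(list()), "empty")
  expect_error(train_segmenter(make_seg_pairs(spec, 4L)), "at least 8")
})

test_that("a degenerate all-foreground mask is fitted exactly", {
  spec <- desk_spec(seed = 8L)
  pairs <- lapply(1:12, function(i) {
    s <- generate_sample(spec, "non-nodule", counter = i)
    list(image = s$image, mask = matrix(1L, 64L, 64L))
  })
  seg <- train_segmenter(pairs, epochs = 10L, seed = 2L)
  pred <- predict_mask(seg, pairs[[1]]$image)
  expect_equal(dice(pred, pairs[[1]]$mask), 1)
})

test_that("QC-passing masks leave two disjoint regions after masking", {
  spec <- desk_spec(seed = 10L)
  s <- generate_sample(spec, "nodule", counter = 1L)
  rm <- repair_mask(s$true_mask)
  expect_identical(qc_mask(rm)$status, "pass")
  masked <- apply_mask(equalize_histogram(s$image), rm)
  comps <- label_components((masked > 0) + 0L, connectivity = 8L)
  expect_gte(attr(comps, "n"), 2L)
})
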