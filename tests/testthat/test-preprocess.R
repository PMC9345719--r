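test_that("binarize_body thresholds strictly above the level", {
  expect_identical(binarize_body(matrix(0L, 4, 4), 10), matrix(0L, 4, 4))
  expect_identical(binarize_body(matrix(255L, 4, 4), 10), matrix(1L, 4, 4))
  img <- matrix(c(10L, 11L), 1, 2)
  expect_identical(as.vector(binarize_body(img, 10)), c(0L, 1L))
  expect_error(binarize_body(matrix(0L, 2, 2), 300),
               class = "rootsu_validation_error")
})

test_that("outermost_pixels matches a literal per-row/per-column scan", {
  m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
  pts <- outermost_pixels(m)
  # 3x3 solid square: its 8 border pixels (the center is never first/last)
  expect_identical(nrow(pts), 8L)
  expect_true(all(m[pts] == 1L))
  expect_false(any(pts[, 1] == 3 & pts[, 2] == 3))

  single <- matrix(0L, 4, 4); single[2, 3] <- 1L
  expect_identical(outermost_pixels(single), cbind(row = 2L, col = 3L))

  full <- matrix(1L, 4, 5)
  pf <- outermost_pixels(full)
  on_border <- pf[, 1] %in% c(1, 4) | pf[, 2] %in% c(1, 5)
  expect_true(all(on_border))
  expect_identical(nrow(pf), 2L * 4L + 2L * 5L - 4L)

  expect_error(outermost_pixels(matrix(0L, 3, 3)),
               class = "rootsu_degenerate_error")

  # oracle: literal scan over rows and columns of a random blob
  set.seed(3)
  blob <- random_mask(9, 9, 0.5)
  blob[1, ] <- 0L  # keep at least some structure
  if (sum(blob) > 0) {
    exp_pts <- matrix(0L, 0, 2)
    for (r in 1:9) {
      w <- which(blob[r, ] == 1L)
      if (length(w)) exp_pts <- rbind(exp_pts, c(r, min(w)), c(r, max(w)))
    }
    for (cl in 1:9) {
      w <- which(blob[, cl] == 1L)
      if (length(w)) exp_pts <- rbind(exp_pts, c(min(w), cl), c(max(w), cl))
    }
    exp_pts <- unique(exp_pts)
    got <- outermost_pixels(blob)
    expect_setequal(paste(got[, 1], got[, 2]),
                    paste(exp_pts[, 1], exp_pts[, 2]))
  }
})

test_that("strip_subcutaneous_band removes the window-union band only", {
  # 31x31 disk body: window 15 strips a rim, preserves the core
  nr <- 31L
  rr <- matrix(1:nr, nr, nr); cc <- t(rr)
  body <- as_binary_mask((rr - 16)^2 + (cc - 16)^2 <= 15^2)
  img <- as_gray_image(body * 100L)
  res <- strip_subcutaneous_band(img, body, band_window = 15L)
  expect_identical(res$cleaned[16, 16], 100L)            # core untouched
  # oracle: brute-force union of 15x15 windows over outermost pixels
  pts <- outermost_pixels(body)
  expected <- matrix(0L, nr, nr)
  for (i in seq_len(nrow(pts))) {
    rw <- max(1, pts[i, 1] - 7):min(nr, pts[i, 1] + 7)
    cw <- max(1, pts[i, 2] - 7):min(nr, pts[i, 2] + 7)
    expected[rw, cw] <- 1L
  }
  expected <- as_binary_mask(expected == 1L & body == 1L)
  expect_identical(res$removed_band, expected)

  # degenerate small body: a window-3 band covers a 3x3 body entirely
  small_body <- matrix(0L, 5, 5); small_body[2:4, 2:4] <- 1L
  res2 <- strip_subcutaneous_band(as_gray_image(small_body * 50L),
                                  small_body, band_window = 3L)
  expect_identical(res2$removed_band, small_body)
  expect_true(all(res2$cleaned == 0L))

  expect_error(strip_subcutaneous_band(img, body, band_window = 4L),
               class = "rootsu_validation_error")
})

test_that("remove_bed keeps the largest component and zeroes the bed", {
  sl <- generate_slice(small_phantom_spec(seed = 21L))
  img <- sl$image
  thr <- otsu_threshold(gray_histogram(img))$threshold
  body0 <- binarize_body(img, thr)
  res <- remove_bed(img, body0)
  bed_px <- which(sl$truth$bed == 1L)
  expect_true(all(res$removed_bed[bed_px] == 1L))          # bed fully removed
  expect_true(all(res$cleaned[bed_px] == 0L))
  peri <- which(sl$truth$perigastric == 1L)
  expect_true(all(res$removed_bed[peri] == 0L))            # fat untouched
  expect_true(all(res$body_mask[peri] == 1L))
  # removed_bed and body_mask are disjoint
  expect_identical(sum(res$removed_bed == 1L & res$body_mask == 1L), 0L)
  expect_error(remove_bed(img, matrix(0L, nrow(img), ncol(img))),
               class = "rootsu_degenerate_error")
})

test_that("remove_bed without a bed keeps the body (up to the border rim)", {
  nr <- 41L
  rr <- matrix(1:nr, nr, nr); cc <- t(rr)
  body <- as_binary_mask((rr - 21)^2 + (cc - 21)^2 <= 18^2)
  img <- as_gray_image(body * 120L)
  res <- remove_bed(img, body)
  expect_true(all(res$body_mask <= body))
  inner <- as_binary_mask((rr - 21)^2 + (cc - 21)^2 <= 16^2)
  expect_true(all(res$body_mask[inner == 1L] == 1L))
})

test_that("largest-component ties break at the smallest top-left pixel", {
  m <- matrix(0L, 7, 9)
  m[5:6, 1:2] <- 1L   # 4 pixels, top-left (5, 1)
  m[1:2, 5:6] <- 1L   # 4 pixels, top-left (1, 5)
  keep <- rootsu:::largest_component(m)
  expect_identical(keep[1, 5], 1L)
  expect_identical(keep[5, 1], 0L)
})

test_that("preprocess_slice composes the stages deterministically", {
  sl <- generate_slice(small_phantom_spec(seed = 8L))
  pp1 <- preprocess_slice(sl$image)
  pp2 <- preprocess_slice(sl$image)
  expect_identical(pp1, pp2)
  # cleaned equals original wherever kept, zero elsewhere
  kept <- pp1$interior == 1L
  expect_identical(pp1$cleaned[kept], sl$image[kept])
  expect_true(all(pp1$cleaned[!kept][pp1$body_mask[!kept] == 0L] == 0L))
  # band pixels never lie deeper than ceil(15/2) = 8 erosions into the body
  deep <- pp1$body_mask
  for (i in 1:8) deep <- erode(deep, structuring_element("square", 3))
  expect_identical(sum(pp1$removed_band == 1L & deep == 1L), 0L)
  # perigastric fat and nodes are untouched on a noise-free phantom
  target <- sl$truth$perigastric == 1L | sl$truth$nodes_mask == 1L
  expect_identical(pp1$cleaned[target], sl$image[target])
})
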