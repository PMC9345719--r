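hist_of <- function(values) {
  gray_histogram(as_gray_image(matrix(as.integer(values), 1)))
}

test_that("region_features reproduces hand-computed window statistics", {
  f <- region_features(matrix(57L, 30, 30), window = 25)
  expect_true(all(f$mean == 57))
  expect_true(all(f$var == 0))

  # 1x3 image [0, 3, 0], window 3: center U = 1, delta = 1 + 4 + 1 = 6
  f2 <- region_features(matrix(c(0L, 3L, 0L), 1, 3), window = 3)
  expect_equal(f2$mean[1, 2], 1)
  expect_equal(f2$var[1, 2], 6)
  # border windows are clipped: m = 2 there
  expect_identical(f2$m[1, 1], 2L)
  expect_equal(f2$mean[1, 1], 1.5)

  expect_error(region_features(matrix(0L, 5, 5), window = 25),
               class = "rootsu_validation_error")
  expect_error(region_features(matrix(0L, 5, 5), window = 4),
               class = "rootsu_validation_error")
})

test_that("region_features matches the naive per-pixel loop", {
  set.seed(31)
  for (i in 1:3) {
    img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    for (w in c(3L, 9L, 25L)) {
      f <- region_features(img, window = w)
      o <- naive_region_features(img, w)
      expect_equal(f$mean, o$mean, tolerance = 1e-12)
      expect_equal(f$var, o$var, tolerance = 1e-9)
    }
  }
})

test_that("normalized and unnormalized variance give the same split away from borders", {
  # with equal-size windows the variance histogram is rescaled by a constant,
  # so the Otsu bin cut and hence the partition are identical; restrict to
  # the interior where windows are not clipped
  sl <- generate_slice(small_phantom_spec(seed = 14L))
  pp <- preprocess_slice(sl$image)
  interior <- erode(pp$interior, structuring_element("square", 25))
  fa <- region_features(pp$cleaned, roi = interior, window = 25, normalize = FALSE)
  fb <- region_features(pp$cleaned, roi = interior, window = 25, normalize = TRUE)
  expect_equal(fb$var, fa$var / (25 * 25), tolerance = 1e-12)
  sa <- consistency_split(fa)
  sb <- consistency_split(fb)
  expect_identical(sa$consistent, sb$consistent)
  expect_identical(sa$roi_of_interest, sb$roi_of_interest)
})

test_that("consistency_split flags borders and nodes, not flat zones", {
  # two flat zones with a sharp border: only border-adjacent pixels are ROI
  img <- matrix(80L, 40, 40); img[, 21:40] <- 160L
  f <- region_features(img, window = 9)
  sp <- consistency_split(f)
  roi_cols <- unique(which(sp$roi_of_interest == 1L, arr.ind = TRUE)[, 2])
  expect_true(all(roi_cols >= 21 - 9 & roi_cols <= 20 + 9))
  expect_true(all(sp$consistent + sp$roi_of_interest == 1L))

  # constant image: degenerate, everything consistent, with a warning
  expect_warning(
    spc <- consistency_split(region_features(matrix(100L, 30, 30), window = 9)),
    class = "rootsu_warning")
  expect_true(spc$degenerate)
  expect_true(all(spc$consistent == 1L))

  # phantom: nearly all node pixels are high-variance ROI. Run at the full
  # 512 clinical matrix: the 25-px window and 3-6 px node radii are absolute,
  # so smaller phantoms leave almost no flat organ area to anchor the split.
  sl <- generate_slice(phantom_spec(seed = 5L))
  pp <- preprocess_slice(sl$image)
  fp <- region_features(pp$cleaned, roi = pp$interior, window = 25)
  spp <- consistency_split(fp)
  node_px <- which(sl$truth$nodes_mask == 1L)
  frac <- mean(spp$roi_of_interest[node_px] == 1L)
  expect_gte(frac, 0.99)
})

test_that("gray_histogram normalizes over the counted pixels", {
  h <- gray_histogram(matrix(c(0L, 0L, 255L, 255L), 2, 2))
  expect_equal(h$freq[1], 0.5)
  expect_equal(h$freq[256], 0.5)
  expect_equal(sum(h$freq), 1)
  hu <- gray_histogram(matrix(7L, 3, 3))
  expect_equal(hu$freq[8], 1)
  set.seed(2)
  img <- matrix(sample(0:255, 100, TRUE), 10, 10)
  roi <- random_mask(10, 10)
  h2 <- gray_histogram(img, roi)
  expect_equal(sum(h2$freq), 1)
  expect_identical(h2$n, sum(roi))
  expect_error(gray_histogram(img, matrix(0L, 10, 10)),
               class = "rootsu_validation_error")
})

test_that("otsu_threshold matches hand-derived cases and the tie rule", {
  r1 <- otsu_threshold(hist_of(c(1, 1, 5, 5)))
  expect_identical(r1$threshold, 1L)       # a in 1..4 tie; smallest wins
  r2 <- otsu_threshold(hist_of(c(rep(0, 3), rep(255, 7))))
  expect_identical(r2$threshold, 0L)       # all a in 0..254 tie; returns 0
  r3 <- otsu_threshold(hist_of(c(rep(0, 10), rep(255, 10))))
  expect_equal(r3$stats$between_var, 127.5^2)   # = 16256.25
  expect_error(otsu_threshold(hist_of(rep(9, 5))),
               class = "rootsu_degenerate_error")
})

test_that("otsu stats satisfy the Otsu invariants", {
  set.seed(17)
  for (i in 1:10) {
    counts <- random_histogram_counts()
    h <- histogram_from_counts(counts)
    d <- otsu_threshold(h)$threshold
    st <- otsu_stats(h, d)
    expect_equal(sum(st$phi), 1)
    expect_equal(sum(st$phi * ifelse(is.na(st$kappa), 0, st$kappa)),
                 st$kappa_total)
    expect_equal(st$M, st$phi * h$n)
    expect_gte(st$between_var, 0)
  }
})

test_that("multi_otsu reduces to otsu_threshold at k = 2", {
  set.seed(23)
  for (i in 1:20) {
    h <- histogram_from_counts(random_histogram_counts())
    expect_identical(multi_otsu(h, 2L)$thresholds,
                     otsu_threshold(h)$threshold)
  }
})

test_that("multi_otsu isolates well-separated modes", {
  counts <- numeric(256)
  counts[c(0, 80, 160, 240) + 1] <- 25
  h <- histogram_from_counts(counts)
  r <- multi_otsu(h, 4L)
  o <- oracle_multi_otsu(counts, 4L)
  expect_identical(r$thresholds, o$thresholds)
  expect_identical(r$thresholds, c(0L, 80L, 160L))  # smallest tuple per tie rule
  expect_equal(r$stats$between_var, o$between_var, tolerance = 1e-12)
  expect_error(multi_otsu(hist_of(c(0, 1, 2)), 4L),
               class = "rootsu_degenerate_error")
})

test_that("label maps reproduce the class proportions of otsu_stats", {
  set.seed(41)
  img <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
  h <- gray_histogram(img)
  mo <- multi_otsu(h, 3L)
  lab <- apply_thresholds(img, mo$thresholds)
  props <- tabulate(lab + 1L, 3L) / length(lab)
  expect_equal(props, mo$stats$phi, tolerance = 1e-12)
})

test_that("apply_thresholds labels intervals (d_{j-1}, d_j] with roi support", {
  img <- matrix(c(0L, 0L, 255L, 255L), 2, 2)
  expect_identical(as.vector(apply_thresholds(img, 1L)), c(0L, 0L, 1L, 1L))
  lab <- apply_thresholds(img, c(10L, 100L), roi = matrix(0L, 2, 2))
  expect_true(all(lab == -1L))
  # boundary membership: value d goes to the lower class, d+1 above
  img2 <- matrix(c(10L, 11L), 1, 2)
  expect_identical(as.vector(apply_thresholds(img2, 10L)), c(0L, 1L))
  expect_error(apply_thresholds(img, c(5L, 5L)), class = "rootsu_validation_error")
})
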