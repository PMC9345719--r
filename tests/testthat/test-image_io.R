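test_that("PNG round-trips 8-bit images and masks losslessly", {
  td <- withr::local_tempdir()
  zero <- matrix(0L, 3, 3)
  p <- file.path(td, "zero.png")
  write_gray_image(zero, p)
  back <- read_gray_image(p)
  expect_identical(back, zero)
  expect_identical(dim(back), c(3L, 3L))

  set.seed(11)
  img <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
  p2 <- file.path(td, "rand.png")
  write_gray_image(img, p2)
  expect_identical(read_gray_image(p2), as_gray_image(img))

  # masks: 1 -> 255 on disk, threshold at 128 recovers the mask
  ones <- matrix(1L, 2, 2)
  pm <- file.path(td, "ones.png")
  write_mask(ones, pm)
  expect_true(all(read_gray_image(pm) == 255L))
  m <- random_mask(16, 16)
  write_mask(m, file.path(td, "m.png"))
  expect_identical(read_mask(file.path(td, "m.png")), as_binary_mask(m))
  write_mask(matrix(0L, 4, 4), file.path(td, "empty.png"))
  expect_true(all(read_gray_image(file.path(td, "empty.png")) == 0L))
})

test_that("PGM round-trips in both plain and binary form", {
  td <- withr::local_tempdir()
  set.seed(5)
  img <- matrix(sample(0:255, 60, TRUE), 6, 10)
  for (plain in c(TRUE, FALSE)) {
    p <- file.path(td, sprintf("img_%d.pgm", plain))
    write_pgm(img, p, plain = plain)
    expect_identical(read_gray_image(p), as_gray_image(img))
  }
})

test_that("I/O failures raise typed errors", {
  expect_error(read_gray_image(file.path(tempdir(), "nope.png")),
               class = "rootsu_io_error")
  expect_error(write_mask(matrix(1L, 2, 2),
                          file.path(tempdir(), "no_dir_here", "m.png")),
               class = "rootsu_io_error")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not an image", bad)
  expect_error(read_gray_image(bad), class = "rootsu_io_error")
})

test_that("HU windowing maps the window linearly and saturates at its edges", {
  w <- windowing_spec(40, 400)
  hu <- matrix(c(40, 40 - 400, 40 - 200, 40 + 200, 40 + 400, -1000), 1)
  g <- apply_windowing(hu, w)
  expect_identical(as.vector(g), c(128L, 0L, 0L, 255L, 255L, 0L))
  # monotone non-decreasing in HU
  ramp <- matrix(seq(-1000, 1000, by = 1), 1)
  gr <- apply_windowing(ramp, w)
  expect_true(all(diff(as.vector(gr)) >= 0L))
  expect_error(windowing_spec(40, 0), class = "rootsu_validation_error")
})

test_that("DICOM input is rescaled to HU and windowed", {
  td <- withr::local_tempdir()
  # stored value 1000 with intercept -1024 -> HU -24; window (40, 400)
  px <- matrix(c(1064L, 664L, 1464L, 0L), 2, 2, byrow = TRUE)
  p <- file.path(td, "a.dcm")
  write_test_dicom(p, px, slope = 1, intercept = -1024)
  g <- read_gray_image(p, windowing = windowing_spec(40, 400))
  # HU: 40 (center -> 128), -360 (clipped -> 0), 440 (clipped -> 255), -1024
  expect_identical(as.vector(t(g)), c(128L, 0L, 255L, 0L))

  # window tags in the file are honored when no spec is passed
  write_test_dicom(p, px, slope = 1, intercept = -1024,
                   window_center = 40, window_width = 400)
  expect_identical(read_gray_image(p), g)

  # multi-frame is rejected
  write_test_dicom(p, px, n_frames = 2)
  expect_error(read_gray_image(p), class = "rootsu_io_error")
})

test_that("annotations validate structure and bounds", {
  td <- withr::local_tempdir()
  p <- file.path(td, "t.json")
  writeLines('{"slices":[{"id":"s1","nodes":[
    {"centroid":[10,12],"radius":3},{"centroid":[40,7],"radius":5}]}]}', p)
  recs <- read_annotations(p)
  expect_length(recs, 1L)
  expect_identical(nrow(recs$s1$nodes), 2L)
  expect_equal(recs$s1$nodes$row, c(10, 40))

  writeLines('{"slices":[]}', p)
  expect_length(read_annotations(p), 0L)

  writeLines('{"slices":[{"id":"s1","nodes":[{"centroid":[-1,5],"radius":3}]}]}', p)
  expect_error(read_annotations(p), class = "rootsu_validation_error")

  writeLines('{"slices":[{"id":"s1","nodes":[{"centroid":[30,5],"radius":3}]}]}', p)
  expect_error(read_annotations(p, image_size = c(20, 20)),
               class = "rootsu_validation_error")

  writeLines("{broken json", p)
  expect_error(read_annotations(p), class = "rootsu_validation_error")

  # write -> read round trip
  slices <- list(s1 = list(id = "s1", nodes = data.frame(
    row = c(1.5, 7), col = c(2, 3), radius = c(3, 4),
    embedded = c(TRUE, FALSE))))
  write_annotations(slices, p)
  back <- read_annotations(p)
  expect_equal(back$s1$nodes, slices$s1$nodes)
})

test_that("gray image and mask validators enforce invariants", {
  expect_error(as_gray_image(matrix(-1, 2, 2)), class = "rootsu_validation_error")
  expect_error(as_gray_image(matrix(256, 2, 2)), class = "rootsu_validation_error")
  expect_error(as_gray_image(matrix(1.5, 2, 2)), class = "rootsu_validation_error")
  expect_error(as_binary_mask(matrix(2, 2, 2)), class = "rootsu_validation_error")
  expect_identical(as_binary_mask(matrix(c(TRUE, FALSE), 1, 2)),
                   matrix(c(1L, 0L), 1, 2))
})
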