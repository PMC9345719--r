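#' CT slice preprocessing: bed removal and subcutaneous-fat stripping
#'
#' Abdominal CT slices carry two structures that confuse downstream
#' segmentation: the bright strip of the examination bed, and the
#' subcutaneous fat layer just under the skin, which contains no lymph nodes
#' but shares the gray range of the perigastric fat that does. Preprocessing
#' removes both:
#'
#' 1. [binarize_body()] thresholds the raw slice (by default with a
#'    single-level Otsu cut) into air background vs. everything else.
#' 2. [remove_bed()] closes small cavities, erodes, keeps the largest
#'    8-connected component (the body), restores the erosion by dilating the
#'    kept component back inside the closed mask, and fills internal holes
#'    (gas). Everything else — the strip-shaped bed in particular — is
#'    zeroed.
#' 3. [outermost_pixels()] scans every row and column of the body mask for
#'    its first and last foreground pixel (the 4-direction outer contour).
#' 4. [strip_subcutaneous_band()] zeroes the union of
#'    `band_window x band_window` windows centered on each outermost pixel,
#'    intersected with the body: a band of roughly `band_window/2` pixels
#'    depth along the skin, i.e. the subcutaneous fat layer.
#'
#' [preprocess_slice()] runs all four in order and returns every
#' intermediate mask.
#'
#' @param img gray image matrix.
#' @param level gray threshold in `[0, 255]`; pixels strictly above it are
#'   foreground. `NULL` (default in [preprocess_slice()]) selects the level
#'   with a single-level Otsu cut on the raw histogram.
#' @return [binarize_body()]: a binary mask.
#' @export
binarize_body <- function(img, level) {
  img <- as_gray_image(img)
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level > 255) {
    stop_validation("binarization level must be in [0, 255]")
  }
  as_binary_mask(img > level)
}

#' @rdname binarize_body
#' @param body binary body-candidate mask derived from `img`.
#' @param close_se structuring element for the closing step (default 5x5
#'   square, large enough to seal 1-pixel cavities).
#' @param erode_se structuring element for the erosion step (default 3x3
#'   square, enough to detach the thin bed strip).
#' @return [remove_bed()]: a list with `cleaned` (gray image, non-body
#'   pixels zeroed), `body_mask`, and `removed_bed` (all foreground that was
#'   discarded).
#' @export
remove_bed <- function(img, body,
                       close_se = structuring_element("square", 5L),
                       erode_se = structuring_element("square", 3L)) {
  img <- as_gray_image(img)
  body <- as_binary_mask(body)
  check_same_shape(img, body, "body mask")
  if (sum(body) == 0L) stop_degenerate("all-background image: empty body mask")
  work <- closing(body, close_se)
  eroded <- erode(work, erode_se)
  if (sum(eroded) == 0L) stop_degenerate("body mask vanished under erosion")
  core <- largest_component(eroded, connectivity = 8L)
  # undo the erosion inside the closed mask, then absorb internal cavities
  body_mask <- dilate(core, erode_se)
  body_mask <- as_binary_mask(body_mask == 1L & work == 1L)
  body_mask <- fill_holes(body_mask)
  removed <- as_binary_mask(body == 1L & body_mask == 0L)
  cleaned <- img
  cleaned[body_mask == 0L] <- 0L
  list(cleaned = as_gray_image(cleaned), body_mask = body_mask,
       removed_bed = removed)
}

#' @rdname binarize_body
#' @return [outermost_pixels()]: an integer matrix with columns `row`, `col`
#'   (1-based), the union over rows and columns of each line's first and
#'   last foreground pixel. Every returned pixel is foreground.
#' @export
outermost_pixels <- function(body) {
  body <- as_binary_mask(body)
  if (sum(body) == 0L) stop_degenerate("empty body mask")
  nr <- nrow(body); nc <- ncol(body)
  pts <- matrix(0L, 0L, 2L)
  for (r in seq_len(nr)) {
    w <- which(body[r, ] == 1L)
    if (length(w)) pts <- rbind(pts, c(r, w[1L]), c(r, w[length(w)]))
  }
  for (cl in seq_len(nc)) {
    w <- which(body[, cl] == 1L)
    if (length(w)) pts <- rbind(pts, c(w[1L], cl), c(w[length(w)], cl))
  }
  pts <- unique(pts)
  colnames(pts) <- c("row", "col")
  pts
}

#' @rdname binarize_body
#' @param band_window odd window width in pixels (default 15): each
#'   outermost pixel is the center of a `band_window x band_window` window;
#'   the union of windows, clipped to the body, is the removed band.
#' @return [strip_subcutaneous_band()]: list with `cleaned` (band zeroed)
#'   and `removed_band` (binary mask of zeroed pixels).
#' @export
strip_subcutaneous_band <- function(img, body, band_window = 15L) {
  img <- as_gray_image(img)
  body <- as_binary_mask(body)
  check_same_shape(img, body, "body mask")
  band_window <- as.integer(band_window)
  if (is.na(band_window) || band_window < 3L || band_window %% 2L == 0L) {
    stop_validation("band_window must be an odd integer >= 3")
  }
  pts <- outermost_pixels(body)
  seeds <- matrix(0L, nrow(body), ncol(body))
  seeds[pts] <- 1L
  band <- dilate(seeds, structuring_element("square", band_window))
  band <- as_binary_mask(band == 1L & body == 1L)
  cleaned <- img
  cleaned[band == 1L] <- 0L
  list(cleaned = as_gray_image(cleaned), removed_band = band)
}

#' @rdname binarize_body
#' @details The default binarization threshold of [preprocess_slice()] is a
#'   single-level Otsu cut on the raw slice; pass `level` to fix it.
#' @return [preprocess_slice()]: a list of class `preprocess_result` with
#'   `cleaned` (gray image with all no-interest pixels zeroed), `body_mask`,
#'   `removed_bed`, `removed_band`, `interior` (body minus band — the pixels
#'   segmentation evaluates) and `body_threshold`.
#' @export
preprocess_slice <- function(img, level = NULL,
                             close_se = structuring_element("square", 5L),
                             erode_se = structuring_element("square", 3L),
                             band_window = 15L) {
  img <- as_gray_image(img)
  if (is.null(level)) {
    level <- otsu_threshold(gray_histogram(img))$threshold
  }
  body0 <- binarize_body(img, level)
  bed <- remove_bed(img, body0, close_se = close_se, erode_se = erode_se)
  band <- strip_subcutaneous_band(bed$cleaned, bed$body_mask,
                                  band_window = band_window)
  interior <- as_binary_mask(bed$body_mask == 1L & band$removed_band == 0L)
  structure(list(cleaned = band$cleaned,
                 body_mask = bed$body_mask,
                 removed_bed = bed$removed_bed,
                 removed_band = band$removed_band,
                 interior = interior,
                 body_threshold = level),
            class = "preprocess_result")
}
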