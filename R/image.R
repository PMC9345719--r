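#' Gray images, binary masks and label maps
#'
#' The package represents a 2-D grayscale CT slice as a plain integer matrix
#' with values in `[0, 255]` (a *gray image*), a segmentation mask as an
#' integer matrix of `{0, 1}` (a *binary mask*), and a multi-class
#' segmentation as an integer matrix of `{-1, 0, ..., k-1}` where `-1` marks
#' ignored pixels (a *label map*). Matrices use R's usual `[row, column]`
#' indexing; annotation coordinates are 0-based `(row, col)` with pixel
#' `(0, 0)` at the top-left, and are converted at the I/O boundary.
#'
#' `as_gray_image()` and `as_binary_mask()` coerce and validate; they are
#' cheap and used at every public entry point so that downstream code can
#' assume the invariants.
#'
#' @param x a numeric matrix.
#' @return `as_gray_image()`: an integer matrix in `[0, 255]`;
#'   `as_binary_mask()`: an integer matrix of 0/1.
#' @examples
#' img <- as_gray_image(matrix(0:254, 5, 51))
#' m <- as_binary_mask(img > 100)
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_validation("a gray image must be a numeric matrix")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop_validation("a gray image must have at least one row and one column")
  }
  if (anyNA(x)) stop_validation("gray image contains NA pixels")
  v <- as.vector(x)
  if (any(v < 0 | v > 255) || any(v != trunc(v))) {
    stop_validation("gray image values must be integers in [0, 255]")
  }
  storage.mode(x) <- "integer"
  x
}

#' @rdname as_gray_image
#' @export
as_binary_mask <- function(x) {
  if (is.matrix(x) && is.logical(x)) {
    storage.mode(x) <- "integer"
    return(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_validation("a binary mask must be a numeric or logical matrix")
  }
  if (anyNA(x)) stop_validation("binary mask contains NA pixels")
  if (!all(x == 0L | x == 1L)) {
    stop_validation("binary mask values must be 0 or 1")
  }
  storage.mode(x) <- "integer"
  x
}

# Internal: check that two matrices share a shape.
check_same_shape <- function(a, b, what = "mask") {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
    stop_validation("%s shape (%d x %d) does not match image shape (%d x %d)",
                    what, nrow(b), ncol(b), nrow(a), ncol(a))
  }
  invisible(TRUE)
}

# Internal: integer matrix shift by (dr, dc) with zero fill. Pixel (r, c) of
# the output holds input pixel (r - dr, c - dc); out-of-image reads are 0.
shift_matrix <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1L, 1L + dr):min(nr, nr + dr)
  c_dst <- max(1L, 1L + dc):min(nc, nc + dc)
  if (dr >= nr || dr <= -nr || dc >= nc || dc <= -nc) return(out)
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc, drop = FALSE]
  out
}
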