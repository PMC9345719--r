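#' Structuring elements for binary morphology
#'
#' A structuring element is the set of integer pixel offsets that probes the
#' image in [dilate()], [erode()], [open()] and [close()]. Three shapes are
#' provided: a full `size x size` square, a discrete disk (offsets with
#' Euclidean norm at most `(size - 1)/2`), and an axis-aligned cross. All
#' three contain the origin, so dilation is extensive and erosion
#' anti-extensive.
#'
#' @param shape one of `"square"`, `"disk"`, `"cross"`.
#' @param size odd side length / diameter in pixels (>= 1).
#' @return an object of class `structuring_element` with an `offsets` matrix
#'   (columns `dr`, `dc`).
#' @examples
#' structuring_element("square", 3)
#' structuring_element("disk", 5)
#' @export
structuring_element <- function(shape = c("square", "disk", "cross"), size = 3L) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (is.na(size) || size < 1L || size %% 2L == 0L) {
    stop_validation("structuring element size must be a positive odd integer")
  }
  r <- (size - 1L) %/% 2L
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- switch(shape,
    square = rep(TRUE, nrow(g)),
    disk = g$dr^2 + g$dc^2 <= r^2 + 1e-9,
    cross = g$dr == 0L | g$dc == 0L
  )
  offsets <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(offsets) <- "integer"
  rownames(offsets) <- NULL
  structure(list(offsets = offsets, shape = shape, size = size),
            class = "structuring_element")
}

#' @rdname structuring_element
#' @param se a structuring element.
#' @details `reflect_se()` negates every offset (point reflection through the
#'   origin); for the symmetric shapes built here it is the identity, but it
#'   is applied wherever duality demands it so asymmetric custom elements
#'   behave correctly too.
#' @export
reflect_se <- function(se) {
  se <- as_structuring_element(se)
  se$offsets <- -se$offsets
  se
}

as_structuring_element <- function(se) {
  if (inherits(se, "structuring_element")) return(se)
  if (is.matrix(se) && ncol(se) == 2L) {
    storage.mode(se) <- "integer"
    return(structure(list(offsets = se, shape = "custom", size = NA_integer_),
                     class = "structuring_element"))
  }
  stop_validation("not a structuring element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("structuring element: %s, size %s, %d offsets\n",
              x$shape, x$size, nrow(x$offsets)))
  invisible(x)
}

#' Binary morphological operators
#'
#' Set-theoretic morphology on binary masks. Dilation marks a pixel
#' foreground when the reflected element placed at that pixel intersects the
#' input foreground; erosion when the element translated to the pixel fits
#' entirely inside the foreground. Opening is erosion followed by dilation
#' with the same element (removes bright specks smaller than the element);
#' closing is dilation followed by erosion (fills dark cavities). Pixels
#' outside the image count as background: erosion removes a border rim and
#' dilation never wraps.
#'
#' @param h a binary mask (see [as_binary_mask()]).
#' @param se a [structuring_element()] (or an offsets matrix).
#' @return a binary mask of the same shape.
#' @examples
#' m <- matrix(0L, 5, 5); m[3, 3] <- 1L
#' sum(dilate(m, structuring_element("square", 3)))  # 9
#' @export
dilate <- function(h, se = structuring_element("square", 3L)) {
  h <- as_binary_mask(h)
  se <- as_structuring_element(se)
  # a square decomposes into a vertical strip dilated by a horizontal strip,
  # turning size^2 shifts into 2*size
  if (identical(se$shape, "square") && isTRUE(se$size >= 5L)) {
    parts <- square_strips(se$size)
    return(dilate(dilate(h, parts$v), parts$h))
  }
  acc <- matrix(FALSE, nrow(h), ncol(h))
  off <- se$offsets
  for (i in seq_len(nrow(off))) {
    acc <- acc | shift_matrix(h, off[i, 1L], off[i, 2L]) == 1L
  }
  as_binary_mask(acc)
}

square_strips <- function(size) {
  r <- (size - 1L) %/% 2L
  list(v = as_structuring_element(cbind(-r:r, 0L)),
       h = as_structuring_element(cbind(0L, -r:r)))
}

#' @rdname dilate
#' @export
erode <- function(h, se = structuring_element("square", 3L)) {
  h <- as_binary_mask(h)
  se <- as_structuring_element(se)
  if (identical(se$shape, "square") && isTRUE(se$size >= 5L)) {
    parts <- square_strips(se$size)
    return(erode(erode(h, parts$v), parts$h))
  }
  acc <- matrix(TRUE, nrow(h), ncol(h))
  off <- se$offsets
  for (i in seq_len(nrow(off))) {
    acc <- acc & shift_matrix(h, -off[i, 1L], -off[i, 2L]) == 1L
  }
  as_binary_mask(acc)
}

#' @rdname dilate
#' @details `opening()`/`closing()` follow the usual names of image-analysis
#'   toolkits to avoid masking base R's `open()`/`close()` connection
#'   generics.
#' @export
opening <- function(h, se = structuring_element("square", 3L)) {
  dilate(erode(h, se), se)
}

#' @rdname dilate
#' @export
closing <- function(h, se = structuring_element("square", 3L)) {
  erode(dilate(h, se), se)
}
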