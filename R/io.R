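#' Hounsfield-unit display windowing
#'
#' A windowing specification maps the Hounsfield interval
#' `[center - width/2, center + width/2]` linearly onto display gray levels
#' `[0, 255]`; HU values outside the window saturate at 0 or 255. The package
#' default (center 40 HU, width 400 HU) is the usual abdominal soft-tissue
#' preset and is applied to DICOM input that carries no window tags.
#'
#' @param center window center in Hounsfield units.
#' @param width window width in Hounsfield units; must be positive.
#' @return an object of class `windowing_spec`.
#' @examples
#' w <- windowing_spec(40, 400)
#' apply_windowing(matrix(c(-500, 40, 600), 1), w)  # 0, 128, 255
#' @export
windowing_spec <- function(center = 40, width = 400) {
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center)) {
    stop_validation("window center must be a finite number")
  }
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0) {
    stop_validation("window width must be a positive number")
  }
  structure(list(center = center, width = width), class = "windowing_spec")
}

#' @rdname windowing_spec
#' @param hu numeric matrix of Hounsfield units.
#' @param windowing a [windowing_spec()].
#' @export
apply_windowing <- function(hu, windowing) {
  if (!inherits(windowing, "windowing_spec")) {
    stop_validation("`windowing` must be a windowing_spec")
  }
  lo <- windowing$center - windowing$width / 2
  g <- round((hu - lo) / windowing$width * 255)
  g[g < 0] <- 0
  g[g > 255] <- 255
  as_gray_image(g)
}

#' Read a grayscale image
#'
#' Reads an 8-bit grayscale raster from PNG, PGM (plain `P2` or binary `P5`)
#' or single-frame uncompressed DICOM. The format is detected from the file's
#' magic bytes, not its extension. PNG input must be single-channel or have
#' identical RGB channels (lossless grayscale); DICOM pixel values are
#' rescaled to Hounsfield units and then windowed to `[0, 255]` with
#' `windowing` (falling back to the file's window tags, then to the abdominal
#' preset of [windowing_spec()]).
#'
#' @param path path to the image file.
#' @param windowing optional [windowing_spec()]; only used for DICOM input.
#' @return an integer gray image matrix (see [as_gray_image()]).
#' @export
read_gray_image <- function(path, windowing = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_io("cannot read image: file not found: %s", path)
  }
  n <- file.size(path)
  head_bytes <- readBin(path, "raw", n = min(n, 160L))
  png_magic <- as.raw(c(0x89, 0x50, 0x4e, 0x47))
  if (n >= 4 && identical(head_bytes[1:4], png_magic)) {
    return(read_png_gray(path))
  }
  if (n >= 2 && head_bytes[1] == charToRaw("P") &&
      head_bytes[2] %in% charToRaw("25")) {
    return(read_pgm(path))
  }
  if (n >= 132 && identical(rawToChar(head_bytes[129:132]), "DICM")) {
    return(read_dicom_image(path, windowing = windowing))
  }
  stop_io("unrecognized image format (not PNG, PGM or DICOM): %s", path)
}

read_png_gray <- function(path) {
  a <- tryCatch(png::readPNG(path), error = function(e) {
    stop_io("failed to read PNG %s: %s", path, conditionMessage(e))
  })
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3L]
    if (nch == 2L) {                      # gray + alpha
      a <- a[, , 1L]
    } else if (nch %in% c(3L, 4L)) {
      if (!isTRUE(all(a[, , 1L] == a[, , 2L]) && all(a[, , 1L] == a[, , 3L]))) {
        stop_io("PNG %s is not losslessly convertible to grayscale", path)
      }
      a <- a[, , 1L]
    } else {
      stop_io("unsupported PNG channel count (%d): %s", nch, path)
    }
  }
  as_gray_image(round(a * 255))
}

#' Write a gray image or a binary mask as 8-bit PNG
#'
#' `write_gray_image()` stores the matrix as an 8-bit grayscale PNG;
#' `write_mask()` maps mask value 1 to gray 255 and 0 to 0, so that reading
#' the file back and thresholding at 128 recovers the mask exactly.
#'
#' @param img gray image matrix.
#' @param mask binary mask matrix.
#' @param path output path; the parent directory must exist.
#' @return the path, invisibly.
#' @export
write_gray_image <- function(img, path) {
  img <- as_gray_image(img)
  if (!dir.exists(dirname(path))) {
    stop_io("cannot write %s: directory does not exist", path)
  }
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' @rdname write_gray_image
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  write_gray_image(mask * 255L, path)
}

#' @rdname write_gray_image
#' @details A mask PNG read back with [read_gray_image()] is recovered with
#'   `read_mask()`, which thresholds at gray level 128.
#' @export
read_mask <- function(path) {
  as_binary_mask(read_gray_image(path) >= 128L)
}

# ---- PGM (portable graymap), plain and raw, maxval <= 255 ------------------
# Kept as a human-readable fixture format: a P2 file is valid text.

read_pgm <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  txt_head <- rawToChar(raw_all[seq_len(min(length(raw_all), 512L))])
  magic <- substr(txt_head, 1, 2)
  if (!magic %in% c("P2", "P5")) stop_io("not a PGM file: %s", path)
  # tokenize header: magic, width, height, maxval (comments start with '#')
  toks <- character(0); pos <- 3L; n <- length(raw_all)
  while (length(toks) < 3L && pos <= n) {
    ch <- rawToChar(raw_all[pos])
    if (ch == "#") {
      while (pos <= n && rawToChar(raw_all[pos]) != "\n") pos <- pos + 1L
    } else if (grepl("[[:space:]]", ch)) {
      pos <- pos + 1L
    } else {
      start <- pos
      while (pos <= n && !grepl("[[:space:]]", rawToChar(raw_all[pos]))) pos <- pos + 1L
      toks <- c(toks, rawToChar(raw_all[start:(pos - 1L)]))
    }
  }
  if (length(toks) < 3L) stop_io("truncated PGM header: %s", path)
  w <- as.integer(toks[1]); h <- as.integer(toks[2]); maxval <- as.integer(toks[3])
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval < 1L || maxval > 255L) {
    stop_io("unsupported PGM header (maxval must be <= 255): %s", path)
  }
  pos <- pos + 1L  # single whitespace after maxval
  if (magic == "P5") {
    if (n - pos + 1L < w * h) stop_io("truncated PGM pixel data: %s", path)
    v <- as.integer(raw_all[pos:(pos + w * h - 1L)])
  } else {
    v <- scan(text = rawToChar(raw_all[pos:n]), what = integer(), quiet = TRUE)
    if (length(v) < w * h) stop_io("truncated PGM pixel data: %s", path)
    v <- v[seq_len(w * h)]
  }
  as_gray_image(matrix(v, nrow = h, ncol = w, byrow = TRUE))
}

#' @rdname write_gray_image
#' @param plain write plain-text `P2` (default) rather than binary `P5`.
#' @export
write_pgm <- function(img, path, plain = TRUE) {
  img <- as_gray_image(img)
  if (!dir.exists(dirname(path))) {
    stop_io("cannot write %s: directory does not exist", path)
  }
  h <- nrow(img); w <- ncol(img)
  if (plain) {
    rows <- apply(img, 1L, paste, collapse = " ")
    writeLines(c("P2", paste(w, h), "255", rows), path)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.vector(t(img))), con)
  }
  invisible(path)
}

# ---- annotations -----------------------------------------------------------

#' Read and write lymph-node annotations
#'
#' Annotations are stored as JSON with the schema
#' `{"slices": [{"id": str, "nodes": [{"centroid": [r, c], "radius": num,
#' "embedded": bool}]}]}` where `centroid` is 0-based `(row, col)` and
#' `embedded` (optional) flags nodes fully surrounded by fat. Coordinates are
#' validated to be non-negative and, when `image_size = c(P, Q)` is supplied,
#' strictly inside the image.
#'
#' @param path JSON file path.
#' @param image_size optional `c(rows, cols)` bound for centroid validation.
#' @return a named list of slice records, each a list with `id` and a
#'   data.frame `nodes` with columns `row`, `col`, `radius`, `embedded`.
#' @export
read_annotations <- function(path, image_size = NULL) {
  if (!file.exists(path)) stop_io("annotation file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_validation("malformed annotation JSON %s: %s",
                                    path, conditionMessage(e))
                  })
  if (!is.list(doc) || is.null(doc$slices)) {
    stop_validation("annotation JSON must contain a \"slices\" array: %s", path)
  }
  recs <- lapply(doc$slices, function(sl) {
    if (is.null(sl$id)) stop_validation("annotation slice without an id")
    nodes <- sl$nodes %||% list()
    df <- if (length(nodes) == 0L) {
      data.frame(row = numeric(0), col = numeric(0),
                 radius = numeric(0), embedded = logical(0))
    } else {
      do.call(rbind, lapply(nodes, function(nd) {
        cen <- unlist(nd$centroid)
        if (length(cen) != 2L || !is.numeric(cen) || anyNA(cen)) {
          stop_validation("slice %s: node centroid must be numeric [row, col]",
                          sl$id)
        }
        if (any(cen < 0)) {
          stop_validation("slice %s: centroid (%g, %g) out of bounds",
                          sl$id, cen[1], cen[2])
        }
        if (!is.null(image_size) &&
            (cen[1] >= image_size[1] || cen[2] >= image_size[2])) {
          stop_validation("slice %s: centroid (%g, %g) outside %d x %d image",
                          sl$id, cen[1], cen[2], image_size[1], image_size[2])
        }
        r <- nd$radius %||% NA_real_
        if (!is.na(r) && (!is.numeric(r) || r < 0)) {
          stop_validation("slice %s: node radius must be non-negative", sl$id)
        }
        data.frame(row = cen[1], col = cen[2], radius = as.numeric(r),
                   embedded = isTRUE(nd$embedded))
      }))
    }
    list(id = as.character(sl$id), nodes = df)
  })
  stats::setNames(recs, vapply(recs, `[[`, character(1), "id"))
}

#' @rdname read_annotations
#' @param slices a named list of slice records in the shape returned by
#'   `read_annotations()`.
#' @export
write_annotations <- function(slices, path) {
  payload <- list(slices = unname(lapply(slices, function(sl) {
    nodes <- lapply(seq_len(nrow(sl$nodes)), function(i) {
      nd <- sl$nodes[i, ]
      list(centroid = c(nd$row, nd$col), radius = nd$radius,
           embedded = nd$embedded)
    })
    list(id = sl$id, nodes = nodes)
  })))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
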