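#' Regional mean/variance consistency features
#'
#' For every evaluated pixel, a `window x window` neighborhood (clipped at
#' the image border; `m` is the in-image pixel count) yields the regional
#' mean `U = sum(l_e) / m` and the regional variance
#' `delta = sum((l_e - U)^2)`. Following the defining formula, `delta` is an
#' *unnormalized* sum of squared deviations; `normalize = TRUE` divides by
#' `m`. Because the consistency threshold is data-driven, both modes give
#' the same consistent/ROI partition when every window has the same size.
#'
#' Organs such as the liver have near-uniform gray and hence near-zero
#' regional variance; the perigastric region — a mixture of fat, vessels and
#' lymph nodes — has high regional variance. [consistency_split()] bins the
#' regional *standard deviation* (`sqrt(delta)`, gray units) into a 256-bin
#' histogram, applies a single-level Otsu cut to it, and partitions the
#' evaluated pixels into the *consistent area* (below the cut) and the
#' *region of interest* (at or above it). Binning on the gray-unit scale
#' rather than raw `delta` matters: variance is quadratic in contrast, so a
#' handful of extreme-contrast pixels (windows straddling the zeroed
#' no-interest band) would otherwise compress all genuine tissue
#' heterogeneity into the lowest variance bins and push the Otsu cut far
#' above it.
#'
#' @param img gray image matrix.
#' @param roi optional binary mask of pixels to evaluate (e.g. the body
#'   interior after preprocessing); features outside are `NA`.
#' @param window odd window width, >= 3 (default 25).
#' @param normalize divide the variance by the window pixel count.
#' @return an object of class `region_feature_map`: list with matrices
#'   `mean` and `var`, the in-window pixel counts `m`, `window` and
#'   `normalized`.
#' @export
region_features <- function(img, roi = NULL, window = 25L, normalize = FALSE) {
  img <- as_gray_image(img)
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L) {
    stop_validation("feature window must be an odd integer >= 3")
  }
  nr <- nrow(img); nc <- ncol(img)
  if (window > nr && window > nc) {
    stop_validation("feature window (%d) larger than both image dimensions (%d x %d)",
                    window, nr, nc)
  }
  r <- (window - 1L) %/% 2L
  X <- matrix(as.numeric(img), nr, nc)
  S1 <- integral_window_sum(X, r)
  S2 <- integral_window_sum(X * X, r)
  lo_r <- pmax(seq_len(nr) - r, 1L); hi_r <- pmin(seq_len(nr) + r, nr)
  lo_c <- pmax(seq_len(nc) - r, 1L); hi_c <- pmin(seq_len(nc) + r, nc)
  m <- outer(hi_r - lo_r + 1L, hi_c - lo_c + 1L)
  storage.mode(m) <- "integer"      # outer() promotes to double
  U <- S1 / m
  V <- S2 - S1 * U          # = sum(l^2) - m*U^2, exact integer numerators
  V[V < 0] <- 0             # guard tiny negative rounding on constant windows
  if (normalize) V <- V / m
  if (!is.null(roi)) {
    roi <- as_binary_mask(roi)
    check_same_shape(img, roi, "feature roi")
    U[roi == 0L] <- NA_real_
    V[roi == 0L] <- NA_real_
  }
  structure(list(mean = U, var = V, m = m, window = window,
                 normalized = normalize),
            class = "region_feature_map")
}

# Window sums via a zero-padded integral image.
integral_window_sum <- function(X, r) {
  nr <- nrow(X); nc <- ncol(X)
  cs <- apply(X, 2L, cumsum)
  if (nr == 1L) cs <- matrix(cs, 1L, nc)
  cs <- t(apply(cs, 1L, cumsum))
  if (nc == 1L) cs <- matrix(cs, nr, 1L)
  I <- matrix(0, nr + 1L, nc + 1L)
  I[-1L, -1L] <- cs
  lo_r <- pmax(seq_len(nr) - r, 1L); hi_r <- pmin(seq_len(nr) + r, nr)
  lo_c <- pmax(seq_len(nc) - r, 1L); hi_c <- pmin(seq_len(nc) + r, nc)
  I[hi_r + 1L, hi_c + 1L, drop = FALSE] -
    I[lo_r, hi_c + 1L, drop = FALSE] -
    I[hi_r + 1L, lo_c, drop = FALSE] +
    I[lo_r, lo_c, drop = FALSE]
}

#' @rdname region_features
#' @param features a `region_feature_map`.
#' @return [consistency_split()]: list with binary masks `consistent` and
#'   `roi_of_interest` (a partition of the evaluated pixels), the variance
#'   `threshold` on the original scale, and `degenerate` (`TRUE` when all
#'   variances were equal and everything was marked consistent, with a
#'   warning).
#' @export
consistency_split <- function(features) {
  if (!inherits(features, "region_feature_map")) {
    stop_validation("`features` must come from region_features()")
  }
  V <- features$var
  evaluated <- !is.na(V)
  if (!any(evaluated)) stop_validation("feature map has no evaluated pixels")
  v <- sqrt(V[evaluated])            # gray-unit scale
  consistent <- matrix(0L, nrow(V), ncol(V))
  roi <- matrix(0L, nrow(V), ncol(V))
  vmax <- max(v)
  degenerate <- FALSE
  if (vmax <= 0 || min(v) == vmax) {
    warn_rootsu("all regional variances are equal; whole area marked consistent")
    consistent[evaluated] <- 1L
    degenerate <- TRUE
    thr <- vmax^2
  } else {
    width <- vmax / 256
    bins <- pmin(floor(v / width), 255)
    counts <- tabulate(bins + 1L, nbins = 256L)
    h <- histogram_from_counts(counts)
    if (sum(counts > 0L) < 2L) {
      warn_rootsu("degenerate variance histogram; whole area marked consistent")
      consistent[evaluated] <- 1L
      degenerate <- TRUE
      thr <- vmax^2
    } else {
      d <- otsu_threshold(h)$threshold
      thr <- ((d + 1) * width)^2      # reported on the variance scale
      is_cons <- bins <= d
      consistent[evaluated][is_cons] <- 1L
      roi[evaluated][!is_cons] <- 1L
    }
  }
  list(consistent = as_binary_mask(consistent),
       roi_of_interest = as_binary_mask(roi),
       threshold = thr, degenerate = degenerate)
}

#' Gray-level histogram of an 8-bit image
#'
#' Counts pixels at each gray level `b` in `0..255` and normalizes to
#' frequencies `p(b)` that sum to one over the counted pixels (the whole
#' `P x Q` image, or the `roi` foreground when given).
#'
#' @param img gray image matrix.
#' @param roi optional binary mask restricting the count.
#' @return an object of class `gray_histogram`: list with integer `counts`
#'   (length 256), `freq` and `n` (pixels counted).
#' @export
gray_histogram <- function(img, roi = NULL) {
  img <- as_gray_image(img)
  v <- if (is.null(roi)) {
    as.vector(img)
  } else {
    roi <- as_binary_mask(roi)
    check_same_shape(img, roi, "histogram roi")
    img[roi == 1L]
  }
  if (length(v) == 0L) stop_validation("empty roi: no pixels to count")
  histogram_from_counts(tabulate(v + 1L, nbins = 256L))
}

#' @rdname gray_histogram
#' @param counts integer vector of length 256 (levels `0..255`).
#' @export
histogram_from_counts <- function(counts) {
  if (length(counts) != 256L || any(counts < 0) || anyNA(counts)) {
    stop_validation("histogram counts must be 256 non-negative values")
  }
  n <- sum(counts)
  if (n == 0) stop_validation("histogram has no pixels")
  structure(list(counts = as.numeric(counts), freq = counts / n, n = n),
            class = "gray_histogram")
}

occupied_levels <- function(hist) sum(hist$counts > 0)

#' Otsu statistics for a threshold set
#'
#' For thresholds `d_1 < ... < d_{k-1}` partitioning levels into classes
#' `j = 0..k-1` (class `j` holds levels in `(d_j-1, d_j]`), returns the class
#' proportions `phi_j`, pixel counts `M_j = n * phi_j`, class means
#' `kappa_j`, the total mean `kappa_total = sum(phi_j * kappa_j)` and the
#' between-class variance
#' `varB = sum(phi_j * (kappa_j - kappa_total)^2)`. An empty class
#' contributes zero and has mean `NA`.
#'
#' @param hist a [gray_histogram()].
#' @param thresholds strictly increasing integer gray levels in `[0, 254]`.
#' @return an object of class `otsu_stats`.
#' @export
otsu_stats <- function(hist, thresholds) {
  check_histogram(hist)
  thresholds <- check_thresholds(thresholds)
  lv <- 0:255
  cls <- findInterval(lv, thresholds + 0.5)
  k <- length(thresholds) + 1L
  phi <- vapply(0:(k - 1L), function(j) sum(hist$freq[cls == j]), numeric(1))
  kap <- vapply(0:(k - 1L), function(j) {
    w <- sum(hist$freq[cls == j])
    if (w == 0) NA_real_ else sum(lv[cls == j] * hist$freq[cls == j]) / w
  }, numeric(1))
  kap_total <- sum(lv * hist$freq)
  contrib <- ifelse(phi > 0, phi * (kap - kap_total)^2, 0)
  structure(list(thresholds = thresholds, k = k,
                 phi = phi, M = phi * hist$n, kappa = kap,
                 kappa_total = kap_total,
                 between_var = sum(contrib)),
            class = "otsu_stats")
}

check_histogram <- function(hist) {
  if (!inherits(hist, "gray_histogram")) {
    stop_validation("`hist` must be a gray_histogram")
  }
  invisible(hist)
}

check_thresholds <- function(thresholds) {
  thresholds <- as.integer(thresholds)
  if (length(thresholds) < 1L || anyNA(thresholds) ||
      any(thresholds < 0L | thresholds > 254L) ||
      any(diff(thresholds) <= 0L)) {
    stop_validation("thresholds must be strictly increasing integers in [0, 254]")
  }
  thresholds
}

#' Single- and multi-threshold Otsu segmentation
#'
#' `otsu_threshold()` scans every candidate cut `a` in `0..254`, splitting
#' gray levels into a target class (`levels <= a`) and a background class
#' (`levels > a`), and returns the `a` maximizing the between-class variance;
#' ties are broken by the smallest `a`. `multi_otsu()` generalizes to `k`
#' classes: it returns the strictly increasing thresholds
#' `(d_1, ..., d_{k-1})` that exactly maximize the k-class between-class
#' variance, with ties broken by the lexicographically smallest tuple. The
#' search is an exact dynamic program over the 256 gray levels (cumulative
#' sums of weight and weighted level), equivalent to exhaustive enumeration
#' of all threshold tuples but far cheaper; no heuristic search is involved.
#'
#' @param hist a [gray_histogram()].
#' @return `otsu_threshold()`: list with `threshold` (integer in `[0, 254]`)
#'   and `stats` (an [otsu_stats()] object).
#' @export
otsu_threshold <- function(hist) {
  check_histogram(hist)
  if (occupied_levels(hist) < 2L) {
    stop_degenerate("histogram has a single occupied gray level")
  }
  p <- hist$freq
  lv <- 0:255
  cw <- cumsum(p)
  cmu <- cumsum(p * lv)
  muT <- cmu[256L]
  w0 <- cw[1:255]
  s0 <- cmu[1:255]
  w1 <- 1 - w0
  k0 <- ifelse(w0 > 0, s0 / w0, 0)
  k1 <- ifelse(w1 > 0, (muT - s0) / w1, 0)
  varB <- ifelse(w0 > 0, w0 * (k0 - muT)^2, 0) +
    ifelse(w1 > 0, w1 * (k1 - muT)^2, 0)
  d <- which.max(varB) - 1L   # first maximum = smallest threshold
  list(threshold = d, stats = otsu_stats(hist, d))
}

#' @rdname otsu_threshold
#' @param k number of classes (>= 2); the pipeline default is 4, splitting
#'   an abdominal slice into gas/dark, fat, soft tissue and enhancing
#'   structures.
#' @return `multi_otsu()`: list with `thresholds` (length `k - 1`) and
#'   `stats`.
#' @export
multi_otsu <- function(hist, k = 4L) {
  check_histogram(hist)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop_validation("class count k must be >= 2")
  if (occupied_levels(hist) < k) {
    stop_degenerate("histogram has %d occupied levels; %d classes requested",
                    occupied_levels(hist), k)
  }
  p <- hist$freq
  lv <- 0:255
  cw1 <- c(0, cumsum(p))        # cw1[i+1] = sum of p over levels 0..i
  cx1 <- c(0, cumsum(p * lv))
  # seg(s, t): contribution w * mean^2 of a class covering levels s..t
  seg <- function(s, t) {
    w <- cw1[t + 2L] - cw1[s + 1L]
    x <- cx1[t + 2L] - cx1[s + 1L]
    ifelse(w > 0, x * x / w, 0)
  }
  # G[c, s+1] = best sum of seg over c classes covering levels s..255
  G <- matrix(-Inf, k, 256L)
  G[1L, ] <- seg(0:255, 255L)
  for (cc in 2:k) {
    for (s in 0:(256L - cc)) {
      t <- s:(255L - cc + 1L)
      G[cc, s + 1L] <- max(seg(s, t) + G[cc - 1L, t + 2L])
    }
  }
  # greedy first-argmax reconstruction = lexicographically smallest tuple
  thresholds <- integer(k - 1L)
  s <- 0L
  for (cc in k:2L) {
    t <- s:(255L - cc + 1L)
    vals <- seg(s, t) + G[cc - 1L, t + 2L]
    d <- t[which.max(vals)]
    thresholds[k - cc + 1L] <- d
    s <- d + 1L
  }
  list(thresholds = thresholds, stats = otsu_stats(hist, thresholds))
}

#' Apply a threshold set to an image
#'
#' Labels pixel values in `(d_{j-1}, d_j]` with class `j` (taking `d_0 = -1`
#' and `d_k = 255`), so class 0 is the darkest. Pixels outside `roi` get the
#' ignore label `-1`.
#'
#' @param img gray image matrix.
#' @param thresholds strictly increasing integer thresholds in `[0, 254]`.
#' @param roi optional binary mask; pixels outside are labeled `-1`.
#' @return an integer label-map matrix with values in `{-1, 0, ..., k-1}`.
#' @export
apply_thresholds <- function(img, thresholds, roi = NULL) {
  img <- as_gray_image(img)
  thresholds <- check_thresholds(thresholds)
  lab <- matrix(findInterval(img, thresholds + 0.5), nrow(img), ncol(img))
  storage.mode(lab) <- "integer"
  if (!is.null(roi)) {
    roi <- as_binary_mask(roi)
    check_same_shape(img, roi, "label roi")
    lab[roi == 0L] <- -1L
  }
  lab
}
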