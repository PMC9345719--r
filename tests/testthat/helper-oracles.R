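# Independent brute-force oracles. These deliberately follow the defining
# set/summation formulas with plain loops, sharing no code with the
# implementation paths they check.

# dilation: output pixel is 1 iff the reflected element placed there
# intersects the input foreground
naive_dilate <- function(m, offsets) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    hit <- FALSE
    for (i in seq_len(nrow(offsets))) {
      rr <- r - offsets[i, 1]; cc <- cl - offsets[i, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && m[rr, cc] == 1L) {
        hit <- TRUE; break
      }
    }
    if (hit) out[r, cl] <- 1L
  }
  out
}

# erosion: output pixel is 1 iff the translated element fits in the
# foreground; outside-image counts as background
naive_erode <- function(m, offsets) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    fits <- TRUE
    for (i in seq_len(nrow(offsets))) {
      rr <- r + offsets[i, 1]; cc <- cl + offsets[i, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || m[rr, cc] != 1L) {
        fits <- FALSE; break
      }
    }
    if (fits) out[r, cl] <- 1L
  }
  out
}

# regional mean / unnormalized variance by direct per-pixel loops
naive_region_features <- function(img, window) {
  nr <- nrow(img); nc <- ncol(img)
  r <- (window - 1) %/% 2
  U <- matrix(NA_real_, nr, nc); V <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- img[max(1, i - r):min(nr, i + r), max(1, j - r):min(nc, j + r)]
    u <- sum(vals) / length(vals)
    U[i, j] <- u
    V[i, j] <- sum((vals - u)^2)
  }
  list(mean = U, var = V)
}

# between-class variance of a class partition, straight from the definition
partition_between_var <- function(counts, classes) {
  p <- counts / sum(counts)
  lv <- 0:255
  mu_t <- sum(lv * p)
  v <- 0
  for (cl in classes) {
    w <- sum(p[cl + 1L])
    if (w > 0) v <- v + w * (sum(lv[cl + 1L] * p[cl + 1L]) / w - mu_t)^2
  }
  v
}

# single-threshold oracle: enumerate every candidate cut a in 0..254
oracle_otsu_single <- function(counts) {
  best_v <- -Inf; best_a <- NA_integer_
  for (a in 0:254) {
    v <- partition_between_var(counts, list(0:a, (a + 1L):255L))
    if (v > best_v) { best_v <- v; best_a <- a }
  }
  list(threshold = best_a, between_var = best_v)
}

# multi-threshold oracle: exhaustively enumerate all ways to cut the
# occupied levels into k non-empty runs (with >= k occupied levels no
# optimal threshold tuple leaves a class empty, and the lexicographically
# smallest tuple of an optimal partition puts each cut at the last occupied
# level of its class).
oracle_multi_otsu <- function(counts, k) {
  levels <- which(counts > 0) - 1L
  L <- length(levels)
  stopifnot(L >= k)
  cuts <- utils::combn(L - 1L, k - 1L)
  best_v <- -Inf; best_d <- NULL
  for (i in seq_len(ncol(cuts))) {
    pos <- cuts[, i]
    bounds <- c(0L, pos, L)
    classes <- lapply(seq_len(k), function(j) {
      levels[(bounds[j] + 1L):bounds[j + 1L]]
    })
    v <- partition_between_var(counts, classes)
    d <- levels[pos]
    if (v > best_v + 1e-12 ||
        (abs(v - best_v) <= 1e-12 && lexi_less(d, best_d))) {
      best_v <- v; best_d <- d
    }
  }
  list(thresholds = best_d, between_var = best_v)
}

lexi_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# random 256-bin histogram with at most max_levels occupied levels
random_histogram_counts <- function(max_levels = 32L, min_levels = 2L) {
  nl <- sample(min_levels:max_levels, 1L)
  levels <- sort(sample(0:255, nl))
  counts <- numeric(256)
  counts[levels + 1L] <- sample(1:50, nl, replace = TRUE)
  counts
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(rbinom(nr * nc, 1L, p), nr, nc)
}
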