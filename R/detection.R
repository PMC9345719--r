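#' Fat mask and lymph-node candidate detection
#'
#' After 4-class segmentation of an abdominal slice the classes, ordered by
#' increasing mean gray, are typically: 0 gas/dark structures, 1 fat, 2 soft
#' tissue, 3 enhancing structures (vessels, lymph nodes). Lymph nodes live
#' in the perigastric fat, so candidates are connected components of
#' brighter-than-fat classes lying in or against the fat class.
#'
#' `fat_mask()` extracts the configured fat class (default class 1, the
#' second darkest). `find_candidates()` then takes, for each class brighter
#' than the fat class, the 8-connected components whose dilation by
#' `embed_margin` pixels touches fat, and filters them by area and
#' circularity. Circularity is `4 * pi * area / perimeter^2` with the
#' perimeter measured as the crack length (count of pixel edges between the
#' component and its complement, image border included); on this measure a
#' digital disk scores about 0.6 and elongated or ring-shaped structures
#' (vessels, stomach wall) score far lower, so the default gate of 0.4
#' separates nodes from them. A candidate is `embedded` when every 8-neighbor
#' of the component outside the component is fat — the fully-infiltrated
#' case; nodes pressed against the stomach wall come out `embedded = FALSE`.
#'
#' @param labels an integer label map from [apply_thresholds()].
#' @param fat_class integer label of the fat class (default 1).
#' @return `fat_mask()`: binary mask of the fat class (empty, with a
#'   warning, when the class is absent).
#' @export
fat_mask <- function(labels, fat_class = 1L) {
  labels <- check_label_map(labels)
  m <- as_binary_mask(labels == fat_class)
  if (sum(m) == 0L) {
    warn_rootsu("fat class %d absent from label map; empty fat mask", fat_class)
  }
  m
}

check_label_map <- function(labels) {
  if (!is.matrix(labels) || !is.numeric(labels)) {
    stop_validation("label map must be an integer matrix")
  }
  if (anyNA(labels) || any(labels < -1L)) {
    stop_validation("label map values must be -1 (ignore) or class labels >= 0")
  }
  storage.mode(labels) <- "integer"
  labels
}

#' @rdname fat_mask
#' @param fat binary fat mask (normally `fat_mask(labels, fat_class)`).
#' @param min_area,max_area candidate area gates in pixels.
#' @param min_circularity circularity gate in `(0, 1]`; set 0 to disable
#'   (the *suspected*-node profile keeps only the area gate, the confirmed
#'   profile adds circularity).
#' @param embed_margin adjacency margin in pixels: a component qualifies
#'   when its dilation by a `(2 * embed_margin + 1)` square intersects fat.
#' @return `find_candidates()`: a data.frame with one row per candidate:
#'   `id`, `class`, `area`, `centroid_row`/`centroid_col` (0-based),
#'   `equiv_diameter`, `perimeter`, `circularity`, `embedded`, and a
#'   list-column `pixels` of matrix indices.
#' @export
find_candidates <- function(labels, fat, fat_class = 1L,
                            min_area = 9L, max_area = 2000L,
                            min_circularity = 0.4, embed_margin = 2L) {
  labels <- check_label_map(labels)
  fat <- as_binary_mask(fat)
  check_same_shape(labels, fat, "fat mask")
  if (min_area <= 0 || max_area <= 0 || min_area > max_area) {
    stop_validation("need 0 < min_area <= max_area")
  }
  if (min_circularity < 0 || min_circularity > 1) {
    stop_validation("min_circularity must be in [0, 1]")
  }
  embed_margin <- as.integer(embed_margin)
  if (is.na(embed_margin) || embed_margin < 0L) {
    stop_validation("embed_margin must be a non-negative integer")
  }
  fat_dil <- if (embed_margin > 0L) {
    dilate(fat, structuring_element("square", 2L * embed_margin + 1L))
  } else fat
  nr <- nrow(labels)
  classes <- sort(unique(labels[labels > fat_class]))
  rows <- list()
  nid <- 0L
  for (cls in classes) {
    comp <- label_components(as_binary_mask(labels == cls), connectivity = 8L)
    if (comp$n == 0L) next
    perim <- component_perimeters(comp$labels, comp$n)
    not_emb <- component_embedding_violations(comp$labels, comp$n, fat)
    for (ci in seq_len(comp$n)) {
      idx <- which(comp$labels == ci)
      if (!any(fat_dil[idx] == 1L)) next
      area <- length(idx)
      if (area < min_area || area > max_area) next
      circ <- 4 * pi * area / perim[ci]^2
      if (circ < min_circularity) next
      rr <- (idx - 1L) %% nr
      cc <- (idx - 1L) %/% nr
      nid <- nid + 1L
      rows[[nid]] <- data.frame(
        id = nid, class = cls, area = area,
        centroid_row = mean(rr), centroid_col = mean(cc),
        equiv_diameter = 2 * sqrt(area / pi),
        perimeter = perim[ci], circularity = circ,
        embedded = not_emb[ci] == 0L)
      rows[[nid]]$pixels <- list(idx)
    }
  }
  if (nid == 0L) {
    out <- data.frame(id = integer(0), class = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      equiv_diameter = numeric(0), perimeter = numeric(0),
                      circularity = numeric(0), embedded = logical(0))
    out$pixels <- list()
    return(out)
  }
  do.call(rbind, rows)
}

# Crack-length perimeter per component: for each of the 4 axial directions,
# count pixels whose neighbor in that direction lies outside the component
# (or outside the image).
component_perimeters <- function(lab, n) {
  perim <- numeric(n)
  for (o in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    nb <- shift_matrix(lab, -o[1], -o[2])   # nb[q] = lab[q + o]
    edge <- lab > 0L & nb != lab
    perim <- perim + tabulate(lab[edge], nbins = n)
  }
  perim
}

# Count, per component, 8-neighbors outside the component that are not fat.
# Zero violations = fully embedded in fat.
component_embedding_violations <- function(lab, n, fat) {
  viol <- numeric(n)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (i in seq_len(nrow(offs))) {
    o <- c(offs$dr[i], offs$dc[i])
    nb_lab <- shift_matrix(lab, -o[1], -o[2])
    nb_fat <- shift_matrix(fat, -o[1], -o[2])
    bad <- lab > 0L & nb_lab != lab & nb_fat != 1L
    viol <- viol + tabulate(lab[bad], nbins = n)
  }
  viol
}

#' Match candidates to manually labeled nodes
#'
#' Greedy one-to-one matching by increasing centroid distance: the closest
#' (truth, candidate) pair under `max_dist` is matched first, both are
#' removed, and so on. Unmatched truth nodes are missed detections.
#'
#' @param candidates a data.frame from [find_candidates()] (columns
#'   `centroid_row`, `centroid_col`).
#' @param truth a data.frame of manual nodes with 0-based columns `row`,
#'   `col` (e.g. one slice record from [read_annotations()]); an optional
#'   `id` column must not contain duplicates.
#' @param max_dist maximum centroid distance in pixels (default 5).
#' @return list with `n_truth`, `n_candidates`, `n_matched`, `n_missed` and
#'   a data.frame `pairs` (`truth_idx`, `cand_idx`, `dist`).
#' @export
match_to_ground_truth <- function(candidates, truth, max_dist = 5) {
  if (!is.null(truth$id) && anyDuplicated(truth$id)) {
    stop_validation("duplicate ids in ground-truth nodes")
  }
  nt <- nrow(truth) %||% 0L
  nc <- nrow(candidates) %||% 0L
  pairs <- data.frame(truth_idx = integer(0), cand_idx = integer(0),
                      dist = numeric(0))
  if (nt > 0L && nc > 0L) {
    d <- outer(truth$row, candidates$centroid_row, `-`)^2 +
      outer(truth$col, candidates$centroid_col, `-`)^2
    d <- sqrt(d)
    cand_pairs <- which(d <= max_dist, arr.ind = TRUE)
    if (nrow(cand_pairs) > 0L) {
      ord <- order(d[cand_pairs], cand_pairs[, 1L], cand_pairs[, 2L])
      used_t <- logical(nt); used_c <- logical(nc)
      for (i in ord) {
        ti <- cand_pairs[i, 1L]; cj <- cand_pairs[i, 2L]
        if (used_t[ti] || used_c[cj]) next
        used_t[ti] <- TRUE; used_c[cj] <- TRUE
        pairs <- rbind(pairs, data.frame(truth_idx = ti, cand_idx = cj,
                                         dist = d[ti, cj]))
      }
    }
  }
  list(n_truth = nt, n_candidates = nc, n_matched = nrow(pairs),
       n_missed = nt - nrow(pairs), pairs = pairs)
}
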