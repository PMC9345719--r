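#' Synthetic abdominal CT phantom
#'
#' Generates 2-D slices that emulate an axial abdominal CT after soft-tissue
#' windowing, with full per-tissue ground truth: a dark air background, a
#' thin bright exam-bed strip below the body, an elliptical body wrapped in
#' a subcutaneous fat ring, near-uniform soft-tissue organs, a stomach with
#' a gas lumen, a perigastric fat annulus, and small bright elliptical lymph
#' nodes planted in that annulus — some fully embedded in fat, some pressed
#' against the stomach wall. Additive Gaussian noise (`noise_sd`, clipped to
#' `[0, 255]`) completes the slice. The default 512 x 512 matrix matches the
#' usual CT reconstruction grid; smaller sizes scale every structure
#' proportionally.
#'
#' Default tissue grays mimic an abdominal window: background 5, gas 10,
#' subcutaneous fat 60, perigastric fat 70, organs/stomach wall 120, nodes
#' 170, bed 200 — four well-separated Otsu classes (dark, fat, soft tissue,
#' enhancing) inside the body.
#'
#' @param width,height image size `Q x P` in pixels (default 512 x 512).
#' @param fat_ring subcutaneous fat ring thickness in pixels.
#' @param perigastric_width width of the perigastric fat annulus; must leave
#'   `node_radius[2] + 2` pixels of clearance for embedded nodes.
#' @param bed_thickness,bed_gap exam-bed strip thickness and its gap below
#'   the body, in pixels.
#' @param intensities named vector of mean tissue grays (`background`,
#'   `gas`, `subcut_fat`, `perigastric_fat`, `organ`, `node`, `bed`).
#' @param n_nodes number of lymph nodes to plant.
#' @param node_radius `c(min, max)` node radius in pixels.
#' @param embedded_fraction fraction of nodes fully embedded in fat (the
#'   rest straddle the stomach wall); the embedded count is
#'   `round(embedded_fraction * n_nodes)`.
#' @param noise_sd additive Gaussian noise standard deviation in gray levels.
#' @param seed integer seed fixing the slice bit-exactly.
#' @return `phantom_spec()`: an object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 512L, height = 512L,
                         fat_ring = NULL, perigastric_width = NULL,
                         bed_thickness = 4L, bed_gap = NULL,
                         intensities = c(background = 5, gas = 10,
                                         subcut_fat = 60, perigastric_fat = 70,
                                         organ = 120, node = 170, bed = 200),
                         n_nodes = 5L, node_radius = c(3, 6),
                         embedded_fraction = 0.6,
                         noise_sd = 0, seed = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 96L || height < 96L) {
    stop_validation("phantom must be at least 96 x 96 pixels")
  }
  scale <- min(width, height) / 512
  fat_ring <- fat_ring %||% max(6L, round(12 * scale))
  perigastric_width <- perigastric_width %||%
    max(2L * (as.integer(node_radius[2]) + 2L), round(20 * scale))
  bed_gap <- bed_gap %||% max(8L, round(24 * scale))
  req <- c("background", "gas", "subcut_fat", "perigastric_fat",
           "organ", "node", "bed")
  if (!all(req %in% names(intensities))) {
    stop_validation("intensities must name: %s", paste(req, collapse = ", "))
  }
  if (any(intensities < 0 | intensities > 255)) {
    stop_validation("tissue intensities must lie in [0, 255]")
  }
  ok_order <- intensities["background"] < intensities["subcut_fat"] &&
    intensities["subcut_fat"] <= intensities["perigastric_fat"] &&
    intensities["perigastric_fat"] < intensities["organ"] &&
    intensities["organ"] < intensities["node"]
  if (!ok_order) {
    stop_validation(
      "intensities must be ordered background < fat <= perigastric fat < organ < node")
  }
  if (length(node_radius) != 2L || node_radius[1] < 1 ||
      node_radius[1] > node_radius[2]) {
    stop_validation("node_radius must be c(min, max) with 1 <= min <= max")
  }
  if (n_nodes < 0L) stop_validation("n_nodes must be >= 0")
  if (embedded_fraction < 0 || embedded_fraction > 1) {
    stop_validation("embedded_fraction must be in [0, 1]")
  }
  if (perigastric_width < 2 * (node_radius[2] + 2)) {
    stop_validation(
      "perigastric_width (%d) too narrow to embed nodes of radius %g (need >= %g)",
      perigastric_width, node_radius[2], 2 * (node_radius[2] + 2))
  }
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  structure(list(width = width, height = height,
                 fat_ring = as.integer(fat_ring),
                 perigastric_width = as.integer(perigastric_width),
                 bed_thickness = as.integer(bed_thickness),
                 bed_gap = as.integer(bed_gap),
                 intensities = intensities,
                 n_nodes = as.integer(n_nodes),
                 node_radius = node_radius,
                 embedded_fraction = embedded_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# filled ellipse mask; center/axes in pixels (1-based grid)
ellipse_mask <- function(nr, nc, center, axes) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  as_binary_mask(((rr - center[1]) / axes[1])^2 +
                   ((cc - center[2]) / axes[2])^2 <= 1)
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @return `generate_slice()`: list with `image` (gray image) and `truth`
#'   (list of per-tissue binary masks plus a `nodes` data.frame with 0-based
#'   `row`, `col`, `radius`, `embedded`).
#' @export
generate_slice <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop_validation("`spec` must come from phantom_spec()")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  P <- spec$height; Q <- spec$width
  it <- spec$intensities
  # body geometry: ellipse in the upper/middle of the frame, bed below
  body_center <- c(0.46 * P, 0.50 * Q)
  body_axes <- c(0.33 * P, 0.42 * Q)
  st_center <- body_center + c(0.02 * P, -0.03 * Q)
  st_axes <- 0.36 * body_axes
  gas_axes <- 0.55 * st_axes
  peri_axes <- st_axes + spec$perigastric_width

  body <- ellipse_mask(P, Q, body_center, body_axes)
  inner <- ellipse_mask(P, Q, body_center, body_axes - spec$fat_ring)
  subcut <- as_binary_mask(body == 1L & inner == 0L)
  stomach <- ellipse_mask(P, Q, st_center, st_axes)
  peri_outer <- ellipse_mask(P, Q, st_center, peri_axes)
  if (any(peri_outer == 1L & inner == 0L)) {
    stop_validation("phantom geometry infeasible: perigastric region reaches the subcutaneous ring")
  }
  gas <- ellipse_mask(P, Q, st_center, gas_axes)
  wall <- as_binary_mask(stomach == 1L & gas == 0L)
  perigastric <- as_binary_mask(peri_outer == 1L & stomach == 0L)
  organs <- as_binary_mask(inner == 1L & peri_outer == 0L)

  bed_top <- round(body_center[1] + body_axes[1]) + spec$bed_gap
  bed_rows <- bed_top:min(P, bed_top + spec$bed_thickness - 1L)
  if (max(bed_rows) > P || bed_top <= 0L) {
    stop_validation("phantom geometry infeasible: bed strip falls outside the image")
  }
  bed <- matrix(0L, P, Q)
  bed[bed_rows, round(0.1 * Q):round(0.9 * Q)] <- 1L

  img <- matrix(it[["background"]], P, Q)
  img[subcut == 1L] <- it[["subcut_fat"]]
  img[organs == 1L] <- it[["organ"]]
  img[perigastric == 1L] <- it[["perigastric_fat"]]
  img[wall == 1L] <- it[["organ"]]
  img[gas == 1L] <- it[["gas"]]
  img[bed == 1L] <- it[["bed"]]

  # ---- plant nodes ---------------------------------------------------------
  n_emb <- round(spec$embedded_fraction * spec$n_nodes)
  n_wall <- spec$n_nodes - n_emb
  kinds <- c(rep(TRUE, n_emb), rep(FALSE, n_wall))
  nodes <- data.frame(row = numeric(0), col = numeric(0),
                      radius = numeric(0), embedded = logical(0))
  node_mask <- matrix(0L, P, Q)
  rr <- matrix(seq_len(P), P, Q)
  cc <- matrix(seq_len(Q), P, Q, byrow = TRUE)
  mid_axes <- st_axes + spec$perigastric_width / 2
  for (i in seq_along(kinds)) {
    emb <- kinds[i]
    radius <- round(stats::runif(1, spec$node_radius[1], spec$node_radius[2]))
    placed <- FALSE
    for (try in 1:400) {
      theta <- stats::runif(1, 0, 2 * pi)
      axes <- if (emb) mid_axes else st_axes
      ctr <- c(st_center[1] + axes[1] * cos(theta),
               st_center[2] + axes[2] * sin(theta))
      if (nrow(nodes) > 0L) {
        sep <- sqrt((nodes$row + 1 - ctr[1])^2 + (nodes$col + 1 - ctr[2])^2)
        if (any(sep < nodes$radius + radius + 4)) next
      }
      disk <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= radius^2
      inside <- if (emb) all(perigastric[disk] == 1L) else
        all(perigastric[disk] == 1L | wall[disk] == 1L)
      if (!inside) next
      if (!emb && !any(wall[disk] == 1L)) next
      img[disk] <- it[["node"]]
      node_mask[disk] <- 1L
      nodes <- rbind(nodes, data.frame(row = ctr[1] - 1, col = ctr[2] - 1,
                                       radius = radius, embedded = emb))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop_validation(
        "node placement infeasible: could not place %s node %d (radius %g) in the fat annulus",
        if (emb) "embedded" else "wall-touching", i, radius)
    }
  }

  if (spec$noise_sd > 0) {
    img <- img + round(stats::rnorm(P * Q, 0, spec$noise_sd))
    img[img < 0] <- 0
    img[img > 255] <- 255
  }
  list(image = as_gray_image(img),
       truth = list(bed = as_binary_mask(bed), body = body, subcut = subcut,
                    perigastric = perigastric, organs = organs, wall = wall,
                    gas = gas, nodes_mask = as_binary_mask(node_mask),
                    nodes = nodes),
       spec = spec)
}

#' @rdname phantom_spec
#' @param template a `phantom_spec` used for every slice; each slice gets
#'   its own seed derived from `seed`, the sample index and the slice index.
#' @param n_samples,slices_per_sample cohort shape (the stand-in for a
#'   patient cohort: each sample is one patient, each slice one image).
#' @param out_dir output directory; refuses to write into a non-empty
#'   directory unless `force = TRUE`.
#' @param force overwrite a non-empty `out_dir`.
#' @return `generate_cohort()`: the manifest (invisibly), after writing
#'   `sample_XX/slice_YY.png`, per-sample `truth.json` annotation files and
#'   a `manifest.json` recording the spec and per-slice seeds.
#' @export
generate_cohort <- function(template, n_samples, slices_per_sample,
                            seed = 1L, out_dir, force = FALSE) {
  if (!inherits(template, "phantom_spec")) {
    stop_validation("`template` must come from phantom_spec()")
  }
  n_samples <- as.integer(n_samples)
  slices_per_sample <- as.integer(slices_per_sample)
  if (is.na(n_samples) || n_samples < 1L) {
    stop_validation("n_samples must be >= 1")
  }
  if (is.na(slices_per_sample) || slices_per_sample < 1L) {
    stop_validation("slices_per_sample must be >= 1")
  }
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    stop_io("output directory %s is not empty (use force = TRUE)", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, n_samples = n_samples,
                   slices_per_sample = slices_per_sample,
                   samples = list())
  for (i in seq_len(n_samples)) {
    sdir <- file.path(out_dir, sprintf("sample_%02d", i))
    dir.create(sdir, showWarnings = FALSE)
    slices <- list()
    seeds <- integer(slices_per_sample)
    for (j in seq_len(slices_per_sample)) {
      sl_seed <- (seed + 7919L * i + 104729L * j) %% .Machine$integer.max
      seeds[j] <- sl_seed
      sp <- template
      sp$seed <- sl_seed
      sl <- generate_slice(sp)
      id <- sprintf("s%02d_%03d", i, j)
      write_gray_image(sl$image, file.path(sdir, paste0(id, ".png")))
      slices[[id]] <- list(id = id, nodes = sl$truth$nodes)
    }
    write_annotations(slices, file.path(sdir, "truth.json"))
    manifest$samples[[sprintf("sample_%02d", i)]] <-
      list(dir = sprintf("sample_%02d", i), seeds = seeds)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
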