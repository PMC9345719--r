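#' Pipeline configuration
#'
#' Collects every stage parameter of the slice-processing pipeline, validates
#' them up front, and round-trips losslessly through JSON so a run can be
#' reproduced from its recorded configuration alone. The configuration hash
#' (MD5 of the canonical JSON serialization) is stamped into every artifact.
#'
#' @param body_threshold fixed gray level for body binarization, or `NULL`
#'   (default) for a single-level Otsu cut on the raw slice.
#' @param close_se_shape,close_se_size closing element (default 5x5 square).
#' @param erode_se_shape,erode_se_size erosion element (default 3x3 square).
#' @param band_window subcutaneous band window width (odd, default 15).
#' @param feature_window regional-consistency window width (odd, default 25).
#' @param normalize_variance divide regional variance by the window count.
#' @param n_classes Otsu class count (default 4).
#' @param otsu_roi where the gray histogram is taken: `"body"` (cleaned body
#'   interior, default), `"consistency"` (the high-variance region of
#'   interest) or `"image"` (whole cleaned image).
#' @param fat_class label of the fat class (default 1, second darkest).
#' @param min_area,max_area,min_circularity,embed_margin candidate gates,
#'   see [find_candidates()].
#' @param max_match_dist matching distance in pixels, see
#'   [match_to_ground_truth()].
#' @param include_empty_slices see [missed_rate_suspected()].
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(body_threshold = NULL,
                            close_se_shape = "square", close_se_size = 5L,
                            erode_se_shape = "square", erode_se_size = 3L,
                            band_window = 15L,
                            feature_window = 25L,
                            normalize_variance = FALSE,
                            n_classes = 4L,
                            otsu_roi = c("body", "consistency", "image"),
                            fat_class = 1L,
                            min_area = 9L, max_area = 2000L,
                            min_circularity = 0.4, embed_margin = 2L,
                            max_match_dist = 5,
                            include_empty_slices = FALSE) {
  otsu_roi <- match.arg(otsu_roi)
  cfg <- list(body_threshold = body_threshold,
              close_se_shape = close_se_shape,
              close_se_size = as.integer(close_se_size),
              erode_se_shape = erode_se_shape,
              erode_se_size = as.integer(erode_se_size),
              band_window = as.integer(band_window),
              feature_window = as.integer(feature_window),
              normalize_variance = isTRUE(normalize_variance),
              n_classes = as.integer(n_classes),
              otsu_roi = otsu_roi,
              fat_class = as.integer(fat_class),
              min_area = as.numeric(min_area),
              max_area = as.numeric(max_area),
              min_circularity = as.numeric(min_circularity),
              embed_margin = as.integer(embed_margin),
              max_match_dist = as.numeric(max_match_dist),
              include_empty_slices = isTRUE(include_empty_slices))
  # stage preconditions are validated before any work happens
  structuring_element(cfg$close_se_shape, cfg$close_se_size)
  structuring_element(cfg$erode_se_shape, cfg$erode_se_size)
  if (!is.null(cfg$body_threshold) &&
      (cfg$body_threshold < 0 || cfg$body_threshold > 255)) {
    stop_validation("body_threshold must be in [0, 255]")
  }
  if (cfg$band_window < 3L || cfg$band_window %% 2L == 0L) {
    stop_validation("band_window must be an odd integer >= 3")
  }
  if (cfg$feature_window < 3L || cfg$feature_window %% 2L == 0L) {
    stop_validation("feature_window must be an odd integer >= 3")
  }
  if (cfg$n_classes < 2L) stop_validation("n_classes must be >= 2")
  if (cfg$fat_class < 0L || cfg$fat_class >= cfg$n_classes) {
    stop_validation("fat_class must be a class label in [0, n_classes - 1]")
  }
  if (cfg$min_area <= 0 || cfg$min_area > cfg$max_area) {
    stop_validation("need 0 < min_area <= max_area")
  }
  if (cfg$min_circularity < 0 || cfg$min_circularity > 1) {
    stop_validation("min_circularity must be in [0, 1]")
  }
  if (cfg$max_match_dist <= 0) stop_validation("max_match_dist must be > 0")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
config_to_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' @rdname pipeline_config
#' @param json a JSON string or path produced by `config_to_json()`.
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' @rdname pipeline_config
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(config_to_json(cfg), tmp)
  unname(tools::md5sum(tmp))
}

close_se_of <- function(cfg) structuring_element(cfg$close_se_shape, cfg$close_se_size)
erode_se_of <- function(cfg) structuring_element(cfg$erode_se_shape, cfg$erode_se_size)

#' Run the full detection pipeline
#'
#' Executes, per slice: preprocessing (bed removal, subcutaneous-fat
#' stripping), regional consistency features, consistency split, k-class
#' Otsu segmentation, fat-mask extraction and candidate detection; when
#' ground truth is given, candidates are matched to the manual nodes and
#' per-sample missed rates are aggregated. Two candidate profiles are
#' evaluated: *suspected* nodes pass the area gate only, confirmed *nodes*
#' additionally pass the circularity gate. Every stage is deterministic, so
#' two runs with the same inputs and configuration produce byte-identical
#' candidate and metric files.
#'
#' @param images character vector of slice image paths. The slice id is the
#'   file name without extension; the sample id is the parent directory name.
#' @param config a [pipeline_config()].
#' @param truth optional annotations: a path to a JSON file, a list of slice
#'   records from [read_annotations()], or a named list mapping sample ids
#'   to such lists (cohort layout).
#' @param out_dir optional output directory: per-slice label and mask PNGs,
#'   `candidates.json`, `metrics.csv` and `report.json` are written there.
#' @return a run report: list with `config`, `config_hash`, `slices` (per
#'   slice: thresholds, candidate table, timings), `evaluation` (stacked
#'   slice evaluations) and `samples` (per-sample alpha/beta) when truth was
#'   given.
#' @export
run_pipeline <- function(images, config = pipeline_config(), truth = NULL,
                         out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop_validation("`config` must come from pipeline_config()")
  }
  if (length(images) == 0L) stop_validation("no input images")
  missing <- images[!file.exists(images)]
  if (length(missing)) {
    stop_io("input image not found: %s", paste(missing, collapse = ", "))
  }
  if (is.character(truth) && length(truth) == 1L) {
    truth <- read_annotations(truth)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  slice_reports <- list()
  evals <- NULL
  all_cands <- list()
  for (path in images) {
    id <- tools::file_path_sans_ext(basename(path))
    sample <- basename(dirname(path))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      process_slice(path, config),
      error = function(e) {
        stop(errorCondition(
          sprintf("slice %s (%s): %s", id, path, conditionMessage(e)),
          class = class(e)))
      })
    elapsed <- proc.time()[["elapsed"]] - t0

    suspected <- res$candidates
    confirmed <- suspected[suspected$circularity >= config$min_circularity, ,
                           drop = FALSE]
    slice_truth <- lookup_truth(truth, sample, id)
    if (!is.null(slice_truth)) {
      ms <- match_to_ground_truth(suspected, slice_truth$nodes,
                                  config$max_match_dist)
      mc <- match_to_ground_truth(confirmed, slice_truth$nodes,
                                  config$max_match_dist)
      ev <- slice_evaluation(sample, id, ms$n_truth, ms$n_missed, mc$n_missed)
      evals <- rbind(evals, ev)
    }
    cand_out <- confirmed
    cand_out$pixels <- NULL
    cand_out$slice <- rep(id, nrow(cand_out))
    cand_out$sample <- rep(sample, nrow(cand_out))
    all_cands[[paste(sample, id, sep = "/")]] <- cand_out
    slice_reports[[id]] <- list(
      slice = id, sample = sample,
      body_threshold = res$body_threshold,
      thresholds = res$thresholds,
      consistency_threshold = res$consistency_threshold,
      n_suspected = nrow(suspected), n_confirmed = nrow(confirmed),
      seconds = elapsed)
    if (!is.null(out_dir)) {
      sdir <- file.path(out_dir, sample)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      write_gray_image(res$cleaned, file.path(sdir, paste0(id, "_cleaned.png")))
      write_mask(res$body_mask, file.path(sdir, paste0(id, "_body.png")))
      lab_png <- label_map_to_gray(res$labels, config$n_classes)
      write_gray_image(lab_png, file.path(sdir, paste0(id, "_labels.png")))
    }
  }

  report <- list(config = unclass(config), config_hash = hash,
                 slices = slice_reports)
  cands <- do.call(rbind, unname(all_cands))
  report$candidates <- cands
  if (!is.null(evals)) {
    report$evaluation <- evals
    report$samples <- evaluate_samples(evals, config$include_empty_slices)
  }
  if (!is.null(out_dir)) {
    cands_json <- cands
    jsonlite::write_json(
      list(config_hash = hash,
           candidates = if (is.null(cands_json)) list() else cands_json),
      file.path(out_dir, "candidates.json"),
      auto_unbox = TRUE, digits = 8, dataframe = "rows", pretty = TRUE)
    if (!is.null(evals)) {
      utils::write.csv(report$samples, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
      utils::write.csv(evals, file.path(out_dir, "slice_metrics.csv"),
                       row.names = FALSE)
    }
    writeLines(config_to_json(config), file.path(out_dir, "config.json"))
    jsonlite::write_json(
      list(config_hash = hash,
           slices = lapply(slice_reports, function(s) s[names(s) != "seconds"])),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = 8, pretty = TRUE)
  }
  report
}

# One slice through preprocess -> features -> split -> multi-Otsu -> detect.
process_slice <- function(path, config) {
  img <- read_gray_image(path)
  pp <- preprocess_slice(img, level = config$body_threshold,
                         close_se = close_se_of(config),
                         erode_se = erode_se_of(config),
                         band_window = config$band_window)
  feats <- region_features(pp$cleaned, roi = pp$interior,
                           window = config$feature_window,
                           normalize = config$normalize_variance)
  split <- withCallingHandlers(
    consistency_split(feats),
    rootsu_warning = function(w) invokeRestart("muffleWarning"))
  roi <- switch(config$otsu_roi,
                body = pp$interior,
                consistency = split$roi_of_interest,
                image = NULL)
  hist <- gray_histogram(pp$cleaned, roi)
  mo <- multi_otsu(hist, config$n_classes)
  labels <- apply_thresholds(pp$cleaned, mo$thresholds, roi)
  fat <- withCallingHandlers(
    fat_mask(labels, config$fat_class),
    rootsu_warning = function(w) invokeRestart("muffleWarning"))
  cands <- find_candidates(labels, fat, fat_class = config$fat_class,
                           min_area = config$min_area,
                           max_area = config$max_area,
                           min_circularity = 0,  # profiles filtered upstream
                           embed_margin = config$embed_margin)
  list(cleaned = pp$cleaned, body_mask = pp$body_mask, labels = labels,
       fat = fat, candidates = cands,
       body_threshold = pp$body_threshold,
       thresholds = mo$thresholds,
       consistency_threshold = split$threshold)
}

lookup_truth <- function(truth, sample, id) {
  if (is.null(truth)) return(NULL)
  if (!is.null(truth[[sample]]) && is.null(truth[[sample]]$nodes)) {
    truth <- truth[[sample]]   # cohort layout: per-sample record lists
  }
  truth[[id]]
}

label_map_to_gray <- function(labels, k) {
  g <- matrix(0L, nrow(labels), ncol(labels))
  for (j in 0:(k - 1L)) {
    g[labels == j] <- as.integer(round(255 * (j + 1) / k))
  }
  as_gray_image(g)
}
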