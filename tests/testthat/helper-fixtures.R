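# Shared fixtures: small phantoms and hand-crafted DICOM bytes.

small_phantom_spec <- function(size = 192L, seed = 1L, noise_sd = 0, ...) {
  phantom_spec(width = size, height = size, seed = seed, noise_sd = noise_sd, ...)
}

# Write a cohort to a temp dir and return its path.
tmp_cohort <- function(n_samples, slices, seed = 1L, size = 192L, noise_sd = 0) {
  out <- tempfile("cohort")
  generate_cohort(small_phantom_spec(size = size, noise_sd = noise_sd),
                  n_samples, slices, seed = seed, out_dir = out)
  out
}

cohort_paths <- function(dir) {
  sort(list.files(dir, pattern = "\\.png$", recursive = TRUE, full.names = TRUE))
}

cohort_truth <- function(dir) {
  tf <- sort(list.files(dir, pattern = "^truth\\.json$", recursive = TRUE,
                        full.names = TRUE))
  stats::setNames(lapply(tf, read_annotations), basename(dirname(tf)))
}

# ---- minimal DICOM writer (explicit VR little endian) ----------------------

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dcm_elem <- function(group, elem, vr, value_raw) {
  long <- vr %in% c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  len <- length(value_raw)
  if (len %% 2 == 1) { value_raw <- c(value_raw, as.raw(0)); len <- len + 1 }
  hdr <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (long) hdr <- c(hdr, as.raw(c(0, 0)), u32le(len)) else hdr <- c(hdr, u16le(len))
  c(hdr, value_raw)
}

dcm_str <- function(s) charToRaw(s)

# pixels: integer matrix (row-major in file); 16-bit signed by default
write_test_dicom <- function(path, pixels, slope = 1, intercept = 0,
                             window_center = NULL, window_width = NULL,
                             n_frames = NULL) {
  body <- raw(0)
  if (!is.null(n_frames)) {
    body <- c(body, dcm_elem(0x0028, 0x0008, "IS", dcm_str(as.character(n_frames))))
  }
  body <- c(body,
            dcm_elem(0x0028, 0x0010, "US", u16le(nrow(pixels))),
            dcm_elem(0x0028, 0x0011, "US", u16le(ncol(pixels))),
            dcm_elem(0x0028, 0x0100, "US", u16le(16)),
            dcm_elem(0x0028, 0x0103, "US", u16le(1)))
  if (!is.null(window_center)) {
    body <- c(body,
              dcm_elem(0x0028, 0x1050, "DS", dcm_str(as.character(window_center))),
              dcm_elem(0x0028, 0x1051, "DS", dcm_str(as.character(window_width))))
  }
  body <- c(body,
            dcm_elem(0x0028, 0x1052, "DS", dcm_str(as.character(intercept))),
            dcm_elem(0x0028, 0x1053, "DS", dcm_str(as.character(slope))))
  px <- writeBin(as.integer(t(pixels)), raw(), size = 2L, endian = "little")
  body <- c(body, dcm_elem(0x7FE0, 0x0010, "OW", px))
  meta <- dcm_elem(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1"))
  bytes <- c(raw(128), charToRaw("DICM"), meta, body)
  writeBin(bytes, path)
  invisible(path)
}
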