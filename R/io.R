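# File formats: B-scans as 32-bit TIFF or NPY with a JSON provenance
# sidecar; raw volumes as little-endian float32 binary + JSON sidecar;
# run configurations as YAML.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a B-scan image with its provenance sidecar
#'
#' `write_bscan()` stores the pixels as 32-bit TIFF (samples min-max
#' normalized to `[0, 1]`; the normalization is undone on read from the
#' sidecar, with 2^-32 quantization) or as NPY (IEEE float32, exact to
#' float32 precision), plus a `<path>.json` sidecar carrying scale,
#' depth pitch and provenance (compensation coefficient etc.).
#'
#' @param path Output path; the format follows the extension (`.tif`,
#'   `.tiff` or `.npy`).
#' @param bscan An `oct_bscan` (or plain matrix).
#' @return `write_bscan()` the path, invisibly; `read_bscan()` an
#'   `oct_bscan`. A missing sidecar yields linear-scale defaults with a
#'   warning.
#' @export
write_bscan <- function(path, bscan) {
  img <- if (inherits(bscan, "oct_bscan")) bscan$image else bscan
  meta <- list(
    scale = if (inherits(bscan, "oct_bscan")) bscan$scale else "linear",
    depth_pitch_um = if (inherits(bscan, "oct_bscan"))
      bscan$depth_pitch_um else NA_real_,
    provenance = if (inherits(bscan, "oct_bscan")) bscan$provenance else list(),
    dim = dim(img))
  if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    write_npy(path, img)
  } else {
    lo <- min(img); hi <- max(img)
    meta$tiff_range <- c(lo, hi)
    norm <- if (hi > lo) (img - lo) / (hi - lo) else img * 0
    tiff::writeTIFF(norm, path, bits.per.sample = 32L, compression = "none")
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  } else {
    warning("no sidecar for ", path, "; assuming linear scale",
            call. = FALSE)
    meta <- list(scale = "linear", depth_pitch_um = NA_real_,
                 provenance = list())
  }
  img <- if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    read_npy(path)
  } else {
    norm <- tiff::readTIFF(path)
    r <- meta$tiff_range %||% c(0, 1)
    norm * (r[2] - r[1]) + r[1]
  }
  new_bscan(img, scale = meta$scale %||% "linear",
            depth_pitch_um = meta$depth_pitch_um %||% NA_real_,
            provenance = as.list(meta$provenance))
}

# Minimal NPY v1.0 (little-endian float32, C order) writer/reader; the
# payload is transposed so that numpy sees the same row-major image.
write_npy <- function(path, mat) {
  header <- sprintf("{'descr': '<f4', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(mat), ncol(mat))
  pad <- (64L - ((10L + nchar(header) + 1L) %% 64L)) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))))
    stop_octadc(path, " is not an NPY file")
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  shp <- regmatches(header, regexec("shape': \\((\\d+), (\\d+)\\)", header))[[1]]
  if (length(shp) != 3L) stop_octadc("unsupported NPY header: ", header)
  nr <- as.integer(shp[2]); nc <- as.integer(shp[3])
  if (!grepl("'<f4'", header)) stop_octadc("only <f4 NPY supported")
  v <- readBin(con, "double", nr * nc, size = 4L, endian = "little")
  matrix(v, nr, nc, byrow = TRUE)
}

#' Write / read a raw volume
#'
#' Stores every frame's fringe matrix as little-endian float32 in one
#' binary file (pixel-fastest, frames in order) with a JSON sidecar
#' recording dimensions, the wavelength span, seeds and the per-location
#' ground-truth layer tables — the parameter-recovery test surface.
#'
#' @param dir Output directory (created).
#' @param volume An `oct_volume`.
#' @export
write_volume <- function(dir, volume) {
  stopifnot(inherits(volume, "oct_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  P <- nrow(volume$frames[[1]]$fringes)
  A <- ncol(volume$frames[[1]]$fringes)
  con <- file(file.path(dir, "fringes.f32"), "wb")
  for (fr in volume$frames)
    writeBin(as.vector(fr$fringes), con, size = 4L, endian = "little")
  close(con)
  src <- volume$source
  meta <- list(
    n_pixels = P, a_lines = A, n_bscans = volume$n_bscans,
    repeats = volume$repeats, seed = volume$seed,
    center_wavelength_nm = src$center_wavelength_nm,
    wavelength_span_nm = range(src$wavelengths_nm),
    frame_order = "location-major (all repeats of location 1 first)",
    truth = lapply(volume$truth, function(tr) lapply(tr, as.numeric)))
  jsonlite::write_json(meta, file.path(dir, "volume.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_volume
#' @export
read_volume <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "volume.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  P <- meta$n_pixels; A <- meta$a_lines
  span <- meta$wavelength_span_nm
  center <- meta$center_wavelength_nm
  source <- make_source_spectrum(center, (span[2] - span[1]) / 4, P)
  grid <- resample_to_k(source)
  n_frames <- meta$n_bscans * meta$repeats
  con <- file(file.path(dir, "fringes.f32"), "rb")
  frames <- vector("list", n_frames)
  fi <- 0L
  for (loc in seq_len(meta$n_bscans)) {
    for (rp in seq_len(meta$repeats)) {
      fi <- fi + 1L
      v <- readBin(con, "double", P * A, size = 4L, endian = "little")
      frames[[fi]] <- new_raw_frame(matrix(v, P, A), source, grid,
                                    repeats = meta$repeats,
                                    frame_index = fi,
                                    location_index = loc, repeat_index = rp)
    }
  }
  close(con)
  structure(list(frames = frames, source = source, grid = grid,
                 n_bscans = meta$n_bscans, repeats = meta$repeats,
                 a_lines = A,
                 truth = lapply(meta$truth, as.data.frame),
                 seed = meta$seed),
            class = "oct_volume")
}

#' Read / write a run configuration
#'
#' YAML round trip of the nested run configuration (simulator,
#' reconstruction, ground-truth, model and evaluation blocks, each carrying
#' a schema version).
#'
#' @param path YAML file.
#' @param config Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  modifyList(defaults, cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(path, config) {
  yaml::write_yaml(config, path)
  invisible(path)
}

default_run_config <- function() {
  list(
    schema_version = 1L,
    simulator = list(n_pixels = 512L, center_wavelength_nm = 840,
                     fwhm_bandwidth_nm = 50, a_lines = 128L,
                     n_volumes = 2L, locations = 4L, repeats = 4L,
                     noise_gaussian_sd = 0.05, noise_shot_scale = 0,
                     speckle_density = 8, curvature_sag_um = 20,
                     a2_jitter_sd = 2),
    reconstruction = list(c_min = -40, c_max = 40, n_channels = 5L,
                          interpolation = "spline", floor_db = -60),
    gtruth = list(bands = 5L, feather = 0L,
                  sweep = c(-40, 40, 5), pool_depth = 4L,
                  pool_lateral = 2L),
    model = list(n_channels = 5L, encoder_stages = 3L,
                 growth_per_block = 12L, base_filters = 12L,
                 final_activation = "sigmoid", loss = "mae",
                 learning_rate = 2e-3, epochs = 8L, batch_size = 4L),
    evaluation = list(ssim_scales = 3L, repeats_averaged = TRUE))
}
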