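# File formats: the HDF5 RF container, B-mode PNG export, sweep CSV,
# codec bitstream + JSON sidecar, and run configuration files.

#' Write RF frames to the HDF5 container
#'
#' Layout: one `elements x samples` dataset per firing — `/rf` for a
#' single frame, `/rf001`, `/rf002`, ... for a multi-firing schedule —
#' each carrying the attributes `sample_rate`, `sound_speed`, `element_x`,
#' `t0` and `elements` (1-based array element indices of the rows).
#' Values round-trip losslessly (double precision).
#'
#' @param frames An [rf_frame()] or list of them.
#' @param path Output file path (overwritten).
#' @return `path`, invisibly.
#' @export
write_rf <- function(frames, path) {
  single <- inherits(frames, "rf_frame")
  if (single) frames <- list(frames)
  stopifnot(all(vapply(frames, inherits, logical(1), "rf_frame")))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    name <- if (single) "rf" else sprintf("rf%03d", i)
    rhdf5::h5write(f$samples, path, name)
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, name)
    rhdf5::h5writeAttribute(f$sample_rate, did, "sample_rate")
    rhdf5::h5writeAttribute(f$sound_speed %||% NA_real_, did, "sound_speed")
    rhdf5::h5writeAttribute(f$element_x %||% NA_real_, did, "element_x")
    rhdf5::h5writeAttribute(f$t0, did, "t0")
    rhdf5::h5writeAttribute(as.integer(f$elements), did, "elements")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Read RF frames from the HDF5 container
#'
#' @param path File written by [write_rf()] (or following its documented
#'   layout). A file missing a required attribute raises a schema error
#'   naming the field.
#' @return A single [rf_frame()] if the file holds one firing, otherwise a
#'   list of frames in firing-index order.
#' @export
read_rf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  names <- sort(ls$name[ls$group == "/" & grepl("^rf", ls$name)])
  if (!length(names))
    stop("schema error: no /rf dataset in ", path, call. = FALSE)
  frames <- lapply(names, function(name) {
    samples <- rhdf5::h5read(path, name)
    at <- rhdf5::h5readAttributes(path, name)
    for (field in c("sample_rate", "t0", "elements"))
      if (is.null(at[[field]]))
        stop(sprintf("schema error: dataset '%s' lacks attribute '%s'",
                     name, field), call. = FALSE)
    ex <- at$element_x
    ex <- if (is.null(ex) || all(is.na(ex))) NULL else as.numeric(ex)
    cs <- at$sound_speed
    if (!is.null(cs) && all(is.na(cs))) cs <- NULL
    rf_frame(samples, sample_rate = as.numeric(at$sample_rate),
             t0 = as.numeric(at$t0), elements = as.integer(at$elements),
             element_x = ex, sound_speed = if (is.null(cs)) NULL
             else as.numeric(cs))
  })
  if (length(frames) == 1L) frames[[1]] else frames
}

#' Write a B-mode image as a grayscale PNG
#'
#' Maps `[-dynamic_range_db, 0]` dB linearly to intensities `[0, 255]`
#' (clipping floor black, brightest pixel white), depth running down the
#' image.
#'
#' @param bmode A `bmode_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_bmode_png <- function(bmode, path) {
  stopifnot(inherits(bmode, "bmode_image"))
  u <- bmode$values_db / bmode$dynamic_range_db + 1
  ok <- tryCatch({png::writePNG(pmin(pmax(u, 0), 1), target = path); TRUE},
                 error = function(e)
                   stop("failed writing PNG '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write sweep results as CSV
#'
#' Columns `strategy,levels,ssim`, one record per sweep point.
#'
#' @param results Data frame from [quant_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(results, path) {
  stopifnot(all(c("strategy", "levels", "ssim") %in% names(results)))
  utils::write.csv(results[, c("strategy", "levels", "ssim")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write the packed bitstreams and JSON sidecar of an encoded frame
#'
#' Stores one packed 2-bit/sample stream per channel (concatenated, in
#' element order) next to a JSON sidecar holding the grid parameters,
#' initial level, normalization offset/scale and per-channel byte
#' offsets — everything needed for exact decoding.
#'
#' @param streams List of `coded_stream`s (one per channel).
#' @param norm Normalization list from [normalize_rf()].
#' @param path Output path for the packed bits; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param metadata Named list of extra sidecar fields (e.g. sample_rate).
#' @return `path`, invisibly.
#' @export
write_stream_sidecar <- function(streams, norm, path, metadata = list()) {
  bytes_per <- vapply(streams, function(s) ceiling(2 * s$n_samples / 8),
                      numeric(1))
  payload <- do.call(c, lapply(streams, serialize_stream))
  writeBin(payload, path)
  g <- streams[[1]]$grid
  sidecar <- list(
    n_channels = length(streams),
    n_samples = vapply(streams, `[[`, numeric(1), "n_samples"),
    byte_offset = cumsum(c(0, bytes_per[-length(bytes_per)])),
    initial_level = vapply(streams, `[[`, numeric(1), "initial_level"),
    grid = list(n_levels = g$n_levels, base = g$base, y_max = g$y_max),
    offset = norm$offset, scale = norm$scale,
    bit_order = "per sample: delta bit then sign bit, MSB-first in byte",
    metadata = metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an encoded frame back from bitstream + sidecar
#'
#' @param path Path passed to [write_stream_sidecar()].
#' @return List with `streams` (list of `coded_stream`), `norm` and
#'   `metadata`.
#' @export
read_stream_sidecar <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  payload <- readBin(path, "raw", n = file.info(path)$size)
  grid <- level_grid(side$grid$n_levels, side$grid$base, side$grid$y_max)
  streams <- lapply(seq_len(side$n_channels), function(i) {
    n <- side$n_samples[i]
    off <- side$byte_offset[i]
    deserialize_stream(payload[(off + 1):(off + ceiling(2 * n / 8))],
                       n, grid, as.integer(side$initial_level[i]))
  })
  list(streams = streams,
       norm = list(offset = side$offset, scale = side$scale),
       metadata = side$metadata)
}

#' Default run configuration
#'
#' Nested parameter groups mirroring the modelled system: 32 elements at
#' 180 um / 8.2 MHz / 78 % BW; 32 MS/s sampling in 1480 m/s water with a
#' 5-cycle 132 ns transmit; the 11-level-per-polarity base-2 codec; the
#' 8 MHz / 50 % reconstruction filter with 30 dB display range and 10
#' averages; the three-wire phantom.
#'
#' @return Named nested list.
#' @export
default_run_config <- function() {
  list(
    array = list(n_elements = 32L, pitch = 180e-6,
                 center_frequency = 8.2e6, fractional_bandwidth_6db = 0.78),
    acquisition = list(sample_rate = 32e6, n_samples = 2048L,
                       sound_speed = 1480, tx_cycles = 5L,
                       tx_period = 132e-9, noise_snr_db = 40,
                       attenuation_db_mhz_cm = 0, seed = 1L),
    phantom = list(wire_depths_mm = c(34, 37, 40), n_diffuse = 150L,
                   diffuse_reflectivity = 0.03),
    codec = list(n_levels = 11L, base = 2, initial_level = "min"),
    imaging = list(filter_center = 8e6, filter_fractional_bandwidth = 0.5,
                   dynamic_range_db = 30, n_averages = 10L,
                   z_min_mm = 30, z_max_mm = 43),
    metrics = list(ssim_span_db = 60,
                   sweep_strategies = c("linear", "log", "log_delta"),
                   sweep_levels = list(linear = c(32L, 256L, 1024L),
                                       log = c(8L, 16L, 22L),
                                       log_delta = c(8L, 16L, 22L))),
    seed = 1L)
}

#' Read a run configuration from YAML or JSON
#'
#' User files may specify any subset of the groups in
#' [default_run_config()]; missing entries keep their defaults. Unknown
#' top-level groups raise an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (group in names(user)) {
    if (is.list(cfg[[group]]) && is.list(user[[group]]))
      cfg[[group]] <- utils::modifyList(cfg[[group]], user[[group]])
    else cfg[[group]] <- user[[group]]
  }
  cfg
}
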