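# B-mode reconstruction chain: Gaussian band-pass -> delay-and-sum
# beamforming -> Hilbert envelope -> logarithmic compression.

#' Reconstruction pixel grid
#'
#' @param x_coords Strictly increasing lateral pixel centres (m). Default
#'   for [default_image_grid()] is the element positions themselves.
#' @param z_coords Strictly increasing depth pixel centres (m, > 0).
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(x_coords, z_coords) {
  if (any(diff(x_coords) <= 0) || any(diff(z_coords) <= 0))
    stop("grid coordinates must be strictly increasing", call. = FALSE)
  if (any(z_coords <= 0)) stop("depths must be > 0", call. = FALSE)
  structure(list(x_coords = as.numeric(x_coords),
                 z_coords = as.numeric(z_coords)),
            class = "image_grid")
}

#' Default grid: element positions laterally, c/(2 fs) axially
#'
#' @param array A [transducer_array()].
#' @param acq An [acquisition_config()].
#' @param z_range Depth span in metres (length 2).
#' @return An [image_grid()] with axial step `sound_speed / (2 * sample_rate)`
#'   (one pixel per RF sample of round-trip travel).
#' @export
default_image_grid <- function(array, acq,
                               z_range = c(acq$sound_speed / acq$sample_rate,
                                           acq$sound_speed * (acq$n_samples - 1) /
                                             (2 * acq$sample_rate))) {
  dz <- acq$sound_speed / (2 * acq$sample_rate)
  image_grid(array$element_x, seq(z_range[1], z_range[2], by = dz))
}

# shared zero-phase frequency response helper: applies gain g(|f|) to each
# row of a matrix (time along columns)
.apply_freq_gain_rows <- function(x, sample_rate, gain_fun) {
  n <- ncol(x)
  f <- (seq_len(n) - 1) / n * sample_rate
  f_fold <- pmin(f, sample_rate - f)   # |f| on the periodic axis
  g <- gain_fun(f_fold)
  t(apply(x, 1, function(row) Re(stats::fft(stats::fft(row) * g,
                                            inverse = TRUE) / n)))
}

#' Zero-phase Gaussian band-pass filter
#'
#' Filters each channel with a frequency-domain Gaussian magnitude
#' response, unity gain at `center` and -6 dB points at
#' `center * (1 +- fractional_bandwidth / 2)`. Zero-phase (no delay), as in
#' offline B-mode processing. The default 8 MHz / 50 % matches the
#' pre-beamforming conditioning filter of the modelled system.
#'
#' @param frame An [rf_frame()].
#' @param center Centre frequency in Hz.
#' @param fractional_bandwidth Fractional -6 dB bandwidth.
#' @return A filtered [rf_frame()].
#' @export
bandpass_gaussian <- function(frame, center = 8e6,
                              fractional_bandwidth = 0.5) {
  stopifnot(inherits(frame, "rf_frame"))
  fs <- frame$sample_rate
  edge <- center * (1 + fractional_bandwidth / 2)
  if (edge >= fs / 2)
    stop("filter band exceeds the Nyquist frequency", call. = FALSE)
  sigma_f <- center * fractional_bandwidth / (2 * sqrt(2 * log(2)))
  y <- .apply_freq_gain_rows(frame$samples, fs, function(fa)
    exp(-(fa - center)^2 / (2 * sigma_f^2)))
  rf_frame(y, fs, t0 = frame$t0, elements = frame$elements,
           element_x = frame$element_x, sound_speed = frame$sound_speed)
}

#' Delay-and-sum plane-wave beamforming
#'
#' For each pixel `(x, z)` sums the element signals evaluated at the
#' normal-incidence plane-wave round-trip delay
#' `tau = (z + sqrt((x - x_e)^2 + z^2)) / c`, with linear interpolation
#' between samples, no apodization. Delays outside the recorded window
#' contribute zero. Accepts either a single full-aperture frame or a list
#' of frames with `elements` subsets (e.g. the multiplexed firing
#' schedule); together the supplied firings must cover every element.
#'
#' @param frames An [rf_frame()] or list of them.
#' @param array A [transducer_array()].
#' @param grid An [image_grid()].
#' @param sound_speed Sound speed in m/s.
#' @return Numeric matrix `length(z_coords)` x `length(x_coords)` of
#'   pre-envelope beamformed RF.
#' @export
das_beamform <- function(frames, array, grid, sound_speed) {
  if (inherits(frames, "rf_frame")) frames <- list(frames)
  stopifnot(inherits(array, "transducer_array"), inherits(grid, "image_grid"))
  covered <- sort(unique(unlist(lapply(frames, `[[`, "elements"))))
  if (!identical(covered, seq_len(array$n_elements)))
    stop("supplied firings do not cover every array element exactly",
         call. = FALSE)
  z <- grid$z_coords
  nx <- length(grid$x_coords)
  nz <- length(z)
  img <- matrix(0, nz, nx)
  for (frame in frames) {
    fs <- frame$sample_rate
    ns <- ncol(frame$samples)
    for (r in seq_len(nrow(frame$samples))) {
      xe <- array$element_x[frame$elements[r]]
      s <- frame$samples[r, ]
      for (j in seq_len(nx)) {
        tau <- (z + sqrt((grid$x_coords[j] - xe)^2 + z^2)) / sound_speed
        pos <- (tau - frame$t0) * fs + 1
        i0 <- floor(pos)
        w <- pos - i0
        ok <- i0 >= 1 & i0 < ns
        if (any(ok)) {
          v <- numeric(nz)
          v[ok] <- s[i0[ok]] * (1 - w[ok]) + s[i0[ok] + 1L] * w[ok]
          img[, j] <- img[, j] + v
        }
      }
    }
  }
  img
}

#' Envelope detection along depth
#'
#' Magnitude of the analytic signal (Hilbert transform) of each image
#' column, removing the carrier oscillation.
#'
#' @param rf_image Numeric matrix (depth x lateral) or vector.
#' @return Non-negative array of the same shape.
#' @export
envelope_detect <- function(rf_image) {
  vec_in <- is.null(dim(rf_image))
  x <- if (vec_in) matrix(rf_image, ncol = 1) else rf_image
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  env <- apply(x, 2, function(col)
    Mod(stats::fft(stats::fft(col) * h, inverse = TRUE) / n))
  if (vec_in) as.vector(env) else matrix(env, nrow = n)
}

#' Log compression to a display dynamic range
#'
#' Maps an envelope image to dB relative to its brightest pixel,
#' `20 * log10(v / max(v))`, clipped at `-dynamic_range_db`.
#'
#' @param env Non-negative envelope matrix with at least one positive pixel.
#' @param dynamic_range_db Display dynamic range in dB (default 30).
#' @param grid Optional [image_grid()] carried for plotting/peak lookup.
#' @return Object of class `bmode_image`: fields `values_db` (matrix, max
#'   0 dB, floor `-dynamic_range_db`), `dynamic_range_db`, `grid`.
#' @export
log_compress_display <- function(env, dynamic_range_db = 30, grid = NULL) {
  if (any(env < 0)) stop("envelope must be non-negative", call. = FALSE)
  peak <- max(env)
  if (peak <= 0) stop("all-zero image cannot be log compressed", call. = FALSE)
  if (dynamic_range_db <= 0)
    stop("`dynamic_range_db` must be > 0", call. = FALSE)
  vdb <- 20 * log10(pmax(env / peak, 10^(-dynamic_range_db / 20 - 16)))
  vdb <- pmax(vdb, -dynamic_range_db)
  structure(list(values_db = vdb, dynamic_range_db = dynamic_range_db,
                 grid = grid),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d px, %g dB dynamic range\n",
              nrow(x$values_db), ncol(x$values_db), x$dynamic_range_db))
  invisible(x)
}

#' Average a stack of RF frames
#'
#' Sample-wise arithmetic mean of repeated identical firings; averaging N
#' independent-noise frames improves amplitude SNR by sqrt(N) (the system
#' uses 10 averages).
#'
#' @param frames Non-empty list of [rf_frame()]s with identical shape.
#' @return An [rf_frame()].
#' @export
average_frames <- function(frames) {
  if (!length(frames)) stop("empty frame stack", call. = FALSE)
  dims <- vapply(frames, function(f) dim(f$samples), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames must share dimensions", call. = FALSE)
  acc <- Reduce(`+`, lapply(frames, `[[`, "samples")) / length(frames)
  f1 <- frames[[1]]
  rf_frame(acc, f1$sample_rate, t0 = f1$t0, elements = f1$elements,
           element_x = f1$element_x, sound_speed = f1$sound_speed)
}

#' Zero the initial samples of a frame
#'
#' Blanks the receive interval contaminated by the electrical
#' transmit-coupling burst before reconstruction.
#'
#' @param frame An [rf_frame()].
#' @param t_blank Samples with time (from firing) below this are zeroed.
#' @return A blanked [rf_frame()].
#' @export
blank_frame <- function(frame, t_blank) {
  stopifnot(inherits(frame, "rf_frame"))
  if (t_blank <= 0) return(frame)
  t_axis <- frame$t0 + (seq_len(ncol(frame$samples)) - 1) / frame$sample_rate
  x <- frame$samples
  x[, t_axis < t_blank] <- 0
  rf_frame(x, frame$sample_rate, t0 = frame$t0, elements = frame$elements,
           element_x = frame$element_x, sound_speed = frame$sound_speed)
}

#' Full RF-to-B-mode reconstruction
#'
#' Convenience pipeline: Gaussian band-pass, delay-and-sum, Hilbert
#' envelope, log compression — the standard processing chain.
#'
#' @param frames An [rf_frame()] or list of firing frames.
#' @param array A [transducer_array()].
#' @param grid An [image_grid()]; default [default_image_grid()] needs
#'   `acq`.
#' @param sound_speed Sound speed (m/s).
#' @param filter_center,filter_fractional_bandwidth Band-pass parameters;
#'   set `filter_center = NULL` to skip filtering.
#' @param dynamic_range_db Display dynamic range.
#' @param blank_interval_s Initial receive interval zeroed before
#'   processing (see [blank_frame()]); 0 disables.
#' @return A `bmode_image`.
#' @export
reconstruct_bmode <- function(frames, array, grid, sound_speed = 1480,
                              filter_center = 8e6,
                              filter_fractional_bandwidth = 0.5,
                              dynamic_range_db = 30,
                              blank_interval_s = 0) {
  if (inherits(frames, "rf_frame")) frames <- list(frames)
  if (blank_interval_s > 0)
    frames <- lapply(frames, blank_frame, t_blank = blank_interval_s)
  if (!is.null(filter_center))
    frames <- lapply(frames, bandpass_gaussian, center = filter_center,
                     fractional_bandwidth = filter_fractional_bandwidth)
  rf_img <- das_beamform(frames, array, grid, sound_speed)
  log_compress_display(envelope_detect(rf_img), dynamic_range_db, grid = grid)
}

#' Brightest well-separated local maxima of a B-mode image
#'
#' Finds pixels that are local maxima of the dB image (8-neighbourhood)
#' and returns the brightest ones subject to a minimum mutual distance,
#' for locating point/wire targets.
#'
#' @param bmode A `bmode_image` with a grid.
#' @param n Number of maxima to return.
#' @param min_separation_m Minimum Euclidean separation between reported
#'   maxima (m).
#' @return Data frame with columns `x`, `z` (m) and `db`, ordered bright
#'   to dim.
#' @export
find_bright_maxima <- function(bmode, n = 3, min_separation_m = 1.5e-3) {
  stopifnot(inherits(bmode, "bmode_image"), !is.null(bmode$grid))
  v <- bmode$values_db
  nz <- nrow(v); nx <- ncol(v)
  is_max <- matrix(TRUE, nz, nx)
  shift_ok <- function(di, dj) {
    big <- matrix(-Inf, nz + 2, nx + 2)
    big[2:(nz + 1), 2:(nx + 1)] <- v
    v >= big[(2 + di):(nz + 1 + di), (2 + dj):(nx + 1 + dj)]
  }
  for (di in -1:1) for (dj in -1:1)
    if (di || dj) is_max <- is_max & shift_ok(di, dj)
  idx <- which(is_max, arr.ind = TRUE)
  ord <- order(v[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  keep <- list()
  for (k in seq_len(nrow(idx))) {
    z <- bmode$grid$z_coords[idx[k, 1]]
    x <- bmode$grid$x_coords[idx[k, 2]]
    far <- all(vapply(keep, function(p)
      sqrt((p$x - x)^2 + (p$z - z)^2) >= min_separation_m, logical(1)))
    if (far) keep[[length(keep) + 1]] <-
        list(x = x, z = z, db = v[idx[k, 1], idx[k, 2]])
    if (length(keep) >= n) break
  }
  do.call(rbind, lapply(keep, as.data.frame))
}
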