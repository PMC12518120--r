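# Image-quality metrics and the quantization-strategy sweep harness.

#' Global-moment structural similarity index
#'
#' SSIM computed from whole-image moments with no windowing and no
#' stabilizing constants:
#' \deqn{SSIM = \frac{2\mu_x\mu_y \cdot 2\sigma_{xy}}
#'   {(\mu_x^2+\mu_y^2)(\sigma_x^2+\sigma_y^2)}}
#' A guard `eps` is added to a denominator factor only when both of its
#' terms fall below `eps`, so constant-image degeneracies return a finite
#' value without perturbing ordinary inputs. The value is invariant to
#' population-vs-sample moment normalization (both covariance terms
#' rescale identically). Inputs are expected on a shared scale, typically
#' log-compressed images mapped to [0, 1] (see [bmode_unit_image()]).
#'
#' @param x,y Numeric arrays of identical shape.
#' @param eps Degeneracy guard (default 1e-12).
#' @return Scalar similarity, 1 for identical non-constant images.
#' @export
ssim_global <- function(x, y, eps = 1e-12) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("`x` and `y` must have identical shape", call. = FALSE)
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  d1 <- mx^2 + my^2
  d2 <- vx + vy
  if (mx^2 < eps && my^2 < eps) d1 <- d1 + eps
  if (vx < eps && vy < eps) d2 <- d2 + eps
  (2 * mx * my) * (2 * cxy) / (d1 * d2)
}

#' Map a B-mode image to the unit interval over a fixed dB span
#'
#' Rescales `values_db` from `[-span_db, 0]` to `[0, 1]`, the common
#' domain on which reconstructed images are compared with SSIM.
#'
#' @param bmode A `bmode_image`.
#' @param span_db dB span mapped onto [0, 1] (default 60).
#' @return Numeric matrix in [0, 1].
#' @export
bmode_unit_image <- function(bmode, span_db = 60) {
  stopifnot(inherits(bmode, "bmode_image"))
  pmin(pmax(bmode$values_db / span_db + 1, 0), 1)
}

#' Image SNR from peak and background regions
#'
#' `max(dB in peak region) - mean(dB in background region)`, the figure
#' used to quote wire-target SNR (e.g. -6 dB peak over a -46 dB
#' background gives 40 dB).
#'
#' @param bmode A `bmode_image`.
#' @param peak_region,background_region Logical masks or index vectors
#'   into `values_db`; non-empty, and normally disjoint.
#' @return SNR in dB.
#' @export
image_snr_db <- function(bmode, peak_region, background_region) {
  stopifnot(inherits(bmode, "bmode_image"))
  v <- bmode$values_db
  pk <- v[peak_region]
  bg <- v[background_region]
  if (!length(pk) || !length(bg))
    stop("regions must be non-empty", call. = FALSE)
  max(pk) - mean(bg)
}

#' Quantization-strategy SSIM sweep
#'
#' For each (strategy, level count) pair, quantizes the raw RF frame,
#' reconstructs a B-mode image through the identical pipeline, and
#' computes the global-moment SSIM against the float-RF reconstruction.
#' Strategies:
#' \describe{
#'   \item{`linear`}{RF min-max mapped to [0, 1], uniformly quantized to
#'     `levels` values ([quantize_linear()]), mapped back.}
#'   \item{`log`}{RF normalized symmetrically around its mean, memoryless
#'     signed log quantization with `levels` total signed codes
#'     (`levels / 2` magnitudes per polarity, base 2).}
#'   \item{`log_delta`}{the full 2-bit codec: per-channel delta + sign
#'     encoding on the same signed grid, then decoding.}
#' }
#'
#' When `frames` is a list of repeated firings the chain runs exactly as
#' the modelled system does: every firing is quantized (digitized)
#' individually, the decoded firings are averaged, and the average is
#' reconstructed — the float reference is the reconstruction of the
#' averaged float firings.
#'
#' @param frames Raw [rf_frame()], or a list of repeated firings to
#'   average after quantization.
#' @param strategies Character vector from `c("linear", "log", "log_delta")`.
#' @param levels_list Integer vector of level counts; for the log
#'   strategies these are total signed codes and must be even.
#' @param array A [transducer_array()].
#' @param grid An [image_grid()].
#' @param sound_speed Sound speed (m/s).
#' @param filter_center,filter_fractional_bandwidth Band-pass settings.
#' @param ssim_span_db dB span of the unit-interval comparison images.
#' @return Data frame with columns `strategy`, `levels`, `ssim`.
#' @export
quant_sweep <- function(frames, strategies, levels_list,
                        array, grid, sound_speed = 1480,
                        filter_center = 8e6,
                        filter_fractional_bandwidth = 0.5,
                        ssim_span_db = 60) {
  if (inherits(frames, "rf_frame")) frames <- list(frames)
  stopifnot(all(vapply(frames, inherits, logical(1), "rf_frame")))
  bad <- setdiff(strategies, c("linear", "log", "log_delta"))
  if (length(bad))
    stop("unknown strategy: ", paste(bad, collapse = ", "), call. = FALSE)
  recon <- function(f)
    reconstruct_bmode(f, array, grid, sound_speed,
                      filter_center = filter_center,
                      filter_fractional_bandwidth = filter_fractional_bandwidth,
                      dynamic_range_db = ssim_span_db)
  ref <- bmode_unit_image(recon(average_frames(frames)), ssim_span_db)
  rows <- list()
  for (strategy in strategies) {
    for (levels in levels_list) {
      qf <- average_frames(lapply(frames, quantize_frame, strategy, levels))
      img <- bmode_unit_image(recon(qf), ssim_span_db)
      rows[[length(rows) + 1]] <- data.frame(
        strategy = strategy, levels = as.integer(levels),
        ssim = ssim_global(ref, img))
    }
  }
  if (!length(rows))
    return(data.frame(strategy = character(), levels = integer(),
                      ssim = numeric()))
  do.call(rbind, rows)
}

#' Apply one quantization strategy to a whole RF frame
#'
#' @param frame Raw [rf_frame()].
#' @param strategy One of `"linear"`, `"log"`, `"log_delta"`.
#' @param levels Level count (total signed codes for the log strategies).
#' @return An [rf_frame()] with quantized samples on the original scale.
#' @export
quantize_frame <- function(frame, strategy, levels) {
  stopifnot(inherits(frame, "rf_frame"))
  x <- frame$samples
  out <- switch(
    strategy,
    linear = {
      lo <- min(x); hi <- max(x)
      if (hi == lo) stop("constant frame", call. = FALSE)
      u <- (x - lo) / (hi - lo)
      quantize_linear(u, levels)$values * (hi - lo) + lo
    },
    log = {
      grid <- .signed_grid(levels)
      norm <- normalize_rf(x)
      denormalize_rf(quantize_log_memoryless(norm$x, grid), norm)
    },
    log_delta = {
      grid <- .signed_grid(levels)
      return(logdelta_roundtrip_frame(frame, grid))
    },
    stop("unknown strategy: ", strategy, call. = FALSE))
  rf_frame(out, frame$sample_rate, t0 = frame$t0, elements = frame$elements,
           element_x = frame$element_x, sound_speed = frame$sound_speed)
}

.signed_grid <- function(levels, base = 2) {
  if (levels %% 2 != 0 || levels < 4)
    stop("signed log quantization needs an even level count >= 4",
         call. = FALSE)
  level_grid(n_levels = levels / 2L, base = base, y_max = 0L)
}
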