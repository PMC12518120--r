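# 2-bit log-delta codec: 1-bit delta modulation over logarithmically
# spaced amplitude levels plus a 1-bit sign (phase) channel.
#
# The tracked state is the integer level exponent Y; the represented
# magnitude is base^Y and the decoder reconstructs D[i] = sign[i] * base^Y[i]
# (base 2 by default, so decoding is D[i] = sign[i] * 2^Y[i]).

#' Logarithmically spaced amplitude level grid
#'
#' `n_levels` magnitudes `base^y` for `y` in
#' `[y_max - n_levels + 1, y_max]`, used for one polarity; with the sign bit
#' the signed code book has `2 * n_levels` codes. The default 11 levels per
#' polarity at base 2 give 22 signed codes spanning
#' `20*log10(2^10) ~ 60.2 dB` of magnitude dynamic range.
#'
#' @param n_levels Levels per polarity (>= 2).
#' @param base Ratio between adjacent levels (> 1); base 2 matches the
#'   power-of-two decoder.
#' @param y_max Integer exponent of the largest level; `y_max = 0` puts the
#'   top of the grid at magnitude 1, matching normalized input.
#' @return An object of class `level_grid` with fields `n_levels`, `base`,
#'   `y_max`, `y_min` and `levels` (increasing magnitudes).
#' @examples
#' g <- level_grid(11, 2, 0)
#' g$levels[1]                       # 2^-10
#' 20 * log10(max(g$levels) / min(g$levels))   # ~60.2 dB
#' @export
level_grid <- function(n_levels = 11L, base = 2, y_max = 0L) {
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop("`n_levels` must be >= 2", call. = FALSE)
  if (!is.finite(base) || base <= 1)
    stop("`base` must be > 1", call. = FALSE)
  y_max <- as.integer(y_max)
  y_min <- y_max - n_levels + 1L
  structure(
    list(n_levels = n_levels, base = base, y_max = y_max, y_min = y_min,
         levels = base^(y_min:y_max)),
    class = "level_grid")
}

#' @export
print.level_grid <- function(x, ...) {
  cat(sprintf(
    "<level_grid> %d levels/polarity (%d signed codes), base %g, y in [%d, %d], %.1f dB range\n",
    x$n_levels, 2L * x$n_levels, x$base, x$y_min, x$y_max,
    20 * log10(x$base^(x$n_levels - 1L))))
  invisible(x)
}

#' Normalize a signal symmetrically around its mean
#'
#' Subtracts the mean and scales so that the largest absolute deviation
#' maps to `peak` (the top of the quantizer grid, 1 by default). The
#' returned offset and scale invert the transform exactly:
#' `x = normalized / scale + offset`.
#'
#' @param x Numeric vector or matrix (a whole RF frame may be normalized
#'   jointly, mimicking a fixed front-end gain).
#' @param peak Target peak magnitude (default 1).
#' @return List with `x` (normalized data, same shape), `offset` (the mean)
#'   and `scale` (multiplier applied after centring).
#' @export
normalize_rf <- function(x, peak = 1) {
  if (!is.numeric(x) || !length(x))
    stop("`x` must be numeric and non-empty", call. = FALSE)
  offset <- mean(x)
  m <- max(abs(x - offset))
  if (m == 0)
    stop("constant signal: nothing to encode", call. = FALSE)
  scale <- peak / m
  list(x = (x - offset) * scale, offset = offset, scale = scale)
}

#' Invert [normalize_rf()]
#' @param x Normalized data.
#' @param norm The list returned by [normalize_rf()].
#' @return Data on the original scale.
#' @export
denormalize_rf <- function(x, norm) x / norm$scale + norm$offset

#' Encode a normalized signal with the 2-bit log-delta scheme
#'
#' Per sample the encoder emits one sign bit (`1` when `x[i] >= 0`; exact
#' zero counts as positive) and one delta bit: if `|x[i]|` exceeds the
#' currently tracked level `base^Y` the level steps up (`delta = 1`),
#' otherwise it steps down (`delta = 0`). `Y` moves by exactly one step per
#' sample and is clamped to the grid; a clamped step still emits the
#' attempted direction so the decoder can replay the recursion exactly.
#' A constant input therefore toggles between the two nearest levels.
#'
#' @param x Normalized numeric vector (see [normalize_rf()]).
#' @param grid A [level_grid()].
#' @param initial_level Starting exponent `Y` before the first sample;
#'   `"min"` (default, quiet start), `"max"`, or an integer within the grid.
#' @return An object of class `coded_stream`: fields `delta_bits`,
#'   `sign_bits` (integer 0/1 vectors), `initial_level`, `grid`,
#'   `n_samples`, and `levels` (the tracked exponent per sample, kept for
#'   inspection; it is fully determined by the bits).
#' @export
logdelta_encode <- function(x, grid, initial_level = "min") {
  stopifnot(inherits(grid, "level_grid"))
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  y0 <- .resolve_initial_level(initial_level, grid)
  n <- length(x)
  delta_bits <- integer(n)
  sign_bits <- as.integer(x >= 0)
  levels <- integer(n)
  y <- y0
  ax <- abs(x)
  for (i in seq_len(n)) {
    if (ax[i] > grid$base^y) {
      delta_bits[i] <- 1L
      y <- min(y + 1L, grid$y_max)
    } else {
      delta_bits[i] <- 0L
      y <- max(y - 1L, grid$y_min)
    }
    levels[i] <- y
  }
  structure(
    list(delta_bits = delta_bits, sign_bits = sign_bits,
         initial_level = y0, grid = grid, n_samples = n, levels = levels),
    class = "coded_stream")
}

.resolve_initial_level <- function(initial_level, grid) {
  if (identical(initial_level, "min")) return(grid$y_min)
  if (identical(initial_level, "max")) return(grid$y_max)
  y0 <- as.integer(initial_level)
  if (is.na(y0) || y0 < grid$y_min || y0 > grid$y_max)
    stop(sprintf("`initial_level` must be 'min', 'max' or an integer in [%d, %d]",
                 grid$y_min, grid$y_max), call. = FALSE)
  y0
}

#' Decode a log-delta stream back to amplitudes
#'
#' Replays the encoder's level recursion from `initial_level` — step up on
#' `delta = 1`, down on `delta = 0`, clamped to the grid — and returns
#' `D[i] = sign[i] * base^Y[i]`; with the default base 2 this is the
#' power-of-two base-station decoder. If `norm` is supplied the
#' normalization is inverted as well.
#'
#' @param stream A `coded_stream` from [logdelta_encode()], or a list with
#'   fields `delta_bits`, `sign_bits`, `initial_level`, `grid`.
#' @param norm Optional list from [normalize_rf()] to map the result back
#'   to the original signal scale.
#' @return Numeric vector of length `n_samples`.
#' @export
logdelta_decode <- function(stream, norm = NULL) {
  grid <- stream$grid
  delta <- as.integer(stream$delta_bits)
  sgn <- ifelse(as.integer(stream$sign_bits) == 1L, 1, -1)
  if (length(delta) != length(sgn))
    stop("delta and sign bit sequences differ in length", call. = FALSE)
  y <- .resolve_initial_level(stream$initial_level, grid)
  levels <- integer(length(delta))
  for (i in seq_along(delta)) {
    y <- if (delta[i] == 1L) min(y + 1L, grid$y_max) else max(y - 1L, grid$y_min)
    levels[i] <- y
  }
  out <- sgn * grid$base^levels
  if (!is.null(norm)) out <- denormalize_rf(out, norm)
  out
}

#' Encode/decode every channel of an RF frame
#'
#' Convenience wrapper applying the 2-bit log-delta codec independently to
#' each element's signal, after a single frame-wide symmetric
#' normalization (one fixed full-scale for all channels, as a shared
#' front-end reference would impose).
#'
#' @param frame An [rf_frame()].
#' @param grid A [level_grid()].
#' @param initial_level See [logdelta_encode()].
#' @return An [rf_frame()] whose samples are the decoded reconstruction on
#'   the original amplitude scale.
#' @export
logdelta_roundtrip_frame <- function(frame, grid = level_grid(),
                                     initial_level = "min") {
  stopifnot(inherits(frame, "rf_frame"))
  norm <- normalize_rf(frame$samples)
  rec <- t(apply(norm$x, 1, function(ch)
    logdelta_decode(logdelta_encode(ch, grid, initial_level))))
  rf_frame(denormalize_rf(rec, norm), frame$sample_rate, t0 = frame$t0,
           elements = frame$elements, element_x = frame$element_x,
           sound_speed = frame$sound_speed)
}

#' Serialize a coded stream to packed bytes
#'
#' Bit order: per sample the delta bit then the sign bit, packed MSB-first
#' within each byte; the tail byte is zero-padded. Storage cost is exactly
#' 2 bits per sample. Grid parameters, the initial level and any
#' normalization belong in a JSON sidecar (see [write_stream_sidecar()]).
#'
#' @param stream A `coded_stream`.
#' @return Raw vector of `ceiling(2 * n_samples / 8)` bytes.
#' @export
serialize_stream <- function(stream) {
  bits <- as.integer(rbind(stream$delta_bits, stream$sign_bits))
  pad <- (-length(bits)) %% 8
  bits <- c(bits, integer(pad))
  m <- matrix(bits, nrow = 8)
  as.raw(colSums(m * 2^(7:0)))
}

#' Deserialize packed bytes back to a coded stream
#'
#' @param bytes Raw vector from [serialize_stream()].
#' @param n_samples Number of encoded samples.
#' @param grid The [level_grid()] used at encode time.
#' @param initial_level The encoder's initial level.
#' @return A `coded_stream`.
#' @export
deserialize_stream <- function(bytes, n_samples, grid,
                               initial_level = "min") {
  need <- ceiling(2 * n_samples / 8)
  if (length(bytes) < need)
    stop("byte stream shorter than 2 bits/sample requires", call. = FALSE)
  bits <- as.integer(rawToBits(bytes))
  # rawToBits is LSB-first per byte; flip to the documented MSB-first order
  bits <- as.vector(matrix(bits, nrow = 8)[8:1, ])
  bits <- bits[seq_len(2 * n_samples)]
  delta <- bits[seq(1, length(bits), by = 2)]
  sgn <- bits[seq(2, length(bits), by = 2)]
  stream <- list(delta_bits = delta, sign_bits = sgn,
                 initial_level = initial_level, grid = grid,
                 n_samples = n_samples, levels = NULL)
  class(stream) <- "coded_stream"
  stream
}

#' Uniform (linear) quantization on [0, 1]
#'
#' Rounds each sample to the nearest of `n_levels` equispaced values on
#' the unit interval; the maximum absolute error is half a step,
#' `1 / (2 * (n_levels - 1))`.
#'
#' @param x Numeric data in `[0, 1]` (vector or matrix).
#' @param n_levels Number of levels (>= 2), e.g. `2^10`.
#' @return List with `values` (quantized data, same shape as `x`) and
#'   `codes` (integer codes in `0:(n_levels - 1)`).
#' @export
quantize_linear <- function(x, n_levels) {
  if (n_levels < 2) stop("`n_levels` must be >= 2", call. = FALSE)
  if (any(x < 0 | x > 1)) stop("`x` must lie in [0, 1]", call. = FALSE)
  codes <- round(x * (n_levels - 1))
  values <- codes / (n_levels - 1)
  if (is.matrix(x)) { dim(codes) <- dim(x); dim(values) <- dim(x) }
  list(values = values, codes = codes)
}

#' Memoryless signed logarithmic quantization
#'
#' Maps each sample to `sign(x) * base^y` with `y` the grid exponent
#' nearest to `log_base(|x|)` (nearest in the log domain; a magnitude at
#' the geometric midpoint of two levels rounds to the upper level).
#' Magnitudes below the bottom of the grid map to the smallest level;
#' exact zeros keep a positive sign. Unlike the delta encoder this places
#' no slew constraint on consecutive samples — it is the idealized
#' many-comparator log ADC used for level-count sweeps.
#'
#' @param x Normalized numeric data (vector or matrix).
#' @param grid A [level_grid()].
#' @return Quantized data, same shape as `x`.
#' @export
quantize_log_memoryless <- function(x, grid) {
  stopifnot(inherits(grid, "level_grid"))
  sgn <- ifelse(x >= 0, 1, -1)
  ax <- abs(x)
  y <- floor(log(pmax(ax, .Machine$double.xmin), grid$base) + 0.5)
  y <- pmin(pmax(y, grid$y_min), grid$y_max)
  out <- sgn * grid$base^y
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Statistics of direct delta encoding over an integer code sequence
#'
#' Measures the largest jump between consecutive quantizer codes and the
#' number of bits a direct (multi-bit) delta encoder would need to
#' transmit it: `bits_required = ceiling(log2(max_jump))` (1 when the
#' sequence is constant or steps by at most 1). The reduction fraction
#' compares that with sending full codes of `log2(code_space)` bits.
#'
#' @param codes Integer code sequence in `[0, code_space)`.
#' @param code_space Size of the code alphabet, e.g. `2^10`.
#' @return List of class `delta_stats`: `max_abs_code_difference`,
#'   `bits_required`, `reduction_fraction`.
#' @examples
#' # a 60-code jump in a 1024-code space needs 6 bits: only a 40% saving
#' delta_stats(c(0L, 60L), 1024L)
#' @export
delta_stats <- function(codes, code_space) {
  if (!length(codes)) stop("empty code sequence", call. = FALSE)
  if (any(codes < 0 | codes >= code_space))
    stop("codes must lie in [0, code_space)", call. = FALSE)
  d <- if (length(codes) > 1) max(abs(diff(as.numeric(codes)))) else 0
  bits <- if (d >= 2) ceiling(log2(d)) else 1
  structure(
    list(max_abs_code_difference = d, bits_required = bits,
         reduction_fraction = 1 - bits / log2(code_space)),
    class = "delta_stats")
}

#' Data-compression ratio between two encodings
#'
#' @param bits_baseline Bits per sample of the reference encoding (e.g. 10).
#' @param bits_proposed Bits per sample of the compressed encoding (e.g. 2).
#' @return `bits_baseline / bits_proposed` (5 for 10 -> 2).
#' @export
compression_ratio <- function(bits_baseline, bits_proposed) {
  if (bits_baseline <= 0 || bits_proposed <= 0)
    stop("bit counts must be > 0", call. = FALSE)
  bits_baseline / bits_proposed
}
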