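#' Time-average spiking features over one attention window
#'
#' The attention generator consumes the extractor's features integrated over
#' one window of length `Tf` (an integer number of sampling intervals `Td`);
#' the discrete realization is the elementwise arithmetic mean of the
#' per-step feature arrays.
#'
#' @param feature_steps List of per-step feature arrays (all the same shape),
#'   one entry per sampling interval in the window.
#' @param Tf Window length, milliseconds.
#' @param Td Sampling interval, milliseconds.
#' @return The averaged feature array.
#' @export
integrate_features <- function(feature_steps, Tf = 2, Td = 1) {
  if (!is.list(feature_steps) || length(feature_steps) < 1L) {
    stop("`feature_steps` must be a non-empty list", call. = FALSE)
  }
  w <- Tf / Td
  if (abs(w - round(w)) > 1e-9 || round(w) < 1) {
    stop("`Tf` must be a positive integer multiple of `Td`", call. = FALSE)
  }
  if (length(feature_steps) != round(w)) {
    stop("window must contain exactly Tf/Td steps", call. = FALSE)
  }
  Reduce(`+`, feature_steps) / length(feature_steps)
}

#' Temperature schedule for attention-map squashing
#'
#' The sigmoid squashing of the attention map carries a temperature
#' coefficient that controls gate hardness. During training it is annealed
#' linearly from 1 to `t_max` over the first `span` epochs (then held); at
#' inference the maximum is always used, giving the hardest gates.
#'
#' @param t_max Maximum temperature (default 6).
#' @param span Annealing span in epochs.
#' @return An object of class `temperature_schedule`.
#' @export
temperature_schedule <- function(t_max = 6, span = 48L) {
  stopifnot(t_max >= 1, span >= 0)
  structure(list(t_max = t_max, span = as.integer(span)),
            class = "temperature_schedule")
}

#' Evaluate a temperature schedule
#'
#' @param epoch Zero-based epoch index.
#' @param schedule A [temperature_schedule()].
#' @param inference If `TRUE`, return the maximum regardless of epoch.
#' @return The temperature at that epoch.
#' @export
schedule_temperature <- function(epoch, schedule, inference = FALSE) {
  stopifnot(epoch >= 0)
  if (inference || schedule$span == 0L || epoch >= schedule$span) {
    return(schedule$t_max)
  }
  1 + (schedule$t_max - 1) * epoch / schedule$span
}

#' Squash a pre-normalization map into attention gates
#'
#' Standardizes the raw generator output over all elements of each map
#' (layer normalization: mean 0, unit variance, `eps = 1e-5`, no learned
#' affine terms) and passes it through a temperature-scaled sigmoid. Gates
#' therefore lie strictly in (0, 1), and the result is invariant to affine
#' rescaling of the input map.
#'
#' @param pre_map A numeric matrix (one map) with at least 2 elements.
#' @param Te Temperature coefficient.
#' @param eps Normalization stabilizer.
#' @return A matrix of gates in (0, 1) with class `attention_map`.
#' @export
squash_map <- function(pre_map, Te = 6, eps = 1e-5) {
  stopifnot(is.matrix(pre_map), length(pre_map) >= 2L)
  ln <- layernorm_fwd(matrix(as.numeric(pre_map), ncol = 1L), eps = eps)
  m <- matrix(sigmoid(Te * ln$z), nrow(pre_map), ncol(pre_map))
  attention_map(m)
}

#' Construct an attention map
#'
#' A spatial gate matrix in `[0, 1]` at input resolution. The initial map
#' (index 0) is exactly all-ones, meaning no spatial preference.
#'
#' @param values Gate matrix; all values must lie in `[0, 1]`.
#' @param index Which attention window produced the map (0 = initial).
#' @return The matrix with class `attention_map` and attribute `index`.
#' @export
attention_map <- function(values, index = NA_integer_) {
  stopifnot(is.matrix(values))
  if (any(values < 0 | values > 1)) {
    stop("attention gates must lie in [0, 1]", call. = FALSE)
  }
  structure(values, class = c("attention_map", "matrix", "array"),
            index = index)
}

#' The all-ones initial attention map
#'
#' @param h,w Spatial size.
#' @return An [attention_map()] of ones with index 0.
#' @export
initial_map <- function(h, w = h) {
  attention_map(matrix(1, h, w), index = 0L)
}

#' Gate an input frame with an attention map
#'
#' Elementwise product of the frame with the gate matrix, the single-channel
#' map being broadcast across all input channels.
#'
#' @param frame A numeric matrix (H x W) or array (H x W x C).
#' @param map An [attention_map()] (or plain matrix) of matching spatial size.
#' @return The gated frame, same shape as `frame`.
#' @export
modulate_input <- function(frame, map) {
  m <- unclass(map)
  attr(m, "index") <- NULL
  d <- dim(frame)
  if (is.matrix(frame)) {
    if (!all(d == dim(m))) stop("map/frame spatial size mismatch", call. = FALSE)
    return(frame * m)
  }
  if (length(d) == 3L) {
    if (!all(d[1:2] == dim(m))) stop("map/frame spatial size mismatch", call. = FALSE)
    return(frame * array(rep(m, d[3L]), d))
  }
  stop("`frame` must be a matrix or H x W x C array", call. = FALSE)
}

#' Map index applied at each inference step
#'
#' For static inputs a single map is generated from the first completed
#' window's features and shared by all later steps; the steps of the first
#' window use the all-ones initial map (index 0). For dynamic inputs the map
#' is regenerated every window: steps in window `n + 1` apply the map
#' produced by window `n`.
#'
#' @param k Step index in `1..K`, or a vector of steps.
#' @param mode `"static"` or `"dynamic"`.
#' @param window Window length in steps (`Tf / Td`).
#' @return Integer map index (0 = initial all-ones map) per step.
#' @export
attention_cadence <- function(k, mode = c("static", "dynamic"), window = 2L) {
  mode <- match.arg(mode)
  stopifnot(all(k >= 1), window >= 1)
  if (mode == "static") {
    as.integer(ifelse(k <= window, 0L, 1L))
  } else {
    as.integer((k - 1) %/% window)
  }
}

#' Export an attention map as an 8-bit grayscale PNG
#'
#' Pixel value = `round(255 * gate)`, for visual inspection of where the
#' model attends.
#'
#' @param map An [attention_map()] or gate matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_attention_png <- function(map, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  png::writePNG(round(255 * unclass(map)) / 255, target = path)
  invisible(path)
}

# --- internal batched attention pieces (used by the network) -------------

# Squash a batched pre-map (1, H, W, N): layernorm per sample then sigmoid.
squash_map_batch <- function(pre, Te, eps = 1e-5) {
  d <- dim(pre)
  x <- matrix(pre, d[2L] * d[3L], d[4L])
  ln <- layernorm_fwd(x, eps = eps)
  m <- sigmoid(Te * ln$z)
  map <- array(m, d)
  list(map = map, ln = ln, Te = Te)
}

squash_map_batch_bwd <- function(dmap, cache) {
  d <- dim(dmap)
  m <- sigmoid(cache$Te * cache$ln$z)
  dz <- matrix(dmap, d[2L] * d[3L], d[4L]) * cache$Te * m * (1 - m)
  dpre <- layernorm_bwd(dz, cache$ln)
  array(dpre, d)
}
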