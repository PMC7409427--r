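#' Quantize a nominal depth to the device axial grid
#'
#' The device samples every `axial_step` um beneath Bruch membrane, so a
#' requested depth is realised at the nearest multiple of the step (ties at
#' exactly half a step round upward/deeper). With the 2.6 um step this turns
#' the nominal 50, 100, ..., 550 um series into 49.4, 98.8, 150.8, 200.2,
#' 249.6, 299.0, 351.0, 400.4, 449.8, 499.2 and 551.2 um.
#'
#' @param nominal Nominal depth(s) in um, > 0 (vectorised).
#' @param axial_step Axial sampling step in um, > 0.
#' @return Actual depth(s) `k * axial_step` with `|actual - nominal| <=
#'   axial_step / 2`.
#' @export
quantize_depth <- function(nominal, axial_step = 2.6) {
  if (any(!is.finite(nominal)) || any(nominal <= 0)) {
    stop("`nominal` depths must be positive", call. = FALSE)
  }
  if (!is.finite(axial_step) || axial_step <= 0) {
    stop("`axial_step` must be positive", call. = FALSE)
  }
  k <- floor(nominal / axial_step + 0.5 + 1e-12)  # half-up ties
  round(k * axial_step, 9)
}

#' Fixed-depth series on the device grid
#'
#' @param axial_step Axial sampling step in um.
#' @param nominal Nominal depths in um (default 50 to 550 in 50 um steps).
#' @return Quantized actual depths in um.
#' @export
fixed_depths <- function(axial_step = 2.6, nominal = seq(50, 550, by = 50)) {
  quantize_depth(nominal, axial_step)
}

#' Percentile-depth series for one eye
#'
#' Depths as close as possible to 12.5, 25.0, ..., 87.5% of the eye's
#' subfoveal choroidal thickness (SCT) beneath BM, quantized to the axial
#' grid.
#'
#' @param sct Subfoveal choroidal thickness in um; must exceed
#'   `8 * axial_step` so the seven levels are distinct after quantization.
#' @param axial_step Axial sampling step in um.
#' @param fractions Fractions of SCT (default seven eighths-free levels).
#' @return Strictly increasing quantized depths in um, one per fraction.
#' @export
percentile_depths <- function(sct, axial_step = 2.6,
                              fractions = seq(0.125, 0.875, by = 0.125)) {
  if (!is.finite(sct) || sct <= 8 * axial_step) {
    stop(sprintf("`sct` (%.1f um) is too small to separate the percentile levels (needs > %.1f um)",
                 sct, 8 * axial_step), call. = FALSE)
  }
  out <- quantize_depth(fractions * sct, axial_step)
  if (any(diff(out) <= 0)) {
    stop("percentile depths are not strictly increasing after quantization",
         call. = FALSE)
  }
  out
}

#' Extract a BM-referenced single-pixel en-face slab pair
#'
#' For every (x, y) position the single voxel at
#' `bm_depth_map(x, y) + actual_depth` is taken from both volumes, i.e. the
#' slab follows the (possibly tilted) Bruch membrane surface.
#'
#' @param volume_pair A `volume_pair` (see [generate_phantom_eye()] or
#'   [read_volume_pair()]).
#' @param actual_depth Depth beneath BM in um; must be a multiple of the
#'   axial step and within the volume extent after BM flattening.
#' @param nominal_depth Optional nominal label (um or %SCT) carried along.
#' @return An object of class `image_pair`: matrices `octa_image` and
#'   `oct_image` (grey 0-255), `eye_id`, `nominal_depth`, `actual_depth`.
#' @export
extract_slab <- function(volume_pair, actual_depth, nominal_depth = NULL) {
  stopifnot(inherits(volume_pair, "volume_pair"))
  step <- volume_pair$axial_step
  kk <- actual_depth / step
  if (abs(kk - round(kk)) > 1e-6) {
    stop(sprintf("`actual_depth` (%.3f um) is not on the %.2f um axial grid",
                 actual_depth, step), call. = FALSE)
  }
  d <- dim(volume_pair$oct_volume)
  bm_steps <- round(volume_pair$bm_depth_map / step)
  max_depth <- (d[3] - 1 - max(bm_steps)) * step
  if (actual_depth < 0 || actual_depth > max_depth + 1e-9) {
    stop(sprintf("depth %.1f um is beyond the volume extent; maximum valid depth beneath BM is %.1f um",
                 actual_depth, max_depth), call. = FALSE)
  }
  j0 <- as.integer(round(kk)) + 1L
  idx <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]),
               as.vector(bm_steps) + j0)
  structure(list(
    octa_image = matrix(volume_pair$octa_volume[idx], d[1], d[2]),
    oct_image = matrix(volume_pair$oct_volume[idx], d[1], d[2]),
    eye_id = volume_pair$eye_id,
    nominal_depth = nominal_depth,
    actual_depth = actual_depth
  ), class = "image_pair")
}

#' Depth eligibility of an eye
#'
#' A slab deeper than the eye's subfoveal choroidal thickness lies below the
#' chorioscleral interface and is not choroid, so the eye drops out of the
#' per-depth tally there.
#'
#' @param sct SCT in um, or an eye record (list/data.frame row) with an
#'   `sct` field.
#' @param actual_depth Quantized depth in um.
#' @return `TRUE` iff `actual_depth <= sct`.
#' @export
eligible_at_depth <- function(sct, actual_depth) {
  if (is.list(sct) || is.data.frame(sct)) sct <- sct$sct
  actual_depth <= sct
}

#' Depth schedule for profile construction
#'
#' @param kind `"fixed"` (values are nominal depths in um) or `"percentile"`
#'   (values are fractions of SCT in (0, 1)).
#' @param values Nominal values, strictly increasing and positive; defaults
#'   to the standard series for the chosen kind.
#' @param axial_step Axial sampling step in um.
#' @return An object of class `depth_schedule`.
#' @export
depth_schedule <- function(kind = c("fixed", "percentile"), values = NULL,
                           axial_step = 2.6) {
  kind <- match.arg(kind)
  if (is.null(values)) {
    values <- if (kind == "fixed") seq(50, 550, by = 50)
              else seq(0.125, 0.875, by = 0.125)
  }
  if (any(values <= 0) || any(diff(values) <= 0)) {
    stop("schedule `values` must be positive and strictly increasing",
         call. = FALSE)
  }
  if (kind == "percentile" && any(values >= 1)) {
    stop("percentile schedule `values` must be fractions of SCT below 1",
         call. = FALSE)
  }
  structure(list(kind = kind, values = values, axial_step = axial_step),
            class = "depth_schedule")
}
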