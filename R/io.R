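# file plumbing: multi-page TIFF volumes, PNG slabs and comparison maps,
# CSV rosters/profiles, YAML sidecar metadata

.depth_tag <- function(depth_um) sprintf("%05.1f", depth_um)

.vol_to_pages <- function(vol) {
  lapply(seq_len(dim(vol)[3]), function(j) vol[, , j] / 255)
}

.pages_to_vol <- function(pages) {
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (j in seq_along(pages)) arr[, , j] <- round(pages[[j]] * 255)
  arr
}

#' Write a phantom eye to disk
#'
#' The structural and angiographic volumes go to 8-bit multi-page TIFF
#' stacks (one page per axial step), the lumen ground truth to a binary
#' multi-page TIFF, and the acquisition metadata (axial step, SCT, seed, BM
#' tilt) to a YAML sidecar.
#'
#' @param eye A list with `volume` and optionally `truth`, as returned by
#'   [generate_phantom_eye()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the sidecar.
#' @return Invisibly, the written file paths.
#' @export
write_volume_pair <- function(eye, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vp <- eye$volume
  id <- vp$eye_id
  paths <- c(
    oct = file.path(dir, paste0(id, "_oct.tif")),
    octa = file.path(dir, paste0(id, "_octa.tif")),
    meta = file.path(dir, paste0(id, "_meta.yml"))
  )
  tiff::writeTIFF(.vol_to_pages(vp$oct_volume), paths["oct"],
                  bits.per.sample = 8, compression = "none")
  tiff::writeTIFF(.vol_to_pages(vp$octa_volume), paths["octa"],
                  bits.per.sample = 8, compression = "none")
  if (!is.null(eye$truth)) {
    paths["truth"] <- file.path(dir, paste0(id, "_lumen.tif"))
    tiff::writeTIFF(.vol_to_pages(255 * (eye$truth$lumen_mask * 1)),
                    paths["truth"], bits.per.sample = 8,
                    compression = "none")
  }
  yaml::write_yaml(list(
    eye_id = id, axial_step = vp$axial_step, sct = vp$sct,
    bm_tilt_um = as.numeric(range(vp$bm_depth_map)),
    seed = seed
  ), paths["meta"])
  invisible(paths)
}

#' Read a phantom eye back from disk
#'
#' @param dir Directory written by [write_volume_pair()].
#' @param eye_id Eye identifier (file stem).
#' @return A list with `volume` (class `volume_pair`) and, when the lumen
#'   stack exists, `truth` (class `vessel_truth`).
#' @export
read_volume_pair <- function(dir, eye_id) {
  meta <- yaml::read_yaml(file.path(dir, paste0(eye_id, "_meta.yml")))
  octv <- .pages_to_vol(tiff::readTIFF(file.path(dir, paste0(eye_id, "_oct.tif")),
                                       all = TRUE))
  octa <- .pages_to_vol(tiff::readTIFF(file.path(dir, paste0(eye_id, "_octa.tif")),
                                       all = TRUE))
  nx <- dim(octv)[1]; ny <- dim(octv)[2]
  bm <- matrix(0, nx, ny)  # phantoms are stored BM-flattened
  volume <- structure(list(
    oct_volume = octv, octa_volume = octa, bm_depth_map = bm,
    axial_step = meta$axial_step, sct = meta$sct, eye_id = meta$eye_id
  ), class = "volume_pair")
  out <- list(volume = volume)
  tr_path <- file.path(dir, paste0(eye_id, "_lumen.tif"))
  if (file.exists(tr_path)) {
    lum <- .pages_to_vol(tiff::readTIFF(tr_path, all = TRUE)) > 127
    out$truth <- structure(list(lumen_mask = lum,
                                axial_step = meta$axial_step,
                                bm_depth_map = bm),
                           class = "vessel_truth")
  }
  out
}

#' Write an en-face image pair as grayscale PNGs
#'
#' Files are named `{eye_id}_{series}_{ddd.d}um_{octa|oct}.png` with a
#' zero-padded one-decimal depth for lexicographic ordering.
#'
#' @param pair An `image_pair`.
#' @param dir Output directory.
#' @param series Series tag (e.g. `"fixed"` or `"percentile"`).
#' @return Invisibly, the two file paths.
#' @export
write_image_pair <- function(pair, dir, series = "fixed") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%s_%sum", pair$eye_id, series,
                  .depth_tag(pair$actual_depth))
  p1 <- file.path(dir, paste0(stem, "_octa.png"))
  p2 <- file.path(dir, paste0(stem, "_oct.png"))
  png::writePNG(pair$octa_image / 255, p1)
  png::writePNG(pair$oct_image / 255, p2)
  invisible(c(octa = p1, oct = p2))
}

#' Render a comparison map to an RGB PNG
#'
#' Both-white pixels render white (#FFFFFF), both-black black (#000000),
#' OCTA-white/OCT-black green (#00FF00) and OCTA-black/OCT-white red
#' (#FF0000).
#'
#' @param map A [comparison_map()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_comparison_map_png <- function(map, path) {
  stopifnot(inherits(map, "comparison_map"))
  cm <- map$categories
  rgb <- array(0, dim = c(nrow(cm), ncol(cm), 3))
  rgb[, , 1] <- (cm == 1L) + (cm == 4L)  # red channel: white + red
  rgb[, , 2] <- (cm == 1L) + (cm == 3L)  # green channel: white + green
  rgb[, , 3] <- (cm == 1L)               # blue channel: white only
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write a depth profile as CSV
#'
#' Columns mirror the per-depth report: depth, eyes at that depth, eyes
#' displaying vessels (count and percent), similarity mean and SD.
#'
#' @param profile A [depth_profile()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_depth_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write / read a cohort roster CSV
#'
#' @param records Roster data.frame (one row per eye).
#' @param path CSV path.
#' @return `write_roster_csv` invisibly returns `path`; `read_roster_csv`
#'   returns the data.frame.
#' @export
write_roster_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster_csv
#' @export
read_roster_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
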