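#' Pixel-agreement similarity between two binary images
#'
#' The percentage of matched pixels (both black or both white) in the total
#' number of pixels compared.
#'
#' @param a,b `binary_image` objects or logical matrices of equal shape.
#' @return Similarity in percent, in \[0, 100\].
#' @export
similarity <- function(a, b) {
  ma <- .as_mask(a); mb <- .as_mask(b)
  if (!identical(dim(ma), dim(mb))) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(ma), collapse = "x"),
                 paste(dim(mb), collapse = "x")), call. = FALSE)
  }
  100 * mean(ma == mb)
}

#' Four-colour comparison map of two binary images
#'
#' Classifies each pixel as white in both (rendered white), black in both
#' (black), white on OCTA but black on en-face OCT (green), or black on OCTA
#' but white on en-face OCT (red).
#'
#' @param octa,oct `binary_image` objects or logical masks (TRUE = black) of
#'   equal shape; first argument is the OCTA mask.
#' @return An object of class `comparison_map`: integer matrix `categories`
#'   (1 both white, 2 both black, 3 green, 4 red), the category `counts`,
#'   and the implied `similarity`.
#' @export
comparison_map <- function(octa, oct) {
  ma <- .as_mask(octa); mb <- .as_mask(oct)
  if (!identical(dim(ma), dim(mb))) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(ma), collapse = "x"),
                 paste(dim(mb), collapse = "x")), call. = FALSE)
  }
  cat_m <- matrix(1L, nrow(ma), ncol(ma))
  cat_m[ma & mb] <- 2L
  cat_m[!ma & mb] <- 3L
  cat_m[ma & !mb] <- 4L
  counts <- tabulate(cat_m, 4L)
  names(counts) <- c("both_white", "both_black",
                     "octa_white_oct_black", "octa_black_oct_white")
  structure(list(categories = cat_m, counts = counts,
                 similarity = 100 * (counts[1] + counts[2]) / length(cat_m)),
            class = "comparison_map")
}

#' @export
print.comparison_map <- function(x, ...) {
  cat(sprintf("Comparison map %d x %d: similarity %.1f%%\n",
              nrow(x$categories), ncol(x$categories), x$similarity))
  print(x$counts)
  invisible(x)
}

# the three display checks on pre-binarized masks; cutoffs are configuration
.display_checks <- function(mask_octa, mask_oct, octa_degenerate = FALSE,
                            black_range = c(0.10, 0.90),
                            min_similarity = 70,
                            min_median_component = 20,
                            reference_pixels = 300 * 300) {
  bf <- if (octa_degenerate) 0 else mean(mask_octa)
  ok_fraction <- bf >= black_range[1] && bf <= black_range[2]
  ok_similarity <- similarity(mask_octa, mask_oct) >= min_similarity
  ok_components <- FALSE
  if (any(mask_octa)) {
    lab <- label_components_8(mask_octa)
    sizes <- tabulate(lab[lab > 0L])
    # component size experienced by a typical black pixel (area-weighted
    # median), so sparse single-pixel speckle cannot outvote the stripes
    med <- stats::median(sizes[lab[lab > 0L]])
    cutoff <- min_median_component * length(mask_octa) / reference_pixels
    ok_components <- med >= cutoff
  }
  c(black_fraction = ok_fraction, similarity = ok_similarity,
    stripe_components = ok_components)
}

#' Automated choroidal-vessel display criterion
#'
#' Operational surrogate for the graders' judgement of "appropriate
#' choroidal vessel display": the binarized OCTA image must have (i) a black
#' fraction between 10 and 90%, (ii) at least 70% pixel agreement with its
#' binarized en-face OCT counterpart, and (iii) stripe-like black structure,
#' measured as an area-weighted median black component size (8-connectivity)
#' of at least 20 px at the 300 x 300 reference scale. All cutoffs are
#' configurable.
#'
#' @param pair An `image_pair` from [extract_slab()].
#' @param black_range Admissible range of the OCTA black-pixel fraction.
#' @param min_similarity Minimum OCTA vs en-face OCT similarity in percent.
#' @param min_median_component Minimum area-weighted median black component
#'   size in pixels at `reference_pixels` image size.
#' @param reference_pixels Image size at which `min_median_component` is
#'   stated; the cutoff scales proportionally.
#' @return Logical flag with attribute `checks` (the three sub-criteria).
#' @export
displays_vessels <- function(pair, black_range = c(0.10, 0.90),
                             min_similarity = 70,
                             min_median_component = 20,
                             reference_pixels = 300 * 300) {
  stopifnot(inherits(pair, "image_pair"))
  ba <- suppressWarnings(binarize(pair$octa_image))
  bb <- suppressWarnings(binarize(pair$oct_image))
  checks <- .display_checks(ba$mask, bb$mask, ba$degenerate,
                            black_range, min_similarity,
                            min_median_component, reference_pixels)
  structure(all(checks), checks = checks)
}

#' Per-depth display and similarity profile of a cohort
#'
#' For every depth of a schedule, tallies the eligible eyes (quantized depth
#' not deeper than the eye's SCT), the number whose OCTA slab displays
#' vessels under [displays_vessels()], and the mean and sample SD of the
#' OCTA vs en-face OCT similarity.
#'
#' @param eyes List of eyes; each element is a list with components `volume`
#'   (a `volume_pair`) and `record` (a list or data.frame row with at least
#'   `sct`).
#' @param schedule A [depth_schedule()].
#' @param ... Cutoff overrides passed to [displays_vessels()].
#' @return A data.frame of class `depth_profile` with columns `depth_label`
#'   (actual um for the fixed series, %SCT for the percentile series),
#'   `n_eyes`, `n_displaying`, `pct_displaying`, `similarity_mean`,
#'   `similarity_sd` (NA when fewer than two eligible eyes).
#' @export
depth_profile <- function(eyes, schedule, ...) {
  stopifnot(inherits(schedule, "depth_schedule"))
  rows <- lapply(seq_along(schedule$values), function(v) {
    val <- schedule$values[v]
    sims <- numeric(0)
    disp <- logical(0)
    for (eye in eyes) {
      ad <- if (schedule$kind == "fixed") {
        quantize_depth(val, schedule$axial_step)
      } else {
        quantize_depth(val * eye$record$sct, schedule$axial_step)
      }
      if (!eligible_at_depth(eye$record, ad)) next
      pair <- extract_slab(eye$volume, ad, nominal_depth = val)
      ba <- suppressWarnings(binarize(pair$octa_image))
      bb <- suppressWarnings(binarize(pair$oct_image))
      sims <- c(sims, similarity(ba, bb))
      disp <- c(disp, all(.display_checks(ba$mask, bb$mask,
                                          ba$degenerate, ...)))
    }
    label <- if (schedule$kind == "fixed") {
      quantize_depth(val, schedule$axial_step)
    } else {
      100 * val
    }
    data.frame(
      depth_label = label,
      n_eyes = length(sims),
      n_displaying = sum(disp),
      pct_displaying = if (length(sims)) 100 * mean(disp) else NA_real_,
      similarity_mean = if (length(sims)) mean(sims) else NA_real_,
      similarity_sd = if (length(sims) > 1) stats::sd(sims) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "kind") <- schedule$kind
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' @export
print.depth_profile <- function(x, ...) {
  kind <- attr(x, "kind")
  cat(sprintf("Depth profile (%s series)\n",
              if (is.null(kind)) "?" else kind))
  unit <- if (identical(kind, "percentile")) "%SCT" else "um"
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %7.1f %s  n=%3d  displaying %3d (%5.1f%%)  similarity %s\n",
                x$depth_label[i], unit, x$n_eyes[i], x$n_displaying[i],
                x$pct_displaying[i],
                if (is.na(x$similarity_mean[i])) "--"
                else if (is.na(x$similarity_sd[i]))
                  sprintf("%.1f", x$similarity_mean[i])
                else sprintf("%.1f +/- %.1f", x$similarity_mean[i],
                             x$similarity_sd[i])))
  }
  invisible(x)
}

#' @export
plot.depth_profile <- function(x, ...) {
  kind <- attr(x, "kind")
  unit <- if (identical(kind, "percentile")) "%SCT" else "um beneath BM"
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$depth_label, x$pct_displaying, type = "b", pch = 19,
                 xlab = paste("Depth,", unit),
                 ylab = "Eyes displaying vessels, %", ylim = c(0, 100), ...)
  graphics::plot(x$depth_label, x$similarity_mean, type = "b", pch = 19,
                 xlab = paste("Depth,", unit),
                 ylab = "OCTA vs en-face OCT similarity, %", ...)
  invisible(x)
}

#' Select the optimal depth from a profile
#'
#' Maximizes, lexicographically, the fraction of eyes displaying vessels,
#' then the mean similarity, then prefers the shallower depth.
#'
#' @param profile A [depth_profile()].
#' @return The winning `depth_label`, or `NA` (with a warning) when no depth
#'   displays vessels in any eye.
#' @export
select_optimal_depth <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"), nrow(profile) > 0)
  p <- profile[profile$n_eyes > 0, , drop = FALSE]
  if (nrow(p) == 0 || all(p$n_displaying == 0)) {
    warning("no depth displays choroidal vessels in any eye", call. = FALSE)
    return(NA_real_)
  }
  rate <- p$n_displaying / p$n_eyes
  ord <- order(-rate, -p$similarity_mean, p$depth_label)
  p$depth_label[ord[1]]
}
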