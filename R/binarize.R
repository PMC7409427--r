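# map an arbitrary-range image onto integer 8-bit levels; images already in
# [0, 255] are only rounded
.rescale_to_8bit <- function(image) {
  if (length(image) == 0) stop("`image` is empty", call. = FALSE)
  if (anyNA(image)) stop("`image` contains missing values", call. = FALSE)
  x <- image
  if (min(x) < 0 || max(x) > 255) {
    rng <- range(x)
    x <- if (diff(rng) == 0) x * 0
         else (x - rng[1]) / diff(rng) * 255
  }
  round(x)
}

#' Otsu's optimum threshold from the 256-bin histogram
#'
#' Finds the grey level that minimizes the weighted intra-class intensity
#' variance (equivalently maximizes between-class variance) over the 256-bin
#' histogram of an 8-bit image. Among tied thresholds the smallest is
#' returned; on images with an empty grey-level gap between modes the
#' between-class variance is constant across the gap, so the threshold sits
#' at the gap's lower edge. Images whose range exceeds 0-255 are first
#' rescaled linearly onto it; values are binned at integer levels.
#'
#' @param image Non-empty numeric matrix of grey values.
#' @return Integer threshold in 0-255 with attribute `degenerate` (`TRUE`,
#'   with a warning, when the image is constant: all pixels then fall into
#'   one class and the constant level itself is returned).
#' @export
otsu_threshold <- function(image) {
  x <- as.numeric(.rescale_to_8bit(image))
  h <- as.numeric(tabulate(x + 1L, nbins = 256L))
  n <- as.numeric(length(x))
  if (sum(h > 0) == 1L) {
    t <- which(h > 0) - 1L
    warning("degenerate image: all pixels share one grey level", call. = FALSE)
    return(structure(as.integer(t), degenerate = TRUE))
  }
  lev <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mt <- m0[256]
  w1 <- n - w0
  # between-class variance; 0 where a class is empty
  sb <- ifelse(w0 > 0 & w1 > 0, (mt * w0 - n * m0)^2 / (w0 * w1), 0)
  structure(as.integer(which.max(sb) - 1L), degenerate = FALSE)
}

#' Binarize a grayscale image with Otsu's method
#'
#' Pixels at or below the Otsu threshold become black (vessel lumen), pixels
#' above it white (choroidal stroma). Degenerate (constant) images yield an
#' all-white mask by convention, with a warning.
#'
#' @param image Numeric matrix of grey values 0-255.
#' @return An object of class `binary_image`: `mask` (logical matrix, `TRUE`
#'   = black/lumen), `threshold`, `source_shape`, `degenerate`.
#' @export
binarize <- function(image) {
  scaled <- .rescale_to_8bit(image)
  t <- otsu_threshold(image)
  degen <- isTRUE(attr(t, "degenerate"))
  mask <- if (degen) {
    matrix(FALSE, nrow(image), ncol(image))
  } else {
    scaled <= as.numeric(t)
  }
  structure(list(mask = mask, threshold = as.integer(t),
                 source_shape = dim(image), degenerate = degen),
            class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("Binary image %d x %d: threshold %d, %.1f%% black%s\n",
              x$source_shape[1], x$source_shape[2], x$threshold,
              100 * mean(x$mask), if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# coerce binary_image / logical matrix to a logical mask
.as_mask <- function(x) {
  if (inherits(x, "binary_image")) return(x$mask)
  if (is.logical(x) && is.matrix(x)) return(x)
  stop("expected a `binary_image` or a logical matrix", call. = FALSE)
}
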