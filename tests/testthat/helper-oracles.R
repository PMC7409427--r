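# Independent Otsu oracle: exhaustive minimization of the weighted
# intra-class variance over all 256 candidate levels, computed directly from
# the pixel values (population variances), never from cumulative-histogram
# identities. Smallest threshold wins ties.
oracle_otsu <- function(image) {
  x <- round(as.numeric(image))
  n <- length(x)
  pop_var <- function(v) if (length(v) < 2) 0 else mean((v - mean(v))^2)
  best <- Inf
  best_t <- NA_integer_
  for (t in 0:255) {
    lo <- x[x <= t]
    hi <- x[x > t]
    wv <- (length(lo) * pop_var(lo) + length(hi) * pop_var(hi)) / n
    if (wv < best - 1e-9) {
      best <- wv
      best_t <- t
    }
  }
  best_t
}

# small fast phantom configuration for unit tests: 10 um pixels over a
# reduced field of view
small_config <- function(..., grid_nx = 96L, grid_ny = 96L, sct = 260,
                         lumen_fraction_by_depth = c("98.8" = 0.55),
                         seed = 1) {
  phantom_config(grid_nx = grid_nx, grid_ny = grid_ny, pixel_pitch = 10,
                 sct = sct, lumen_fraction_by_depth = lumen_fraction_by_depth,
                 seed = seed, ...)
}

# roster builder for QC tests
make_roster <- function(n, ...) {
  df <- data.frame(
    eye_id = sprintf("E%03d", seq_len(n)),
    image_score = rep(80, n),
    flag_banding = FALSE, flag_blink = FALSE, flag_vessel_doubling = FALSE,
    flag_stretching = FALSE, flag_out_of_window = FALSE,
    flag_crisscross = FALSE,
    wide_motion_artefact_count = 0,
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) df[[nm]] <- mods[[nm]]
  df
}

# raw data with exactly the requested mean and sample SD
data_with_summary <- function(n, mean, sd) {
  x <- seq_len(n)
  as.numeric(scale(x)) * sd + mean
}
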