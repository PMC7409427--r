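#' Configuration for a synthetic choroid phantom eye
#'
#' Describes one synthetic eye: the en-face grid, the axial sampling step of
#' the device, subfoveal choroidal thickness (SCT), the vessel population
#' (straight dark-lumen tubes whose calibre grows from the Sattler-like
#' shallow range to the Haller-like deep range), the granular
#' choriocapillaris band seen on OCTA, depth attenuation of signal toward a
#' noise floor, and additive Gaussian image noise.
#'
#' Depths are in micrometres beneath Bruch membrane (BM), positive downward,
#' 0 = BM itself. `lumen_fraction_by_depth` is a named numeric vector mapping
#' depth (in um, as the names) to the target fraction of lumen pixels in the
#' single-pixel slab at that depth; between / beyond keyed depths the target
#' is linearly interpolated / extended as constant. No vessels are placed
#' inside the choriocapillaris band or below the chorioscleral interface
#' (depth > `sct`).
#'
#' @param grid_nx,grid_ny En-face grid size in pixels (device images are
#'   300 x 300 over a 3.0 x 3.0 mm field).
#' @param axial_step Axial sampling step of the device in um (2.6).
#' @param sct Subfoveal choroidal thickness in um; voxels deeper than `sct`
#'   carry noise-floor signal only.
#' @param pixel_pitch En-face pixel size in um; defaults to a 3 mm field of
#'   view divided by `grid_nx`.
#' @param choriocap_thickness Thickness (um) of the fully granular
#'   choriocapillaris band at the top of the OCTA volume.
#' @param granular_decay_length Decay length (um) of residual granular
#'   corruption of OCTA voxels below the choriocapillaris band; models
#'   projection of the band into shallow slabs.
#' @param vessel_diameter_range_shallow,vessel_diameter_range_deep Vessel
#'   diameter ranges (um) at the top and bottom of the vascular choroid;
#'   interpolated linearly in depth.
#' @param lumen_fraction_by_depth Named numeric vector, names = depth in um,
#'   values = target lumen fraction in \[0, 1\].
#' @param attenuation_length Depth constant L (um): signal contrast above the
#'   noise floor is multiplied by exp(-depth / L).
#' @param noise_sd SD of additive Gaussian noise in 8-bit grey levels.
#' @param noise_floor Deep-signal floor in grey levels.
#' @param stroma_level,lumen_level Unattenuated grey levels of stroma
#'   (bright) and vessel lumen (dark).
#' @param depth_margin Extra imaged depth (um) below `sct` retained in the
#'   volume so that slabs beyond the chorioscleral interface exist.
#' @param bm_tilt_steps Integer; if > 0, the BM surface is tilted across the
#'   x direction by this many axial steps and `bm_depth_map` records the
#'   per-column offset (exercises BM flattening in slab extraction).
#' @param seed Integer seed; generation is deterministic given the seed.
#'
#' @return An object of class `phantom_config` (a validated list).
#' @seealso [generate_phantom_eye()], [generate_cohort()]
#' @export
phantom_config <- function(grid_nx = 300L, grid_ny = 300L,
                           axial_step = 2.6,
                           sct = 333,
                           pixel_pitch = 3000 / grid_nx,
                           choriocap_thickness = 10,
                           granular_decay_length = 20,
                           vessel_diameter_range_shallow = c(30, 80),
                           vessel_diameter_range_deep = c(80, 200),
                           lumen_fraction_by_depth = c("98.8" = 0.55),
                           attenuation_length = 100,
                           noise_sd = 10,
                           noise_floor = 15,
                           stroma_level = 180,
                           lumen_level = 30,
                           depth_margin = 40,
                           bm_tilt_steps = 0L,
                           seed = NULL) {
  if (!is.numeric(grid_nx) || grid_nx < 16) {
    stop("`grid_nx` must be at least 16 pixels", call. = FALSE)
  }
  if (!is.numeric(grid_ny) || grid_ny < 16) {
    stop("`grid_ny` must be at least 16 pixels", call. = FALSE)
  }
  if (!is.numeric(axial_step) || axial_step <= 0) {
    stop("`axial_step` must be a positive depth step in um", call. = FALSE)
  }
  if (!is.numeric(sct) || sct <= 0) {
    stop("`sct` must be a positive thickness in um", call. = FALSE)
  }
  fr <- lumen_fraction_by_depth
  if (length(fr)) {
    if (is.null(names(fr)) || anyNA(suppressWarnings(as.numeric(names(fr))))) {
      stop("`lumen_fraction_by_depth` must be named by depth in um",
           call. = FALSE)
    }
    if (any(fr < 0) || any(fr > 1)) {
      stop("`lumen_fraction_by_depth` values must lie in [0, 1]",
           call. = FALSE)
    }
  }
  for (nm in c("vessel_diameter_range_shallow", "vessel_diameter_range_deep")) {
    rg <- get(nm)
    if (length(rg) != 2 || any(rg <= 0) || rg[2] < rg[1]) {
      stop(sprintf("`%s` must be an increasing pair of positive diameters", nm),
           call. = FALSE)
    }
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (attenuation_length <= 0) {
    stop("`attenuation_length` must be positive", call. = FALSE)
  }
  structure(list(
    grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
    axial_step = axial_step, sct = sct, pixel_pitch = pixel_pitch,
    choriocap_thickness = choriocap_thickness,
    granular_decay_length = granular_decay_length,
    vessel_diameter_range_shallow = vessel_diameter_range_shallow,
    vessel_diameter_range_deep = vessel_diameter_range_deep,
    lumen_fraction_by_depth = fr,
    attenuation_length = attenuation_length,
    noise_sd = noise_sd, noise_floor = noise_floor,
    stroma_level = stroma_level, lumen_level = lumen_level,
    depth_margin = depth_margin,
    bm_tilt_steps = as.integer(bm_tilt_steps),
    seed = seed
  ), class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("Synthetic choroid phantom configuration\n")
  cat(sprintf("  grid %d x %d px (%.1f um/px), axial step %.2f um\n",
              x$grid_nx, x$grid_ny, x$pixel_pitch, x$axial_step))
  cat(sprintf("  SCT %.0f um; choriocapillaris band %.0f um; attenuation length %.0f um\n",
              x$sct, x$choriocap_thickness, x$attenuation_length))
  if (length(x$lumen_fraction_by_depth)) {
    cat("  target lumen fraction:",
        paste(sprintf("%s um -> %.2f", names(x$lumen_fraction_by_depth),
                      x$lumen_fraction_by_depth), collapse = ", "), "\n")
  }
  cat(sprintf("  noise sd %.1f, floor %.0f; seed %s\n", x$noise_sd,
              x$noise_floor, if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# target lumen fraction as a function of depth (um); zero inside the
# choriocapillaris band and beyond the chorioscleral interface
.target_fraction_fun <- function(config) {
  fr <- config$lumen_fraction_by_depth
  if (!length(fr)) return(function(z) rep(0, length(z)))
  keys <- as.numeric(names(fr))
  vals <- unname(fr)
  core <- if (length(keys) == 1L) {
    function(z) rep(vals, length(z))
  } else {
    ord <- order(keys)
    stats::approxfun(keys[ord], vals[ord], rule = 2)
  }
  function(z) {
    out <- core(z)
    out[z <= config$choriocap_thickness | z > config$sct] <- 0
    out
  }
}

# Straight-tube lumen mask construction.
#
# Phase 1 lays tube "layers" from the choriocapillaris downward, each layer
# filled with randomly oriented tubes until slightly *below* the local target
# fraction. Phase 2 tops up each keyed depth exactly, shrinking the final
# tube radii so the realized fraction lands in [target, target + ~0.01].
.build_lumen_mask <- function(config, depths) {
  nx <- config$grid_nx; ny <- config$grid_ny
  P <- config$pixel_pitch
  cc <- config$choriocap_thickness
  sct <- config$sct
  nz <- length(depths)
  mask <- array(FALSE, dim = c(nx, ny, nz))
  tf <- .target_fraction_fun(config)
  if (!length(config$lumen_fraction_by_depth) ||
      all(config$lumen_fraction_by_depth == 0)) {
    return(mask)
  }

  xs <- (seq_len(nx) - 0.5) * P
  ys <- (seq_len(ny) - 0.5) * P
  Xm <- matrix(xs, nx, ny)
  Ym <- matrix(ys, nx, ny, byrow = TRUE)

  lerp <- function(a, b, t) a + (b - a) * pmin(pmax(t, 0), 1)
  diam_range <- function(z) {
    t <- if (sct > cc) (z - cc) / (sct - cc) else 0
    c(lerp(config$vessel_diameter_range_shallow[1],
           config$vessel_diameter_range_deep[1], t),
      lerp(config$vessel_diameter_range_shallow[2],
           config$vessel_diameter_range_deep[2], t))
  }

  # candidate tube axis, Poisson-disk flavoured: re-draw if the axis point
  # already lies in lumen at the reference slab (spreads tubes out)
  draw_axis <- function(j_ref) {
    for (try in 1:6) {
      th <- stats::runif(1, 0, pi)
      px <- stats::runif(1, 0, nx * P)
      py <- stats::runif(1, 0, ny * P)
      ix <- pmin(pmax(ceiling(px / P), 1L), nx)
      iy <- pmin(pmax(ceiling(py / P), 1L), ny)
      if (!mask[ix, iy, j_ref]) break
    }
    abs((Xm - px) * sin(th) - (Ym - py) * cos(th))
  }

  commit_tube <- function(D, z0, r) {
    js <- which(abs(depths - z0) < r & depths <= sct & depths > cc)
    for (j in js) {
      hw <- sqrt(r^2 - (depths[j] - z0)^2)
      mask[, , j] <<- mask[, , j] | (D <= hw)
    }
  }

  # ---- phase 1: layered fill, deliberately undershooting ----
  z <- cc
  repeat {
    rg <- diam_range(z)
    r_rep <- mean(rg) / 2
    z0 <- z + r_rep
    if (z0 >= sct) break
    j0 <- which.min(abs(depths - z0))
    tgt <- max(tf(z0) - 0.08, 0)
    guard <- 0L
    while (mean(mask[, , j0]) < tgt && guard < 400L) {
      r <- stats::runif(1, rg[1], rg[2]) / 2
      # tube top sits at the layer top so nothing pokes into the band above
      commit_tube(draw_axis(j0), z + r, r)
      guard <- guard + 1L
    }
    z <- z0 + 0.9 * r_rep
  }

  # ---- phase 2: exact top-up at keyed depths ----
  keys <- as.numeric(names(config$lumen_fraction_by_depth))
  vals <- unname(config$lumen_fraction_by_depth)
  for (k in seq_along(keys)) {
    dk <- keys[k]
    if (dk <= cc || dk > sct) next
    j <- which.min(abs(depths - dk))
    tgt <- vals[k]
    guard <- 0L
    while (mean(mask[, , j]) < tgt && guard < 3000L) {
      D <- draw_axis(j)
      r <- 12.5
      dz <- depths[j] - dk
      repeat {
        hw <- if (r^2 > dz^2) sqrt(r^2 - dz^2) else 0
        f_after <- mean(mask[, , j] | (D <= hw))
        if (f_after <= tgt + 0.01 || r <= 0.7 * P) break
        r <- r - P / 2
      }
      commit_tube(D, dk, r)
      guard <- guard + 1L
    }
  }
  mask
}

#' Generate one synthetic phantom eye
#'
#' Builds a co-registered structural OCT / OCTA volume pair beneath Bruch
#' membrane together with the boolean vessel-lumen ground truth. Vessel
#' lumens are dark in both modalities; the top of the OCTA volume carries a
#' bright granular choriocapillaris band; contrast above the noise floor
#' decays as `exp(-depth / attenuation_length)`; voxels deeper than the SCT
#' carry noise-floor signal only. Generation is deterministic given
#' `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param eye_id Identifier stored on the volume pair.
#'
#' @return A list with components `volume` (class `volume_pair`: arrays
#'   `oct_volume` and `octa_volume` of dim (nx, ny, n_depths) in 0-255,
#'   `bm_depth_map` in um, `axial_step`, `sct`, `eye_id`) and `truth` (class
#'   `vessel_truth`: `lumen_mask` boolean array aligned to the volumes).
#' @export
generate_phantom_eye <- function(config, eye_id = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  nx <- config$grid_nx; ny <- config$grid_ny
  step <- config$axial_step
  n_flat <- floor((config$sct + config$depth_margin) / step) + 1L
  depths <- (seq_len(n_flat) - 1) * step

  mask <- .build_lumen_mask(config, depths)

  flo <- config$noise_floor
  octv <- array(0, dim = c(nx, ny, n_flat))
  octa <- array(0, dim = c(nx, ny, n_flat))
  for (j in seq_len(n_flat)) {
    d <- depths[j]
    if (d > config$sct) {
      so <- matrix(flo, nx, ny)
      sq <- so
    } else {
      a <- exp(-d / config$attenuation_length)
      base <- matrix(config$stroma_level, nx, ny)
      base[mask[, , j]] <- config$lumen_level
      so <- flo + (base - flo) * a
      gp <- if (d <= config$choriocap_thickness) 1 else
        exp(-(d - config$choriocap_thickness) / config$granular_decay_length)
      if (gp > 1e-3) {
        repl <- matrix(stats::runif(nx * ny) < gp, nx, ny)
        gval <- matrix(ifelse(stats::runif(nx * ny) < 0.5, 200, 60), nx, ny)
        baseq <- base
        baseq[repl] <- gval[repl]
        sq <- flo + (baseq - flo) * a
      } else {
        sq <- so
      }
    }
    if (config$noise_sd > 0) {
      so <- so + matrix(stats::rnorm(nx * ny, 0, config$noise_sd), nx, ny)
      sq <- sq + matrix(stats::rnorm(nx * ny, 0, config$noise_sd), nx, ny)
    }
    octv[, , j] <- round(pmin(pmax(so, 0), 255))
    octa[, , j] <- round(pmin(pmax(sq, 0), 255))
  }

  bm_steps <- matrix(0L, nx, ny)
  if (config$bm_tilt_steps > 0L) {
    tilt <- as.integer(round(seq(0, config$bm_tilt_steps, length.out = nx)))
    bm_steps <- matrix(tilt, nx, ny)
    n_tot <- n_flat + max(tilt)
    shift_down <- function(vol, fill_noise) {
      out <- array(0, dim = c(nx, ny, n_tot))
      for (x in seq_len(nx)) {
        pad <- tilt[x]
        if (pad > 0) {
          padv <- matrix(flo, ny, pad)
          if (config$noise_sd > 0) {
            padv <- padv + matrix(stats::rnorm(ny * pad, 0, config$noise_sd),
                                  ny, pad)
          }
          out[x, , seq_len(pad)] <- round(pmin(pmax(padv, 0), 255))
        }
        out[x, , pad + seq_len(n_flat)] <- vol[x, , ]
        if (pad < max(tilt)) {
          tailn <- max(tilt) - pad
          tailv <- matrix(flo, ny, tailn)
          if (config$noise_sd > 0) {
            tailv <- tailv + matrix(stats::rnorm(ny * tailn, 0,
                                                 config$noise_sd), ny, tailn)
          }
          out[x, , pad + n_flat + seq_len(tailn)] <-
            round(pmin(pmax(tailv, 0), 255))
        }
      }
      out
    }
    octv <- shift_down(octv)
    octa <- shift_down(octa)
    mask2 <- array(FALSE, dim = c(nx, ny, n_tot))
    for (x in seq_len(nx)) {
      mask2[x, , tilt[x] + seq_len(n_flat)] <- mask[x, , ]
    }
    mask <- mask2
  }

  volume <- structure(list(
    oct_volume = octv, octa_volume = octa,
    bm_depth_map = bm_steps * step,
    axial_step = step, sct = config$sct, eye_id = eye_id
  ), class = "volume_pair")
  truth <- structure(list(
    lumen_mask = mask, axial_step = step, bm_depth_map = bm_steps * step
  ), class = "vessel_truth")
  list(volume = volume, truth = truth)
}

#' @export
print.volume_pair <- function(x, ...) {
  d <- dim(x$oct_volume)
  cat(sprintf("OCT/OCTA volume pair '%s': %d x %d px, %d axial samples (%.1f um step, %.1f um extent)\n",
              x$eye_id, d[1], d[2], d[3], x$axial_step,
              (d[3] - 1) * x$axial_step))
  cat(sprintf("  SCT %.0f um; BM tilt range %.1f um\n", x$sct,
              diff(range(x$bm_depth_map))))
  invisible(x)
}

#' Ground-truth lumen fraction of a phantom slab
#'
#' @param truth A `vessel_truth` object from [generate_phantom_eye()].
#' @param depth Depth beneath BM in um (snapped to the nearest axial sample,
#'   BM-referenced, i.e. after undoing any BM tilt).
#' @return The fraction of lumen pixels in the slab at `depth`.
#' @export
lumen_fraction <- function(truth, depth) {
  stopifnot(inherits(truth, "vessel_truth"))
  steps <- truth$bm_depth_map / truth$axial_step
  j0 <- round(depth / truth$axial_step) + 1L
  nx <- dim(truth$lumen_mask)[1]; ny <- dim(truth$lumen_mask)[2]
  idx <- cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx),
               as.vector(steps) + j0)
  mean(truth$lumen_mask[idx])
}

# truncated-normal draws by rejection
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lo && v < hi) break
    }
    out[i] <- v
  }
  out
}

#' Generate a synthetic cohort of phantom eyes
#'
#' Draws per-eye metadata with the cohort structure the downstream analysis
#' assumes: healthy SCT ~ Normal(333, 94) truncated above 150 um, CSC SCT ~
#' Normal(547, 118) truncated above 200 um; the target lumen fraction of the
#' 100 um (quantized 98.8 um) slab is
#' `baseline + slope * (SCT - 333) / 100 + effect * [CSC] + noise`, expressed
#' in CVD percentage points and clamped to [5, 95]. A configurable fraction
#' of eyes receives an artefact flag, a low image score, or >= 2 wide motion
#' artefacts so that quality-control filtering can be exercised.
#'
#' @param n_healthy,n_csc Numbers of healthy and CSC eyes (counts >= 0,
#'   `n_healthy + n_csc >= 1`).
#' @param effect CVD offset (percentage points) added to CSC eyes at equal
#'   SCT.
#' @param slope CVD points per 100 um of SCT.
#' @param seed Integer seed; the cohort (and each eye's phantom seed) is
#'   deterministic given it.
#' @param baseline_cvd Healthy CVD (percent) at the reference SCT of 333 um.
#' @param cvd_noise_sd Residual SD of per-eye CVD in percentage points.
#' @param artefact_fraction Fraction of eyes given a disqualifying artefact
#'   or low image score.
#' @param grid_nx,grid_ny,pixel_pitch,noise_sd,attenuation_length Passed to
#'   each eye's [phantom_config()].
#' @param csc_sct_source `"csc"` (default) draws CSC SCT from the thickened
#'   CSC distribution; `"healthy"` draws it from the healthy distribution
#'   instead, giving groups with equal SCT so that the pure group effect can
#'   be studied without the SCT confound.
#'
#' @return An object of class `phantom_cohort`: a list with `records` (one
#'   data.frame row per eye: `eye_id`, `age`, `sex`, `axial_length`, `sct`,
#'   `group`, `image_score`, six artefact flag columns,
#'   `wide_motion_artefact_count`, `lumen_fraction_100um`) and `configs`
#'   (a `phantom_config` per eye).
#' @export
generate_cohort <- function(n_healthy, n_csc = 0, effect = 8.2, slope = 3.9,
                            seed = NULL,
                            baseline_cvd = 56.5, cvd_noise_sd = 7.3,
                            artefact_fraction = 0,
                            grid_nx = 300L, grid_ny = 300L,
                            pixel_pitch = 3000 / grid_nx,
                            noise_sd = 10, attenuation_length = 100,
                            csc_sct_source = c("csc", "healthy")) {
  csc_sct_source <- match.arg(csc_sct_source)
  if (n_healthy < 0 || n_csc < 0 || n_healthy + n_csc < 1) {
    stop("cohort must contain at least one eye", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_healthy + n_csc
  group <- c(rep("healthy", n_healthy), rep("csc", n_csc))

  sct <- numeric(n); age <- numeric(n); al <- numeric(n); sex <- character(n)
  subtype <- character(n)
  for (i in seq_len(n)) {
    if (group[i] == "healthy") {
      sct[i] <- .rtnorm(1, 333.2, 94.2, lo = 150)
      age[i] <- .rtnorm(1, 39.4, 12.3, lo = 18, hi = 70)
      al[i] <- .rtnorm(1, 23.70, 1.18, lo = 20.5, hi = 26.5)
      sex[i] <- if (stats::runif(1) < 16 / 51) "M" else "F"
      subtype[i] <- "healthy"
    } else {
      sct[i] <- if (csc_sct_source == "healthy") {
        .rtnorm(1, 333.2, 94.2, lo = 150)
      } else {
        .rtnorm(1, 547.3, 118.3, lo = 200)
      }
      age[i] <- .rtnorm(1, 43.0, 8.4, lo = 18, hi = 70)
      al[i] <- .rtnorm(1, 22.82, 1.08, lo = 20.5, hi = 26.5)
      sex[i] <- if (stats::runif(1) < 14 / 22) "M" else "F"
      subtype[i] <- if (stats::runif(1) < 5 / 22) "csc_acute" else "csc_chronic"
    }
  }

  cvd_target <- baseline_cvd + slope * (sct - 333.2) / 100 +
    effect * (group == "csc") + stats::rnorm(n, 0, cvd_noise_sd)
  frac <- pmin(pmax(cvd_target / 100, 0.05), 0.95)

  image_score <- round(stats::runif(n, 70, 95))
  flags <- matrix(FALSE, n, 6,
                  dimnames = list(NULL, c("banding", "blink",
                                          "vessel_doubling", "stretching",
                                          "out_of_window", "crisscross")))
  motion <- stats::rbinom(n, 1, 0.15)

  n_art <- round(artefact_fraction * n)
  if (n_art > 0) {
    bad <- sample.int(n, n_art)
    kind <- sample(1:8, n_art, replace = TRUE)
    for (k in seq_len(n_art)) {
      i <- bad[k]
      if (kind[k] <= 6) {
        flags[i, kind[k]] <- TRUE
      } else if (kind[k] == 7) {
        image_score[i] <- round(stats::runif(1, 20, 49))
      } else {
        motion[i] <- sample(2:3, 1)
      }
    }
  }

  eye_seed <- sample.int(.Machine$integer.max - 1L, n)
  eye_id <- sprintf("%s%03d", ifelse(group == "healthy", "H", "C"),
                    stats::ave(seq_len(n), group, FUN = seq_along))

  records <- data.frame(
    eye_id = eye_id, age = age, sex = sex, axial_length = al, sct = sct,
    group = subtype, image_score = image_score,
    flag_banding = flags[, "banding"], flag_blink = flags[, "blink"],
    flag_vessel_doubling = flags[, "vessel_doubling"],
    flag_stretching = flags[, "stretching"],
    flag_out_of_window = flags[, "out_of_window"],
    flag_crisscross = flags[, "crisscross"],
    wide_motion_artefact_count = motion,
    lumen_fraction_100um = frac,
    stringsAsFactors = FALSE
  )

  configs <- lapply(seq_len(n), function(i) {
    phantom_config(
      grid_nx = grid_nx, grid_ny = grid_ny, pixel_pitch = pixel_pitch,
      sct = sct[i],
      lumen_fraction_by_depth = stats::setNames(frac[i], "98.8"),
      noise_sd = noise_sd, attenuation_length = attenuation_length,
      seed = eye_seed[i]
    )
  })
  names(configs) <- eye_id

  structure(list(records = records, configs = configs),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  r <- x$records
  cat(sprintf("Synthetic cohort: %d eyes (%d healthy, %d CSC)\n",
              nrow(r), sum(r$group == "healthy"), sum(r$group != "healthy")))
  cat(sprintf("  SCT %.0f-%.0f um; target CVD %.1f-%.1f%%\n",
              min(r$sct), max(r$sct),
              100 * min(r$lumen_fraction_100um),
              100 * max(r$lumen_fraction_100um)))
  invisible(x)
}
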