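.default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort = list(
      n_healthy = 6L, n_csc = 0L, effect = 8.2, slope = 3.9,
      baseline_cvd = 56.5, cvd_noise_sd = 7.3, artefact_fraction = 0,
      grid_nx = 300L, grid_ny = 300L, pixel_pitch = NULL,
      noise_sd = 10, attenuation_length = 100
    ),
    cvd_nominal_depth = 100,
    write_comparison_maps = TRUE,
    max_comparison_maps = 3L
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full phantom-to-statistics pipeline
#'
#' Generates a synthetic cohort, applies quality-control exclusions, builds
#' the fixed- and percentile-depth display/similarity profiles, selects the
#' optimal depth per series, measures CVD at the (quantized) nominal CVD
#' depth, and runs the cohort statistics: the healthy-eye regression of CVD
#' on age, axial length and SCT, and -- when CSC eyes are present -- the
#' matched-control one-way ANOVA and SCT-adjusted ANCOVA. All tables are
#' written as CSV, the narrative report and run log as text, and comparison
#' maps at the optimal fixed depth as RGB PNGs. All randomness flows from a
#' single top-level seed; a rerun with the same config and seed reproduces
#' the CSV outputs byte for byte.
#'
#' @param config Path to a YAML configuration file or an equivalent named
#'   list. Keys (all optional): `seed`; `cohort` (`n_healthy`, `n_csc`,
#'   `effect`, `slope`, `baseline_cvd`, `cvd_noise_sd`, `artefact_fraction`,
#'   `grid_nx`, `grid_ny`, `pixel_pitch`, `noise_sd`, `attenuation_length`);
#'   `cvd_nominal_depth`; `write_comparison_maps`; `max_comparison_maps`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a result bundle (class `octacvd_pipeline`): the
#'   cohort, QC split, both profiles, optimal depths, CVD table, statistics
#'   and output paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("octacvd_run_"),
                         seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file '%s' does not exist", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(.default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  notices <- character(0)

  cc <- cfg$cohort
  if (is.null(cc$pixel_pitch)) cc$pixel_pitch <- 3000 / cc$grid_nx
  cohort <- generate_cohort(
    n_healthy = cc$n_healthy, n_csc = cc$n_csc, effect = cc$effect,
    slope = cc$slope, seed = cfg$seed, baseline_cvd = cc$baseline_cvd,
    cvd_noise_sd = cc$cvd_noise_sd, artefact_fraction = cc$artefact_fraction,
    grid_nx = cc$grid_nx, grid_ny = cc$grid_ny, pixel_pitch = cc$pixel_pitch,
    noise_sd = cc$noise_sd, attenuation_length = cc$attenuation_length
  )
  write_roster_csv(cohort$records, file.path(out_dir, "roster.csv"))

  qc <- apply_exclusions(cohort$records)
  write_roster_csv(qc$log, file.path(out_dir, "qc_log.csv"))
  write_roster_csv(qc$included, file.path(out_dir, "roster_included.csv"))
  if (nrow(qc$included) == 0) {
    stop("quality control excluded every eye; nothing to analyse",
         call. = FALSE)
  }

  step <- 2.6
  eyes <- lapply(qc$included$eye_id, function(id) {
    gen <- generate_phantom_eye(cohort$configs[[id]], eye_id = id)
    rec <- qc$included[qc$included$eye_id == id, ]
    list(volume = gen$volume, record = rec, truth = gen$truth)
  })
  names(eyes) <- qc$included$eye_id

  prof_fixed <- depth_profile(eyes, depth_schedule("fixed", axial_step = step))
  write_depth_profile_csv(prof_fixed, file.path(out_dir, "profile_fixed.csv"))
  prof_pct <- depth_profile(eyes,
                            depth_schedule("percentile", axial_step = step))
  write_depth_profile_csv(prof_pct, file.path(out_dir,
                                              "profile_percentile.csv"))
  opt_fixed <- suppressWarnings(select_optimal_depth(prof_fixed))
  opt_pct <- suppressWarnings(select_optimal_depth(prof_pct))

  cvd_depth <- quantize_depth(cfg$cvd_nominal_depth, step)
  cvds <- cvd_table(lapply(eyes, function(e) {
    measure_cvd(extract_slab(e$volume, cvd_depth,
                             nominal_depth = cfg$cvd_nominal_depth))
  }))
  tab <- merge(cvds, qc$included, by = "eye_id", sort = FALSE)
  tab$is_csc <- tab$group != "healthy"
  write_roster_csv(cvds, file.path(out_dir, "cvd.csv"))

  if (isTRUE(cfg$write_comparison_maps) && !is.na(opt_fixed)) {
    n_maps <- min(cfg$max_comparison_maps, length(eyes))
    for (i in seq_len(n_maps)) {
      pair <- extract_slab(eyes[[i]]$volume, opt_fixed)
      cm <- comparison_map(suppressWarnings(binarize(pair$octa_image)),
                           suppressWarnings(binarize(pair$oct_image)))
      write_comparison_map_png(cm, file.path(out_dir,
        sprintf("map_%s_%sum.png", eyes[[i]]$record$eye_id,
                .depth_tag(opt_fixed))))
    }
  }

  healthy <- tab[!tab$is_csc, ]
  regression <- NULL
  if (nrow(healthy) >= 10) {
    regression <- fit_cvd_regression(healthy)
    utils::write.csv(cbind(term = rownames(regression$coefficients),
                           regression$coefficients),
                     file.path(out_dir, "regression.csv"),
                     row.names = FALSE)
  } else {
    notices <- c(notices, sprintf(
      "regression skipped: %d healthy eyes after QC (needs >= 10)",
      nrow(healthy)))
  }

  comparison <- NULL
  if (any(tab$is_csc)) {
    csc <- tab[tab$is_csc, ]
    controls <- tryCatch(
      match_controls(csc, healthy),
      error = function(e) {
        notices <<- c(notices, paste("control matching failed:",
                                     conditionMessage(e)))
        NULL
      })
    if (!is.null(controls) && nrow(csc) >= 3) {
      grp <- rbind(
        data.frame(cvd = csc$cvd, sct = csc$sct, group = "csc"),
        data.frame(cvd = controls$cvd, sct = controls$sct,
                   group = "control")
      )
      comparison <- list(
        n = table(grp$group),
        means = tapply(grp$cvd, grp$group, mean),
        sds = tapply(grp$cvd, grp$group, stats::sd),
        anova = anova_from_summary(
          tapply(grp$cvd, grp$group, mean),
          tapply(grp$cvd, grp$group, stats::sd),
          as.vector(table(grp$group))),
        ancova = ancova_group_effect(grp),
        controls = controls$eye_id
      )
      utils::write.csv(grp, file.path(out_dir, "group_comparison_data.csv"),
                       row.names = FALSE)
    }
  } else {
    notices <- c(notices, "group comparison skipped: no CSC eyes in cohort")
  }

  report <- c(
    "octacvd pipeline report",
    sprintf("eyes generated: %d; included after QC: %d; excluded: %d",
            nrow(cohort$records), nrow(qc$included), nrow(qc$excluded)),
    sprintf("optimal fixed depth: %s um",
            ifelse(is.na(opt_fixed), "none", format(opt_fixed))),
    sprintf("optimal percentile depth: %s %%SCT",
            ifelse(is.na(opt_pct), "none", format(opt_pct))),
    sprintf("CVD at %.1f um: mean %.1f%%, SD %.1f%% (n = %d)",
            cvd_depth, mean(cvds$cvd), stats::sd(cvds$cvd), nrow(cvds))
  )
  if (!is.null(regression)) {
    rc <- regression$coefficients["sct_per_100um", ]
    report <- c(report, sprintf(
      "healthy regression: CVD +%.2f%% per 100 um SCT (95%% CI %.2f to %.2f, p = %.3g), n = %d",
      rc$estimate, rc$ci_lower, rc$ci_upper, rc$p, regression$n))
  }
  if (!is.null(comparison)) {
    report <- c(report, sprintf(
      "CSC %.1f +/- %.1f%% vs matched controls %.1f +/- %.1f%%: ANOVA p = %.3g, SCT-adjusted ANCOVA p = %.3g",
      comparison$means["csc"], comparison$sds["csc"],
      comparison$means["control"], comparison$sds["control"],
      comparison$anova$p, comparison$ancova$p))
  }
  report <- c(report, notices)
  writeLines(report, file.path(out_dir, "report.txt"))

  writeLines(c(
    sprintf("octacvd %s", as.character(utils::packageVersion("octacvd"))),
    sprintf("seed: %s", cfg$seed),
    "configuration:",
    yaml::as.yaml(cfg)
  ), file.path(out_dir, "run_log.txt"))

  invisible(structure(list(
    config = cfg, out_dir = out_dir, cohort = cohort, qc = qc,
    profile_fixed = prof_fixed, profile_percentile = prof_pct,
    optimal_fixed_depth = opt_fixed, optimal_percentile_depth = opt_pct,
    cvd = cvds, regression = regression, comparison = comparison,
    notices = notices, report = report
  ), class = "octacvd_pipeline"))
}

#' @export
print.octacvd_pipeline <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  cat(sprintf("outputs in %s\n", x$out_dir))
  invisible(x)
}
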