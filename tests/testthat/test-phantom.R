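test_that("invalid configurations are rejected with the offending field named", {
  expect_error(phantom_config(sct = -10), "sct")
  expect_error(phantom_config(grid_nx = 8), "grid_nx")
  expect_error(phantom_config(axial_step = 0), "axial_step")
  expect_error(phantom_config(lumen_fraction_by_depth = c("100" = 1.4)),
               "lumen_fraction_by_depth")
  expect_error(phantom_config(vessel_diameter_range_deep = c(80, 20)),
               "vessel_diameter_range_deep")
})

test_that("phantom generation is deterministic given the seed", {
  cfg <- small_config(grid_nx = 48L, grid_ny = 48L, sct = 150,
                      lumen_fraction_by_depth = c("80" = 0.4), seed = 7)
  a <- generate_phantom_eye(cfg)
  b <- generate_phantom_eye(cfg)
  expect_identical(a$volume$oct_volume, b$volume$oct_volume)
  expect_identical(a$volume$octa_volume, b$volume$octa_volume)
  expect_identical(a$truth$lumen_mask, b$truth$lumen_mask)
})

test_that("realized lumen fraction stays within 0.05 of the keyed target", {
  for (target in c(0.30, 0.55, 0.75)) {
    cfg <- small_config(lumen_fraction_by_depth =
                          stats::setNames(target, "98.8"),
                        seed = round(100 * target))
    eye <- generate_phantom_eye(cfg)
    expect_lt(abs(lumen_fraction(eye$truth, 98.8) - target), 0.05)
  }
})

test_that("a zero-lumen, zero-noise phantom has uniform bright slabs", {
  cfg <- small_config(grid_nx = 48L, grid_ny = 48L, sct = 200,
                      lumen_fraction_by_depth = c("100" = 0),
                      noise_sd = 0, granular_decay_length = 0, seed = 3)
  eye <- generate_phantom_eye(cfg)
  slab <- extract_slab(eye$volume, quantize_depth(100, 2.6))
  expect_equal(stats::sd(slab$oct_image), 0)
  expect_equal(stats::sd(slab$octa_image), 0)
  expect_false(any(eye$truth$lumen_mask))
  # stroma is brighter than the deep-signal floor
  expect_gt(mean(slab$oct_image), cfg$noise_floor + 50)
})

test_that("slabs beyond the chorioscleral interface carry noise-floor signal only", {
  cfg <- small_config(seed = 11)
  eye <- generate_phantom_eye(cfg)
  deep <- extract_slab(eye$volume, quantize_depth(cfg$sct + 20, 2.6))
  expect_lte(mean(deep$octa_image), cfg$noise_floor + 3 * cfg$noise_sd)
  expect_lte(mean(deep$oct_image), cfg$noise_floor + 3 * cfg$noise_sd)
})

test_that("mean stroma intensity is non-increasing with depth (attenuation)", {
  cfg <- small_config(seed = 5)
  eye <- generate_phantom_eye(cfg)
  depths <- quantize_depth(seq(20, 240, by = 26), 2.6)
  stroma_mean <- vapply(depths, function(d) {
    j <- round(d / 2.6) + 1
    slab <- eye$volume$oct_volume[, , j]
    mean(slab[!eye$truth$lumen_mask[, , j]])
  }, numeric(1))
  expect_true(all(diff(stroma_mean) <= cfg$noise_sd))
})

test_that("null-slope cohorts give identical target lumen fractions", {
  coh <- generate_cohort(5, 0, effect = 0, slope = 0, seed = 7,
                         cvd_noise_sd = 0, grid_nx = 48, grid_ny = 48)
  expect_equal(nrow(coh$records), 5)
  expect_true(all(coh$records$group == "healthy"))
  expect_true(all(coh$records$lumen_fraction_100um == 0.565))
})

test_that("the group effect shifts CSC lumen fractions by the configured offset", {
  coh <- generate_cohort(300, 300, effect = 8.2, slope = 0, seed = 21,
                         grid_nx = 48, grid_ny = 48)
  r <- coh$records
  healthy <- r$lumen_fraction_100um[r$group == "healthy"]
  csc <- r$lumen_fraction_100um[r$group != "healthy"]
  expect_lt(abs(100 * (mean(csc) - mean(healthy)) - 8.2), 2)
})

test_that("cohorts are deterministic given the seed", {
  a <- generate_cohort(4, 2, seed = 99, grid_nx = 48, grid_ny = 48)
  b <- generate_cohort(4, 2, seed = 99, grid_nx = 48, grid_ny = 48)
  expect_identical(a$records, b$records)
  expect_identical(a$configs[[1]]$seed, b$configs[[1]]$seed)
})

test_that("healthy and CSC SCT distributions sit in their configured ranges", {
  coh <- generate_cohort(200, 200, seed = 13, grid_nx = 48, grid_ny = 48)
  r <- coh$records
  expect_true(all(r$sct[r$group == "healthy"] > 150))
  expect_true(all(r$sct[r$group != "healthy"] > 200))
  expect_lt(abs(mean(r$sct[r$group == "healthy"]) - 333), 25)
  expect_lt(abs(mean(r$sct[r$group != "healthy"]) - 547), 30)
})

test_that("a tilted phantom still recovers the target fraction through BM flattening", {
  cfg <- small_config(bm_tilt_steps = 4L, seed = 17)
  eye <- generate_phantom_eye(cfg)
  expect_equal(diff(range(eye$volume$bm_depth_map)), 4 * 2.6)
  expect_lt(abs(lumen_fraction(eye$truth, 98.8) - 0.55), 0.05)
  cvd <- measure_cvd(extract_slab(eye$volume, 98.8))
  expect_lt(abs(cvd$cvd - 55), 6)
})
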