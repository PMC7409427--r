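random_mask <- function(nx = 10, ny = 10, p = 0.5) {
  matrix(runif(nx * ny) < p, nx, ny)
}

test_that("similarity satisfies its identities", {
  set.seed(1)
  for (i in 1:25) {
    a <- random_mask()
    b <- random_mask()
    expect_equal(similarity(a, a), 100)
    expect_equal(similarity(a, !a), 0)
    expect_equal(similarity(a, b), similarity(b, a))
    s <- similarity(a, b)
    expect_gte(s, 0); expect_lte(s, 100)
    expect_equal(s + similarity(a, !b), 100)
  }
})

test_that("a 10x10 pair differing in 18 pixels has similarity 82", {
  a <- matrix(FALSE, 10, 10)
  b <- a
  b[1:18] <- TRUE
  expect_equal(similarity(a, b), 82)
})

test_that("shape mismatches are rejected naming both shapes", {
  expect_error(similarity(matrix(TRUE, 3, 4), matrix(TRUE, 4, 4)),
               "3x4 vs 4x4")
  expect_error(comparison_map(matrix(TRUE, 2, 2), matrix(TRUE, 2, 3)),
               "2x2 vs 2x3")
})

test_that("comparison maps classify pixels consistently with similarity", {
  set.seed(2)
  for (i in 1:25) {
    a <- random_mask(8, 12)
    b <- random_mask(8, 12)
    cm <- comparison_map(a, b)
    expect_equal(sum(cm$counts), length(a))
    expect_equal(unname(100 * (cm$counts[["both_white"]] +
                                 cm$counts[["both_black"]]) / length(a)),
                 similarity(a, b))
  }
  ident <- comparison_map(a, a)
  expect_equal(unname(ident$counts[c("octa_white_oct_black",
                                     "octa_black_oct_white")]), c(0, 0))
  compl <- comparison_map(a, !a)
  expect_equal(unname(compl$counts[c("both_white", "both_black")]), c(0, 0))
})

test_that("the display criterion passes stripes and rejects flat or noisy slabs", {
  # broad dark stripes on bright background, same in both modalities
  img <- matrix(200, 100, 100)
  img[, rep(seq(1, 100, by = 20), each = 8) +
        rep(0:7, times = 5)] <- 20
  pair <- structure(list(octa_image = img, oct_image = img,
                         eye_id = "s", nominal_depth = NA,
                         actual_depth = 98.8), class = "image_pair")
  expect_true(displays_vessels(pair))

  flat <- structure(list(octa_image = matrix(200, 50, 50),
                         oct_image = matrix(200, 50, 50),
                         eye_id = "f", nominal_depth = NA,
                         actual_depth = 98.8), class = "image_pair")
  expect_false(displays_vessels(flat))

  set.seed(3)
  noisy <- structure(list(octa_image = matrix(runif(2500, 0, 255), 50, 50),
                          oct_image = matrix(runif(2500, 0, 255), 50, 50),
                          eye_id = "n", nominal_depth = NA,
                          actual_depth = 98.8), class = "image_pair")
  expect_false(displays_vessels(noisy))
})

make_profile <- function(df) {
  attr(df, "kind") <- "fixed"
  class(df) <- c("depth_profile", "data.frame")
  df
}

test_that("optimal-depth selection is lexicographic with a shallow tie-break", {
  p <- make_profile(data.frame(
    depth_label = c(49.4, 98.8, 150.8),
    n_eyes = c(10, 10, 10),
    n_displaying = c(5, 10, 10),
    pct_displaying = c(50, 100, 100),
    similarity_mean = c(90, 82, 76),
    similarity_sd = c(1, 1, 1)))
  expect_equal(select_optimal_depth(p), 98.8)

  tied <- make_profile(data.frame(
    depth_label = c(49.4, 98.8),
    n_eyes = c(5, 5), n_displaying = c(5, 5),
    pct_displaying = c(100, 100),
    similarity_mean = c(80, 80), similarity_sd = c(1, 1)))
  expect_equal(select_optimal_depth(tied), 49.4)

  none <- make_profile(data.frame(
    depth_label = c(49.4, 98.8),
    n_eyes = c(5, 5), n_displaying = c(0, 0),
    pct_displaying = c(0, 0),
    similarity_mean = c(60, 55), similarity_sd = c(1, 1)))
  expect_warning(res <- select_optimal_depth(none), "no depth")
  expect_true(is.na(res))
})

test_that("depth profiles tally eligibility and flag undefined SDs", {
  cfg <- small_config(grid_nx = 48L, grid_ny = 48L, sct = 200,
                      lumen_fraction_by_depth = c("98.8" = 0.5), seed = 6)
  eye <- generate_phantom_eye(cfg, "a")
  rec <- list(sct = 200, eye_id = "a")
  eyes3 <- list(list(volume = eye$volume, record = rec),
                list(volume = eye$volume, record = rec),
                list(volume = eye$volume, record = rec))
  sched <- depth_schedule("fixed", values = c(100, 150))
  prof <- depth_profile(eyes3, sched)
  expect_equal(prof$n_eyes, c(3, 3))
  expect_equal(prof$similarity_sd, c(0, 0))  # identical eyes

  prof1 <- depth_profile(eyes3[1], sched)
  expect_equal(prof1$n_eyes, c(1, 1))
  expect_true(all(is.na(prof1$similarity_sd)))

  # a second eye with thinner choroid drops out of the deeper row
  cfg2 <- small_config(grid_nx = 48L, grid_ny = 48L, sct = 120,
                       lumen_fraction_by_depth = c("98.8" = 0.5), seed = 8)
  eye2 <- generate_phantom_eye(cfg2, "b")
  mixed <- list(list(volume = eye$volume, record = rec),
                list(volume = eye2$volume, record = list(sct = 120,
                                                         eye_id = "b")))
  prof2 <- depth_profile(mixed, sched)
  expect_equal(prof2$n_eyes, c(2, 1))
})

test_that("percentile profiles evaluate each eye at its own SCT fractions", {
  cfg <- small_config(grid_nx = 48L, grid_ny = 48L, sct = 208,
                      lumen_fraction_by_depth = c("98.8" = 0.5), seed = 9)
  eye <- generate_phantom_eye(cfg, "a")
  sched <- depth_schedule("percentile", values = c(0.25, 0.5))
  prof <- depth_profile(list(list(volume = eye$volume,
                                  record = list(sct = 208, eye_id = "a"))),
                        sched)
  expect_equal(prof$depth_label, c(25, 50))
  expect_equal(prof$n_eyes, c(1, 1))
})
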