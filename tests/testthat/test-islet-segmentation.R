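test_that("noise-free ellipsoid is delineated with near-perfect overlap", {
  sp <- scene_spec(grid_shape = c(40L, 96L, 96L), voxel_size = c(1, 0.5, 0.5),
                   n_cells = 0L, psf_sigma = c(0, 0, 0),
                   noise_gaussian_sd = 0, noise_poisson_scale = 0)
  sc <- render_scene(sp)
  pan <- delineate_pancreas(sc$red, fx_roi())
  gt <- sc$ground_truth$pancreas_mask
  dice <- 2 * sum(pan$mask & gt) / (sum(pan$mask) + sum(gt))
  expect_false(pan$empty)
  expect_gte(dice, 0.95)
})

test_that("all-zero red channel gives an empty mask with a flag, not an error", {
  red <- volumetric_image(array(0, c(8, 16, 16)), c(1, 0.5, 0.5), "red")
  pan <- delineate_pancreas(red, fx_roi(y_max = 8))
  expect_true(pan$empty)
  expect_false(any(pan$mask))
})

test_that("flipping the ROI tail side confines the mask to the opposite half-plane", {
  sp <- scene_spec(grid_shape = c(24L, 64L, 64L), voxel_size = c(1, 0.5, 0.5),
                   n_cells = 0L, psf_sigma = c(0, 0, 0),
                   noise_gaussian_sd = 0, noise_poisson_scale = 0)
  sc <- render_scene(sp)
  roi_mid <- head_tail_roi(rbind(c(0, 16), c(32, 16)), tail_side = 1L)
  pan_a <- delineate_pancreas(sc$red, roi_mid)
  roi_flip <- head_tail_roi(roi_mid$polyline, tail_side = -1L)
  pan_b <- delineate_pancreas(sc$red, roi_flip)
  xs_a <- which(apply(pan_a$mask, 3, any))
  xs_b <- which(apply(pan_b$mask, 3, any))
  # x voxel centers at (i - 0.5) * 0.5 um; split at 16 um = index 32.5
  expect_true(all(xs_a > 32))
  expect_true(all(xs_b <= 32))
})

test_that("the 100 um3 size filter keeps the r=4 sphere and drops the r=2.5 sphere", {
  sc <- fx_two_sphere_scene()
  res <- quantify_islets(sc$red, sc$green, fx_roi(), min_volume = 100)
  expect_equal(nrow(res$islets), 1L)
  true_v <- 4 / 3 * pi * 4^3
  expect_equal(res$islets$volume_um3, true_v, tolerance = 0.15)
  # and the filter is monotone: raising min_volume never adds objects
  res_lo <- segment_islets(sc$green, res$pancreas$mask, min_volume = 10)
  expect_gte(nrow(res_lo), nrow(res$islets))
  res_hi <- segment_islets(sc$green, res$pancreas$mask, min_volume = 500)
  expect_lte(nrow(res_hi), nrow(res$islets))
})

test_that("empty green channel yields an empty islet table", {
  sc <- fx_two_sphere_scene()
  pan <- delineate_pancreas(sc$red, fx_roi())
  blank <- volumetric_image(array(0, dim(sc$green$voxels)),
                            sc$green$voxel_size, "green")
  expect_equal(nrow(segment_islets(blank, pan$mask, 100)), 0L)
})

test_that("segmented sphere volume error shrinks when the voxel size is halved", {
  mk <- function(grid, vs) {
    sp <- scene_spec(grid_shape = grid, voxel_size = vs, n_cells = 1L,
                     psf_sigma = c(0, 0, 0), noise_gaussian_sd = 0,
                     noise_poisson_scale = 0)
    sc <- render_scene(sp, centers = matrix(c(12, 12, 12), 1), radii = 4)
    pan <- array(TRUE, dim(sc$green$voxels))
    segment_islets(sc$green, pan, min_volume = 100,
                   background_radius = 11)$volume_um3
  }
  true_v <- 4 / 3 * pi * 4^3
  v_coarse <- mk(c(24L, 48L, 48L), c(1, 0.5, 0.5))
  v_fine <- mk(c(48L, 96L, 96L), c(0.5, 0.25, 0.25))
  err_coarse <- abs(v_coarse - true_v) / true_v
  err_fine <- abs(v_fine - true_v) / true_v
  shell_coarse <- 4 * pi * 16 * 1 / true_v
  expect_lt(err_coarse, shell_coarse)
  expect_lt(err_fine, err_coarse)
})

test_that("sum of islet volumes never exceeds the pancreas mask volume", {
  sc <- fx_two_sphere_scene()
  res <- quantify_islets(sc$red, sc$green, fx_roi(), min_volume = 10)
  expect_lte(sum(res$islets$volume_um3), res$pancreas$volume_um3)
})

test_that("segmentation is equivariant to 90-degree rotation of the stack", {
  sc <- fx_two_sphere_scene()
  pan <- array(TRUE, dim(sc$green$voxels))
  isl <- segment_islets(sc$green, pan, min_volume = 10)
  # rotate 90 degrees in the (y, x) plane: x' = y reversed, keep voxel sizes
  rot <- aperm(sc$green$voxels, c(1, 3, 2))[, , dim(sc$green$voxels)[2]:1]
  green_r <- volumetric_image(rot, sc$green$voxel_size[c(1, 3, 2)], "green")
  isl_r <- segment_islets(green_r, array(TRUE, dim(rot)), min_volume = 10)
  expect_equal(sort(isl$volume_um3), sort(isl_r$volume_um3))
})

test_that("missing voxel metadata is a hard error", {
  sc <- fx_two_sphere_scene()
  broken <- sc$green
  broken$voxel_size <- c(NA_real_, NA_real_, NA_real_)
  expect_error(segment_islets(broken, array(TRUE, dim(broken$voxels)), 100),
               "voxel size")
})

test_that("spot counting recovers rendered nuclei and respects the mask", {
  sp <- scene_spec(grid_shape = c(40L, 96L, 96L), voxel_size = c(1, 0.5, 0.5),
                   n_cells = 0L, psf_sigma = c(0.8, 0.4, 0.4),
                   noise_gaussian_sd = 0.01, noise_poisson_scale = 500)
  ctrs <- rbind(c(20, 15, 15), c(20, 30, 30), c(12, 22, 38))
  sc <- render_scene(sp, centers = ctrs, radii = rep(2.5, 3))
  spots <- count_spots(sc$green, diameter = 5, intensity_threshold = 0.1)
  expect_equal(nrow(spots), 3L)

  # exclude one nucleus by masking
  mask <- array(TRUE, dim(sc$green$voxels))
  mask[, , 70:96] <- FALSE   # x > 34.5 um excluded, drops the nucleus at x=38
  spots2 <- count_spots(sc$green, mask, diameter = 5,
                        intensity_threshold = 0.1)
  expect_equal(nrow(spots2), 2L)

  # empty mask -> empty spot set
  expect_equal(nrow(count_spots(sc$green, array(FALSE, dim(sc$green$voxels)),
                                5)), 0L)
})

test_that("seeded random nuclei are all recovered within one voxel", {
  set.seed(77)
  n <- 12L
  centers <- matrix(NA_real_, n, 3)
  i <- 1L
  while (i <= n) {
    cand <- c(runif(1, 8, 32), runif(1, 8, 40), runif(1, 8, 40))
    if (i == 1L ||
        min(sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE],
                               2, cand)^2))) > 7) {
      centers[i, ] <- cand; i <- i + 1L
    }
  }
  sp <- scene_spec(grid_shape = c(40L, 96L, 96L), voxel_size = c(1, 0.5, 0.5),
                   n_cells = 0L, psf_sigma = c(0.8, 0.4, 0.4),
                   noise_gaussian_sd = 0.01, noise_poisson_scale = 500)
  sc <- render_scene(sp, centers = centers, radii = rep(2.5, n))
  spots <- count_spots(sc$green, diameter = 5, intensity_threshold = 0.1)
  expect_equal(nrow(spots), n)
  found <- as.matrix(spots[, c("z_um", "y_um", "x_um")])
  nn <- vapply(seq_len(n), function(i)
    min(sqrt(rowSums(sweep(found, 2, centers[i, ])^2))), 0)
  expect_true(all(nn <= max(sp$voxel_size)))
})

test_that("islet report collates samples deterministically and logs empty ones", {
  sc <- fx_two_sphere_scene()
  res <- quantify_islets(sc$red, sc$green, fx_roi(), min_volume = 10)
  empty_tab <- res$islets[0, ]
  out1 <- withr::local_tempdir()
  tab <- islet_report(list(a = list(islets = res$islets, group = "CTL",
                                    green = sc$green),
                           b = list(islets = empty_tab, group = "LY")),
                      out1, params = list(min_volume = 10))
  expect_equal(nrow(tab), nrow(res$islets))
  log <- jsonlite::read_json(file.path(out1, "run_log.json"),
                             simplifyVector = TRUE)
  expect_equal(log$samples$b$n_islets, 0L)
  expect_true(file.exists(file.path(out1, "a_montage.png")))

  out2 <- withr::local_tempdir()
  islet_report(list(a = list(islets = res$islets, group = "CTL",
                             green = sc$green),
                    b = list(islets = empty_tab, group = "LY")),
               out2, params = list(min_volume = 10))
  expect_identical(readLines(file.path(out1, "islet_volumes.csv")),
                   readLines(file.path(out2, "islet_volumes.csv")))
})

test_that("volumetric TIFF round-trips voxels and metadata", {
  sp <- scene_spec(grid_shape = c(8L, 16L, 16L), n_cells = 1L,
                   psf_sigma = c(0, 0, 0), noise_gaussian_sd = 0,
                   noise_poisson_scale = 0,
                   pancreas_semiaxes = c(3, 6, 6), cell_radius_range = c(2, 2))
  sc <- render_scene(sp)
  path <- withr::local_tempfile(fileext = ".tif")
  write_volumetric_tiff(sc$green, path)
  back <- read_volumetric_tiff(path)
  expect_equal(back$voxel_size, sc$green$voxel_size)
  expect_equal(back$voxels, sc$green$voxels, tolerance = 1e-4)
  expect_equal(back$channel_label, "green")
})

test_that("YAML config round-trips parameters and rejects unknown keys", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_volume: 50", "threshold: 0.2"), cfg_path)
  cfg <- read_pipeline_config(cfg_path)
  expect_equal(cfg$min_volume, 50)
  expect_equal(cfg$threshold, 0.2)
  expect_equal(cfg$smoothing_sigma, 0.5)   # untouched default
  writeLines("min_vol: 50", cfg_path)
  expect_error(read_pipeline_config(cfg_path), "unknown config keys")
  expect_equal(read_pipeline_config()$spot_diameter, 5)
})
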