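test_that("spec validation rejects impossible geometry and GE phantom objects", {
  expect_error(phantom_spec(grid_shape = c(16, 16, 16),
                            brain_axes = c(12, 5, 3)),
               "exceeds the grid")
  expect_error(phantom_spec(brain_axes = c(-1, 5, 3)), "semi-axes")
  expect_error(phantom_spec(modality = "GE", external_phantom = TRUE),
               "SE")
  expect_error(phantom_spec(noise_sigma = -0.1), "noise_sigma")
  expect_error(phantom_spec(tissue_intensities = c(WM = -1, GM = 1, CSF = 1)),
               "intensities")
})

test_that("phantom generation is deterministic and label-consistent", {
  spec <- phantom_spec(seed = 42, modality = "SE")
  a <- make_brain_phantom(spec)
  b <- make_brain_phantom(spec)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$labels, b$labels)
  expect_setequal(unique(as.vector(a$labels)), 0:5)
  expect_identical(a$brain_mask, array(a$labels %in% 1:3, dim = dim(a$labels)))
  # brain mask lies inside the nonzero intensity support
  expect_true(all(a$intensity[a$brain_mask] > 0))
})

test_that("without shell or phantom the brain mask is exactly the support", {
  spec <- phantom_spec(modality = "GE", shell_thickness = 0,
                       external_phantom = FALSE, seed = 3)
  ph <- make_brain_phantom(spec)
  expect_identical(ph$brain_mask, array(ph$intensity > 0, dim = dim(ph$intensity)))
})

test_that("brain volume agrees with the analytic ellipsoid volume", {
  spec <- phantom_spec(grid_shape = c(64, 64, 64), brain_axes = c(10, 8, 6),
                       modality = "GE", shell_thickness = 0,
                       external_phantom = FALSE, seed = 7)
  ph <- make_brain_phantom(spec)
  analytic <- 4 / 3 * pi * 10 * 8 * 6
  expect_lt(abs(sum(ph$brain_mask) - analytic) / analytic, 0.15)
})

test_that("SE shells are brighter than GE shells under default profiles", {
  ge <- make_brain_phantom(phantom_spec(modality = "GE", seed = 5))
  se <- make_brain_phantom(phantom_spec(modality = "SE", seed = 5))
  expect_gt(mean(se$intensity[se$labels == 4]),
            mean(ge$intensity[ge$labels == 4]))
})

test_that("SE phantoms contain a disjoint external object, GE none", {
  se <- make_brain_phantom(phantom_spec(modality = "SE", seed = 9))
  ge <- make_brain_phantom(phantom_spec(modality = "GE", seed = 9))
  expect_gt(sum(se$labels == 5), 0)
  expect_identical(sum(ge$labels == 5), 0L)
  # disjoint from head: external voxels are not shell or brain
  expect_identical(sum(se$labels == 5 & se$brain_mask), 0L)
})

test_that("coil bias follows the closed-form loop falloff", {
  prof <- coil_profile(center = c(1, 1, 1), radius_mm = 10, floor = 0.2)
  b <- make_coil_bias(prof, c(21, 1, 1))
  expect_equal(b[1, 1, 1], 1.0)
  expect_equal(b[11, 1, 1], 0.2 + 0.8 / 2^1.5, tolerance = 1e-12)
  # far-field approaches the floor
  far <- make_coil_bias(prof, c(2000, 1, 1))[2000, 1, 1]
  expect_lt(far - 0.2, 1e-3)
  expect_true(all(b >= 0.2 & b <= 1))
})

test_that("plane-mean bias decreases monotonically away from the coil", {
  spec <- phantom_spec(seed = 1)
  prof <- coil_for_spec(spec)
  b <- make_coil_bias(prof, spec$grid_shape, spec$voxel_size)
  plane_means <- apply(b, 3, mean)
  dist <- abs(seq_len(spec$grid_shape[3]) - prof$center[3]) *
    spec$voxel_size[3]
  ord <- order(dist)
  expect_true(all(diff(plane_means[ord]) <= 1e-12))
})

test_that("source composition obeys bias, noise and masking contracts", {
  spec0 <- phantom_spec(noise_sigma = 0, seed = 11)
  prof <- coil_for_spec(spec0)
  p0 <- make_pair(spec0, prof)
  ph <- make_brain_phantom(spec0)
  bias <- make_coil_bias(prof, spec0$grid_shape, spec0$voxel_size)
  expect_equal(p0$source, ph$intensity * bias, tolerance = 1e-12)
  # target: unbiased intensity on the mask, exactly zero elsewhere
  expect_true(all(p0$target[!p0$brain_mask] == 0))
  expect_equal(p0$target[p0$brain_mask], ph$intensity[p0$brain_mask])
  # uniform coil (floor = 1): source restricted to the mask equals the target
  uni <- coil_profile(center = prof$center, radius_mm = prof$radius_mm,
                      floor = 1)
  p1 <- make_pair(spec0, uni)
  expect_equal(p1$source * p1$brain_mask, p1$target, tolerance = 1e-12)
})

test_that("additive noise matches the requested standard deviation", {
  spec <- phantom_spec(noise_sigma = 0.05, seed = 13)
  prof <- coil_for_spec(spec)
  pair <- make_pair(spec, prof)
  ph <- make_brain_phantom(spec)
  bias <- make_coil_bias(prof, spec$grid_shape, spec$voxel_size)
  # measure on voxels far from the zero-clipping boundary (signal >> sigma)
  signal <- ph$intensity * bias
  idx <- signal > 0.25
  expect_gt(sum(idx), 1000)
  resid <- (pair$source - signal)[idx]
  expect_lt(abs(sd(resid) - 0.05) / 0.05, 0.10)
})

test_that("dataset split arithmetic, determinism and composition hold", {
  base <- toy_base_spec()
  ds <- make_dataset(10, 0, test_fraction = 0.1, seed = 5, base_spec = base)
  expect_identical(sum(ds$split == "train"), 9L)
  expect_identical(sum(ds$split == "test"), 1L)
  expect_true(all(vapply(ds$pairs, function(p) p$modality, "") == "GE"))
  ds2 <- make_dataset(10, 0, test_fraction = 0.1, seed = 5, base_spec = base)
  expect_identical(ds$split, ds2$split)
  expect_identical(ds$pairs[[3]]$source, ds2$pairs[[3]]$source)
  expect_identical(sum(ds$composition$n), 10L)
  # expected held-out count equals round(n * fraction) across seeds
  counts <- vapply(1:20, function(s) {
    d <- make_dataset(8, 4, test_fraction = 0.25, seed = s,
                      base_spec = micro_spec())
    sum(d$split == "test")
  }, integer(1))
  expect_equal(mean(counts), 3)
  expect_error(make_dataset(1, 0, 0.1), "at least 2")
  expect_error(make_dataset(5, 5, 1.5), "test_fraction")
})

test_that("target support and brain mask overlap perfectly by construction", {
  pair <- make_pair(phantom_spec(modality = "SE", seed = 17))
  expect_equal(dice(array(as.numeric(pair$target > 0), dim = dim(pair$target)),
                    array(as.numeric(pair$brain_mask), dim = dim(pair$brain_mask))),
               1.0)
})

test_that("pairs round-trip through NIfTI files with a JSON sidecar", {
  dir <- tempfile("pairs_")
  pair <- make_pair(micro_spec(seed = 21))
  files <- write_pair(pair, dir, "p01", split = "train")
  expect_true(all(file.exists(files)))
  src <- read_volume(files[1])
  expect_equal(as.vector(src), as.vector(pair$source), tolerance = 1e-6)
  expect_equal(attr(src, "voxel_size"), c(0.3, 0.3, 0.5), tolerance = 1e-6)
  meta <- jsonlite::read_json(files[4], simplifyVector = TRUE)
  expect_identical(meta$modality, "GE")
  expect_identical(meta$split, "train")
  unlink(dir, recursive = TRUE)
})
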