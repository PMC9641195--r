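# Phantoms are built small here (coarse meshes/voxels keep the suite fast);
# the tighter convergence checks live in test-acceptance.R.

test_that("closed-form ground truths are what the geometry says", {
  p <- make_phantom(phantom_spec("bullet_lv", list(r = 20, L = 80),
                                 mesh_resolution = 5000, voxel_spacing = 2))
  expect_equal(p$truth_volume_cm3,
               (pi * 400 * 60 + 2 / 3 * pi * 8000) / 1000)   # 92.15 cm^3
  expect_equal(mesh_volume(p$smooth_mesh)$volume_cm3, p$truth_volume_cm3,
               tolerance = 0.01)
  expect_gte(nrow(p$smooth_mesh$faces), 4000)

  e <- make_phantom(phantom_spec("ellipsoid", list(a = 25, b = 25, c = 40),
                                 mesh_resolution = 1280, voxel_spacing = 2))
  expect_equal(e$truth_volume_cm3, 4 / 3 * pi * 25 * 25 * 40 / 1000) # 104.72
  expect_equal(mesh_volume(e$smooth_mesh)$volume_cm3, e$truth_volume_cm3,
               tolerance = 0.01)
})

test_that("phantom meshes are watertight and consistently oriented", {
  for (shape in c("bullet_lv", "ellipsoid", "crescent_rv")) {
    p <- make_phantom(phantom_spec(shape, mesh_resolution = 500,
                                   voxel_spacing = 4,
                                   trabeculation = list(amplitude = 2, seed = 7)))
    for (mesh in list(p$smooth_mesh, p$ibp_mesh)) {
      d <- mesh_diagnostics(mesh)
      expect_true(d$is_watertight)
      expect_true(d$is_orientation_consistent)
    }
    expect_gt(mesh_volume(p$smooth_mesh)$signed_volume_cm3, 0)
  }
})

test_that("crescent quadrature truth matches an independent voxel-counting oracle", {
  spec <- phantom_spec("crescent_rv", mesh_resolution = 320, voxel_spacing = 8)
  p <- make_phantom(spec)
  prm <- chambervol:::crescent_params(spec$dimensions)
  mask <- chambervol:::voxelize_member(
    function(q) chambervol:::crescent_member(q, prm),
    -spec$dimensions$outer, spec$dimensions$outer, 1)
  voxel_truth <- sum(mask$occupancy) * prod(mask$spacing) / 1000
  expect_equal(p$truth_volume_cm3, voxel_truth, tolerance = 0.01)
})

test_that("trabeculation strictly shrinks the inner-blood-pool volume, monotonically", {
  vols <- vapply(c(0, 1, 2, 3), function(a) {
    p <- make_phantom(phantom_spec("bullet_lv", mesh_resolution = 800,
                                   voxel_spacing = 8,
                                   trabeculation = list(amplitude = a, seed = 7)))
    mesh_volume(p$ibp_mesh)$volume_cm3
  }, numeric(1))
  smooth_vol <- vols[1]                 # amplitude 0: ibp equals smooth
  expect_true(all(diff(vols) < 0))
  expect_lt(vols[2], smooth_vol)
})

test_that("excessive trabeculation amplitude is rejected with the violated bound", {
  expect_error(
    make_phantom(phantom_spec("bullet_lv", list(r = 10, L = 40),
                              mesh_resolution = 500, voxel_spacing = 8,
                              trabeculation = list(amplitude = 15, seed = 1))),
    "self-intersect")
})

test_that("mesh and mask both converge to truth along a refinement ladder", {
  spec0 <- phantom_spec("bullet_lv", list(r = 20, L = 80))
  truth <- chambervol:::bullet_truth_cm3(20, 80)
  mesh_err <- vapply(c(500, 2000, 8000), function(res) {
    m <- chambervol:::smooth_phantom_mesh("bullet_lv", spec0$dimensions, res)
    abs(mesh_volume(m)$volume_cm3 - truth) / truth
  }, numeric(1))
  expect_true(all(diff(mesh_err) < 0))

  mask_err <- vapply(c(4, 2, 1), function(h) {
    p <- make_phantom(phantom_spec("bullet_lv", list(r = 20, L = 80),
                                   mesh_resolution = 320, voxel_spacing = h))
    abs(slice_volume(p$smooth_mask)$volume_cm3 - truth) / truth
  }, numeric(1))
  expect_true(all(diff(mask_err) < 0))
  expect_lt(mask_err[3], 0.01)
})

test_that("identical seeds reproduce byte-identical cohort tables", {
  co1 <- make_cohort(n = 3, seed = 123, mesh_resolution = 500, voxel_spacing = 4)
  co2 <- make_cohort(n = 3, seed = 123, mesh_resolution = 500, voxel_spacing = 4)
  expect_identical(co1, co2)
  co3 <- make_cohort(n = 3, seed = 124, mesh_resolution = 500, voxel_spacing = 4)
  expect_false(identical(co1$vrps_cm3, co3$vrps_cm3))
})

test_that("degenerate cohort settings collapse the three methods onto each other", {
  co <- make_cohort(n = 4, seed = 5, method_noise = 0,
                    trabeculation = list(amplitude_mean = 0, amplitude_sd = 0),
                    mesh_resolution = 2000, voxel_spacing = 1)
  expect_identical(co$vribp_cm3, co$vrps_cm3)   # zero amplitude: same mesh
  expect_equal(co$pdp_cm3, co$vrps_cm3, tolerance = 0.02)  # discretization only
})

test_that("cohort with positive trabeculation shows the inner-blood-pool deficit", {
  co <- make_cohort(n = 6, seed = 21, mesh_resolution = 800, voxel_spacing = 4)
  expect_true(all(co$vribp_cm3 + attr(co, "config")$method_noise[["vribp"]] * 10 >
                    0))  # sane magnitudes
  expect_gt(mean(co$vrps_cm3 - co$vribp_cm3), 0)
})

test_that("phantom export writes readable STL + NIfTI + sidecar", {
  p <- make_phantom(phantom_spec("ellipsoid", mesh_resolution = 320,
                                 voxel_spacing = 4))
  dir <- file.path(tempdir(), "phantom_export")
  withr::defer(unlink(dir, recursive = TRUE))
  paths <- export_phantom(p, dir)
  expect_true(all(file.exists(paths)))
  back <- read_stl(paths[["smooth_stl"]])
  expect_equal(mesh_volume(back)$volume_cm3,
               mesh_volume(p$smooth_mesh)$volume_cm3, tolerance = 1e-5)
  mask <- read_mask_nifti(paths[["mask_nii"]])
  expect_equal(slice_volume(mask)$volume_cm3,
               slice_volume(p$smooth_mask)$volume_cm3)
  sc <- jsonlite::read_json(paths[["sidecar"]], simplifyVector = TRUE)
  expect_equal(sc$truth_volume_cm3, p$truth_volume_cm3, tolerance = 1e-8)
})
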