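test_that("tetrahedron signed volume matches the triple product with winding sign", {
  expect_equal(tetra_signed_volume(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 1 / 6)
  expect_equal(tetra_signed_volume(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)), -1 / 6)
  expect_equal(tetra_signed_volume(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)), 0)
  # antisymmetric under swapping any pair
  set.seed(3)
  for (i in 1:10) {
    p <- lapply(1:3, function(i) rnorm(3))
    v0 <- tetra_signed_volume(p[[1]], p[[2]], p[[3]])
    expect_equal(tetra_signed_volume(p[[2]], p[[1]], p[[3]]), -v0)
    expect_equal(tetra_signed_volume(p[[1]], p[[3]], p[[2]]), -v0)
    expect_equal(tetra_signed_volume(p[[3]], p[[2]], p[[1]]), -v0)
  }
})

test_that("polygon summation recovers exact volume, sign, translation and scaling", {
  cube <- cube_mesh(10)
  res <- mesh_volume(cube)
  expect_equal(res$signed_volume_cm3, 1)
  expect_equal(res$volume_cm3, 1)
  expect_identical(res$n_elements, 12L)

  rev <- triangle_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  res_rev <- mesh_volume(rev)
  expect_equal(res_rev$signed_volume_cm3, -1)
  expect_equal(res_rev$volume_cm3, 1)

  shifted <- triangle_mesh(sweep(cube$vertices, 2, c(250, -40, 7), "+"),
                           cube$faces)
  expect_equal(mesh_volume(shifted)$volume_cm3, 1, tolerance = 1e-9)

  scaled <- triangle_mesh(cube$vertices * 3, cube$faces)
  expect_equal(mesh_volume(scaled)$volume_cm3, 27)
})

test_that("polygon summation equals the divergence-theorem oracle on random closed meshes", {
  set.seed(42)
  for (i in 1:50) {
    mesh <- random_star_mesh(radius = runif(1, 5, 40),
                             jitter = runif(1, 0, 0.4),
                             center = runif(3, -100, 100))
    got <- mesh_volume(mesh)$signed_volume_mm3
    want <- divergence_volume_mm3(mesh)
    expect_equal(got, want, tolerance = 1e-9)
    expect_gt(got, 0)   # outward winding
  }
})

test_that("icosphere volume converges to the analytic sphere volume", {
  analytic <- 4 / 3 * pi * 10^3 / 1000
  err <- vapply(1:3, function(s)
    abs(mesh_volume(icosphere_mesh(10, s))$volume_cm3 - analytic) / analytic,
    numeric(1))
  expect_lt(err[3], 0.01)          # 1280 faces within 1%
  expect_true(all(diff(err) < 0))  # refinement strictly reduces the error
})

test_that("strict mode refuses open or inconsistently wound meshes", {
  cube <- cube_mesh(10)
  holed <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_volume(holed), "watertight")
  lenient <- mesh_volume(holed, strict = FALSE)
  expect_false(lenient$diagnostics$is_watertight)
  expect_true(is.finite(lenient$volume_cm3))
})

test_that("slice area is occupied count times in-plane voxel area", {
  expect_equal(slice_area(matrix(1, 10, 10), c(1, 1)), 100)
  expect_equal(slice_area(matrix(0, 4, 4), c(1, 1)), 0)
  s <- matrix(0, 4, 4); s[c(1, 6, 11)] <- 1
  expect_equal(slice_area(s, c(0.5, 0.5)), 0.75)
})

test_that("slice summation equals voxel count times voxel volume, any axis", {
  occ <- array(1L, c(10, 10, 10))
  m <- voxel_mask(occ, spacing = c(1, 1, 1))
  expect_equal(slice_volume(m)$volume_cm3, 1)
  expect_equal(slice_volume(voxel_mask(array(0L, c(5, 5, 5)), 1))$volume_cm3, 0)

  set.seed(9)
  occ <- array(rbinom(6 * 7 * 8, 1, 0.4), c(6, 7, 8))
  m <- voxel_mask(occ, spacing = c(0.7, 1.1, 2.3))
  want <- sum(occ) * 0.7 * 1.1 * 2.3 / 1000
  for (ax in 1:3)
    expect_equal(slice_volume(m, slice_axis = ax)$volume_cm3, want)
  # per-slice areas times thickness recompose the volume
  res <- slice_volume(m, slice_axis = 2)
  expect_equal(sum(res$diagnostics$slice_areas_mm2) *
                 res$diagnostics$slice_thickness_mm / 1000, want)
})

test_that("the engines agree on a matched cube mesh and exact voxelization", {
  cube <- cube_mesh(10)
  m <- voxel_mask(array(1L, c(10, 10, 10)), spacing = 1)
  cmp <- compare_engines(cube, m)
  expect_equal(cmp$difference_cm3, 0)
  expect_equal(cmp$relative_difference, 0)
})

test_that("engine disagreement shrinks under voxel refinement on a sphere", {
  ctr <- c(0.3, 0.7, -0.2)   # off-grid centre: no symmetric voxel luck
  mesh <- icosphere_mesh(15, 4, center = ctr)
  member <- function(p) rowSums(sweep(p, 2, ctr)^2) <= 15^2
  reldiff <- vapply(c(4, 0.75), function(h) {
    mask <- chambervol:::voxelize_member(member, ctr - 15, ctr + 15, h)
    abs(compare_engines(mesh, mask)$relative_difference)
  }, numeric(1))
  expect_lt(reldiff[2], 0.01)
  expect_lt(reldiff[2], reldiff[1])
})

test_that("NIfTI masks round-trip and non-axis-aligned affines are rejected", {
  set.seed(5)
  occ <- array(rbinom(4 * 5 * 6, 1, 0.5), c(4, 5, 6))
  m <- voxel_mask(occ, spacing = c(0.5, 0.5, 2))
  f <- local_tempfile(".nii.gz")
  write_mask_nifti(m, f)
  back <- read_mask_nifti(f)
  expect_equal(back$occupancy, m$occupancy, ignore_attr = TRUE)
  expect_equal(back$spacing, m$spacing)
  expect_equal(slice_volume(back)$volume_cm3, slice_volume(m)$volume_cm3)

  img <- RNifti::asNifti(array(1, c(4, 4, 4)))
  rot <- matrix(c(cos(0.3), -sin(0.3), 0, sin(0.3), cos(0.3), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  aff <- rbind(cbind(rot, c(0, 0, 0)), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  f2 <- local_tempfile(".nii.gz")
  RNifti::writeNifti(img, f2)
  expect_error(read_mask_nifti(f2), "axis-aligned")
})
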