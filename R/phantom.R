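#' Icosphere mesh
#'
#' Geodesic sphere obtained by recursive 4-way subdivision of a regular
#' icosahedron with re-projection onto the sphere; 20 * 4^subdivisions
#' faces, watertight and consistently outward-wound.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of subdivision rounds (0 = icosahedron).
#' @param center sphere centre.
#' @return a [triangle_mesh()].
#' @examples
#' m <- icosphere_mesh(10, 3)   # 1280 faces
#' mesh_volume(m)$volume_cm3    # close to 4/3 pi 10^3 / 1000
#' @export
icosphere_mesh <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  stopifnot(radius > 0, subdivisions >= 0)
  t <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1,  t,  0,   1,  t,  0,  -1, -t,  0,   1, -t,  0,
                 0, -1,  t,   0,  1,  t,   0, -1, -t,   0,  1, -t,
                 t,  0, -1,   t,  0,  1,  -t,  0, -1,  -t,  0,  1),
              ncol = 3L, byrow = TRUE)
  v <- v / sqrt(rowSums(v * v))
  f <- matrix(c(1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
                2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
                4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
                5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2),
              ncol = 3L, byrow = TRUE)
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    nf <- nrow(f)
    ed <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    lo <- pmin(ed[, 1L], ed[, 2L]); hi <- pmax(ed[, 1L], ed[, 2L])
    key <- lo * (nv + 1) + hi
    first <- !duplicated(key)
    mid_of <- nv + match(key, key[first])
    mids <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids * mids))
    v <- rbind(v, mids)
    e1 <- mid_of[seq_len(nf)]
    e2 <- mid_of[nf + seq_len(nf)]
    e3 <- mid_of[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1L], e1, e3),
               cbind(f[, 2L], e2, e1),
               cbind(f[, 3L], e3, e2),
               cbind(e1, e2, e3))
  }
  v <- v * radius
  v <- sweep(v, 2L, as.numeric(center), "+")
  triangle_mesh(v, f, name = sprintf("icosphere_r%g_s%d", radius, subdivisions))
}

# Surface of revolution about the z axis. profile: matrix (rad, z) from the
# bottom pole (rad = 0) to the top pole (rad = 0), traversed "up" along the
# surface; ntheta segments around. Outward winding by construction.
revolve_mesh <- function(profile, ntheta, name = "") {
  stopifnot(nrow(profile) >= 3L, profile[1L, 1L] == 0, profile[nrow(profile), 1L] == 0,
            all(profile[-c(1L, nrow(profile)), 1L] > 0), ntheta >= 3L)
  theta <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  nr <- nrow(profile) - 2L            # interior rings
  rings <- profile[-c(1L, nrow(profile)), , drop = FALSE]
  verts <- matrix(0, 2L + nr * ntheta, 3L)
  verts[1L, ] <- c(0, 0, profile[1L, 2L])
  verts[2L, ] <- c(0, 0, profile[nrow(profile), 2L])
  for (i in seq_len(nr)) {
    idx <- 2L + (i - 1L) * ntheta + seq_len(ntheta)
    verts[idx, ] <- cbind(rings[i, 1L] * cos(theta),
                          rings[i, 1L] * sin(theta),
                          rings[i, 2L])
  }
  ring_idx <- function(i) 2L + (i - 1L) * ntheta + seq_len(ntheta)
  nxt <- c(seq_len(ntheta)[-1L], 1L)
  faces <- vector("list", nr + 1L)
  r1 <- ring_idx(1L)
  faces[[1L]] <- cbind(1L, r1[nxt], r1)            # bottom fan
  if (nr > 1L) for (i in seq_len(nr - 1L)) {
    a <- ring_idx(i); b <- ring_idx(i + 1L)
    faces[[i + 1L]] <- rbind(cbind(a, a[nxt], b[nxt]),
                             cbind(a, b[nxt], b))
  }
  rn <- ring_idx(nr)
  faces[[nr + 1L]] <- cbind(rn, rn[nxt], 2L)       # top fan
  triangle_mesh(verts, do.call(rbind, faces), name = name)
}

# ---- shape definitions ------------------------------------------------------

# Default dimensions per shape (mm): bullet centred near Table-2-scale LV
# volumes, crescent near RV volumes.
default_dimensions <- function(shape) {
  switch(shape,
    bullet_lv = list(r = 23.5, L = 90),
    ellipsoid = list(a = 25, b = 25, c = 40),
    crescent_rv = list(outer = c(36, 27, 52), inner = c(21, 17, 40),
                       inner_offset = c(27, 0, 0)),
    stop("unknown shape: ", shape))
}

bullet_truth_cm3 <- function(r, L) (pi * r^2 * (L - r) + (2 / 3) * pi * r^3) / 1000

bullet_member <- function(p, r, L) {
  rho2 <- p[, 1L]^2 + p[, 2L]^2
  z <- p[, 3L]
  (z >= 0 & z <= L - r & rho2 <= r^2) |
    (z > L - r & rho2 + (z - (L - r))^2 <= r^2)
}

ellipsoid_member <- function(p, a, b, c) {
  (p[, 1L] / a)^2 + (p[, 2L] / b)^2 + (p[, 3L] / c)^2 <= 1
}

# Crescent RV: star-shaped region from centre cc; along each unit direction
# the support radius is the distance to the outer ellipsoid, shortened to
# the entry point of an offset inner ellipsoid when the ray meets it first
# (the concave "bite" that breaks bullet-like convexity).
crescent_params <- function(dims) {
  s <- dims$outer
  list(outer = s, inner = dims$inner, m = dims$inner_offset,
       cc = c(-0.3 * s[1L], 0, 0))
}

crescent_radius <- function(u, prm) {
  cc <- prm$cc; s <- prm$outer; si <- prm$inner; w <- cc - prm$m
  A <- (u[, 1L] / s[1L])^2 + (u[, 2L] / s[2L])^2 + (u[, 3L] / s[3L])^2
  B <- 2 * (cc[1L] * u[, 1L] / s[1L]^2 + cc[2L] * u[, 2L] / s[2L]^2 +
            cc[3L] * u[, 3L] / s[3L]^2)
  C <- sum((cc / s)^2) - 1                      # < 0: centre inside outer
  t_out <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  Ai <- (u[, 1L] / si[1L])^2 + (u[, 2L] / si[2L])^2 + (u[, 3L] / si[3L])^2
  Bi <- 2 * (w[1L] * u[, 1L] / si[1L]^2 + w[2L] * u[, 2L] / si[2L]^2 +
             w[3L] * u[, 3L] / si[3L]^2)
  Ci <- sum((w / si)^2) - 1                     # > 0: centre outside inner
  disc <- Bi^2 - 4 * Ai * Ci
  hit <- disc > 0
  t1 <- rep(Inf, nrow(u))
  t1[hit] <- (-Bi[hit] - sqrt(disc[hit])) / (2 * Ai[hit])
  ifelse(hit & t1 > 0 & t1 < t_out, t1, t_out)
}

crescent_member <- function(p, prm) {
  u <- sweep(p, 2L, prm$cc)
  d <- sqrt(rowSums(u * u))
  ok <- d > 0
  res <- rep(TRUE, nrow(p))                     # centre point is inside
  if (any(ok)) {
    un <- u[ok, , drop = FALSE] / d[ok]
    res[ok] <- d[ok] <= crescent_radius(un, prm)
  }
  res
}

# Exact volume of a star-shaped region, V = (1/3) \oint R(u)^3 dOmega,
# by midpoint quadrature in (cos phi, theta).
star_volume_cm3 <- function(radius_fn, n_mu = 800L, n_theta = 1600L) {
  mu <- -1 + (2 * (seq_len(n_mu) - 0.5)) / n_mu
  th <- 2 * pi * (seq_len(n_theta) - 0.5) / n_theta
  sphi <- sqrt(pmax(0, 1 - mu^2))
  acc <- 0
  for (i in seq_len(n_mu)) {
    u <- cbind(sphi[i] * cos(th), sphi[i] * sin(th), mu[i])
    acc <- acc + sum(radius_fn(u)^3)
  }
  (acc / 3) * (2 / n_mu) * (2 * pi / n_theta) / 1000
}

# ---- phantom specification --------------------------------------------------

#' Synthetic ventricle phantom specification
#'
#' Parametric description of a synthetic chamber with known ground-truth
#' volume. Shapes: `bullet_lv` (cylinder of radius `r` capped by a
#' hemispherical apex and a flat base disk, total length `L`; closed-form
#' volume pi r^2 (L - r) + 2/3 pi r^3), `ellipsoid` (semi-axes `a, b, c`;
#' volume 4/3 pi a b c) and `crescent_rv` (outer ellipsoid with a concave
#' bite carved by an offset inner ellipsoid, emulating the irregular
#' non-bullet right ventricle; volume from an angular-quadrature oracle).
#'
#' The trabeculation field emulates the difference between a smoothed
#' contour that includes trabeculae and papillary muscles within the
#' luminal volume and an inner-blood-pool contour that excludes them: a
#' seeded band-limited radial field, clamped inward-only, shrinks the
#' smooth surface so the inner-blood-pool mesh volume is strictly smaller
#' whenever the amplitude is positive.
#'
#' @param shape `"bullet_lv"`, `"ellipsoid"` or `"crescent_rv"`.
#' @param dimensions named list of shape parameters in mm (see above);
#'   `NULL` uses shape defaults sized to adult ventricular volumes.
#' @param trabeculation list with `amplitude` (mm, >= 0), `frequency`
#'   (oscillations across the surface) and `seed`.
#' @param mesh_resolution target face count of the tessellation.
#' @param voxel_spacing isotropic voxel edge (mm) for the mask.
#' @return an object of class `phantom_spec`.
#' @seealso [make_phantom()], [make_cohort()]
#' @export
phantom_spec <- function(shape = c("bullet_lv", "ellipsoid", "crescent_rv"),
                         dimensions = NULL,
                         trabeculation = list(amplitude = 0, frequency = 6, seed = 1),
                         mesh_resolution = 5000,
                         voxel_spacing = 1) {
  shape <- match.arg(shape)
  dims <- default_dimensions(shape)
  if (!is.null(dimensions)) dims[names(dimensions)] <- dimensions
  tr <- list(amplitude = 0, frequency = 6, seed = 1)
  tr[names(trabeculation)] <- trabeculation
  if (!all(unlist(dims) > 0) && shape != "crescent_rv")
    stop("all dimensions must be strictly positive")
  if (shape == "bullet_lv" && dims$L <= dims$r)
    stop("bullet requires total length L > radius r")
  if (shape == "crescent_rv" &&
      (any(dims$outer <= 0) || any(dims$inner <= 0)))
    stop("crescent semi-axes must be strictly positive")
  if (tr$amplitude < 0) stop("trabeculation amplitude must be >= 0")
  if (mesh_resolution < 20) stop("mesh_resolution too small")
  if (voxel_spacing <= 0) stop("voxel_spacing must be > 0")
  structure(list(shape = shape, dimensions = dims, trabeculation = tr,
                 mesh_resolution = mesh_resolution,
                 voxel_spacing = voxel_spacing),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: %s\n", x$shape))
  cat("  dimensions (mm):", paste(names(unlist(x$dimensions)),
                                  signif(unlist(x$dimensions), 4),
                                  sep = "=", collapse = ", "), "\n")
  cat(sprintf("  trabeculation: amplitude %.2f mm, frequency %g, seed %d\n",
              x$trabeculation$amplitude, x$trabeculation$frequency,
              as.integer(x$trabeculation$seed)))
  cat(sprintf("  mesh resolution ~%d faces, voxel spacing %g mm\n",
              as.integer(x$mesh_resolution), x$voxel_spacing))
  invisible(x)
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

# Band-limited field on the unit sphere, mapped to [0, 1]: a fixed small
# set of seeded random plane waves evaluated at the directions.
trab_field <- function(dirs, frequency, seed, nwaves = 8L) {
  with_seed(seed, {
    dk <- matrix(stats::rnorm(3L * nwaves), nwaves, 3L)
    dk <- dk / sqrt(rowSums(dk * dk))
    ak <- stats::runif(nwaves, 0.5, 1)
    ph <- stats::runif(nwaves, 0, 2 * pi)
    g <- as.vector(cos(pi * frequency * (dirs %*% t(dk)) +
                       matrix(ph, nrow(dirs), nwaves, byrow = TRUE)) %*% ak)
    0.5 * (1 + g / sum(ak))
  })
}

star_center <- function(shape, dims) {
  switch(shape,
    bullet_lv = c(0, 0, dims$L / 2),
    ellipsoid = c(0, 0, 0),
    crescent_rv = crescent_params(dims)$cc)
}

smooth_phantom_mesh <- function(shape, dims, resolution) {
  if (shape == "bullet_lv") {
    r <- dims$r; L <- dims$L
    P <- r + (L - r) + pi * r / 2                 # profile length
    ntheta <- max(16L, round(sqrt(pi * r * resolution / P)))
    nrings <- max(6L, round(resolution / (2 * ntheta)))
    nr <- max(2L, round(nrings * r / P))
    na <- max(3L, round(nrings * (pi * r / 2) / P))
    nz <- max(2L, nrings - nr - na + 1L)
    prof <- rbind(
      cbind(r * seq(0, 1, length.out = nr + 1L), 0),            # base disk
      cbind(r, (L - r) * seq_len(nz) / nz),                     # side wall
      {                                                          # apex cap
        t <- (pi / 2) * seq_len(na) / na
        a <- cbind(r * cos(t), (L - r) + r * sin(t))
        a[na, ] <- c(0, L)                                       # exact pole
        a
      })
    revolve_mesh(prof, ntheta, name = "bullet_lv")
  } else {
    subdiv <- max(2L, ceiling(log(resolution / 20) / log(4)))
    ico <- icosphere_mesh(1, subdiv)
    if (shape == "ellipsoid") {
      v <- sweep(ico$vertices, 2L, c(dims$a, dims$b, dims$c), "*")
      triangle_mesh(v, ico$faces, name = "ellipsoid")
    } else {
      prm <- crescent_params(dims)
      R <- crescent_radius(ico$vertices, prm)
      v <- sweep(ico$vertices * R, 2L, prm$cc, "+")
      triangle_mesh(v, ico$faces, name = "crescent_rv")
    }
  }
}

voxelize_member <- function(member, lo, hi, spacing, pad = 2L) {
  origin <- lo - pad * spacing
  n <- pmax(1L, ceiling((hi - origin) / spacing) + pad)
  xs <- origin[1L] + (seq_len(n[1L]) - 0.5) * spacing
  ys <- origin[2L] + (seq_len(n[2L]) - 0.5) * spacing
  occ <- array(0L, n)
  xy <- cbind(rep(xs, times = n[2L]), rep(ys, each = n[1L]))
  for (k in seq_len(n[3L])) {
    zk <- origin[3L] + (k - 0.5) * spacing
    occ[, , k] <- as.integer(member(cbind(xy, zk)))
  }
  voxel_mask(occ, spacing = rep(spacing, 3L), origin = origin, slice_axis = 3L)
}

#' Generate a matched phantom pair (meshes, mask, ground truth)
#'
#' Builds, from a [phantom_spec()]: a smooth surface mesh tessellating the
#' analytic shape (emulating a smoothed contour that includes trabeculae
#' and papillary muscles); an inner-blood-pool mesh obtained by a seeded
#' inward-only radial perturbation of the smooth surface (strictly smaller
#' volume whenever the amplitude is positive, since every vertex moves
#' towards the star centre); the voxel-centre-inside discretisation of the
#' smooth surface; and the ground-truth volume (closed form for bullet and
#' ellipsoid, angular-quadrature oracle for the crescent).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_pair`: list with `spec`,
#'   `smooth_mesh`, `ibp_mesh`, `smooth_mask`, `truth_volume_cm3`.
#' @examples
#' p <- make_phantom(phantom_spec("bullet_lv", mesh_resolution = 1000,
#'                                voxel_spacing = 2))
#' p$truth_volume_cm3
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dimensions
  smooth <- smooth_phantom_mesh(spec$shape, dims, spec$mesh_resolution)
  c0 <- star_center(spec$shape, dims)

  ibp <- smooth
  if (spec$trabeculation$amplitude > 0) {
    u <- sweep(smooth$vertices, 2L, c0)
    d <- sqrt(rowSums(u * u))
    safe <- d > 0
    f <- numeric(nrow(u))
    f[safe] <- trab_field(u[safe, , drop = FALSE] / d[safe],
                          spec$trabeculation$frequency,
                          spec$trabeculation$seed)
    shrink <- spec$trabeculation$amplitude * f
    bound <- 0.9 * min(d[safe])
    if (any(shrink[safe] >= 0.9 * d[safe]))
      stop(sprintf(paste0("trabeculation amplitude %.2f mm would exceed 90%% of ",
                          "the minimum local radius (%.2f mm); surface would ",
                          "self-intersect"),
                   spec$trabeculation$amplitude, bound))
    vv <- smooth$vertices
    vv[safe, ] <- sweep(u[safe, , drop = FALSE] * (1 - shrink[safe] / d[safe]),
                        2L, c0, "+")
    ibp <- triangle_mesh(vv, smooth$faces, name = paste0(smooth$name, "_ibp"))
  }

  member <- switch(spec$shape,
    bullet_lv = function(p) bullet_member(p, dims$r, dims$L),
    ellipsoid = function(p) ellipsoid_member(p, dims$a, dims$b, dims$c),
    crescent_rv = {
      prm <- crescent_params(dims)
      function(p) crescent_member(p, prm)
    })
  box <- switch(spec$shape,
    bullet_lv = list(lo = c(-dims$r, -dims$r, 0), hi = c(dims$r, dims$r, dims$L)),
    ellipsoid = list(lo = -c(dims$a, dims$b, dims$c), hi = c(dims$a, dims$b, dims$c)),
    crescent_rv = list(lo = -dims$outer, hi = dims$outer))
  mask <- voxelize_member(member, box$lo, box$hi, spec$voxel_spacing)

  truth <- switch(spec$shape,
    bullet_lv = bullet_truth_cm3(dims$r, dims$L),
    ellipsoid = (4 / 3) * pi * dims$a * dims$b * dims$c / 1000,
    crescent_rv = {
      prm <- crescent_params(dims)
      star_volume_cm3(function(u) crescent_radius(u, prm))
    })

  structure(list(spec = spec, smooth_mesh = smooth, ibp_mesh = ibp,
                 smooth_mask = mask, truth_volume_cm3 = truth),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("Phantom pair (%s): truth %.2f cm^3\n",
              x$spec$shape, x$truth_volume_cm3))
  cat(sprintf("  smooth mesh %d faces; inner-blood-pool mesh %d faces; mask %s voxels\n",
              nrow(x$smooth_mesh$faces), nrow(x$ibp_mesh$faces),
              paste(dim(x$smooth_mask$occupancy), collapse = "x")))
  invisible(x)
}

#' Export a phantom pair to files
#'
#' Writes both meshes as STL, the mask as NIfTI, and a JSON sidecar with
#' the specification and ground-truth volume.
#'
#' @param pair a [make_phantom()] result.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @param dialect STL dialect.
#' @return named character vector of paths, invisibly.
#' @export
export_phantom <- function(pair, dir, stem = pair$spec$shape,
                           dialect = c("binary", "ascii")) {
  stopifnot(inherits(pair, "phantom_pair"))
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    smooth_stl = file.path(dir, paste0(stem, "_smooth.stl")),
    ibp_stl = file.path(dir, paste0(stem, "_ibp.stl")),
    mask_nii = file.path(dir, paste0(stem, "_mask.nii.gz")),
    sidecar = file.path(dir, paste0(stem, ".json")))
  write_stl(pair$smooth_mesh, paths[["smooth_stl"]], dialect)
  write_stl(pair$ibp_mesh, paths[["ibp_stl"]], dialect)
  write_mask_nifti(pair$smooth_mask, paths[["mask_nii"]])
  jsonlite::write_json(
    list(spec = unclass(pair$spec), truth_volume_cm3 = pair$truth_volume_cm3),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# Default population models for cohort dimension draws.
default_population <- function(shape) {
  switch(shape,
    bullet_lv = list(r_mean = 23.5, r_sd = 2.2, L_mean = 90, L_sd = 7),
    ellipsoid = list(a_mean = 25, a_sd = 2, b_mean = 25, b_sd = 2,
                     c_mean = 40, c_sd = 3),
    crescent_rv = list(scale_mean = 1, scale_sd = 0.08))
}

draw_dimensions <- function(shape, pop) {
  base <- default_dimensions(shape)
  redraws <- 0L
  repeat {
    dims <- switch(shape,
      bullet_lv = list(r = stats::rnorm(1, pop$r_mean, pop$r_sd),
                       L = stats::rnorm(1, pop$L_mean, pop$L_sd)),
      ellipsoid = list(a = stats::rnorm(1, pop$a_mean, pop$a_sd),
                       b = stats::rnorm(1, pop$b_mean, pop$b_sd),
                       c = stats::rnorm(1, pop$c_mean, pop$c_sd)),
      crescent_rv = {
        s <- stats::rnorm(1, pop$scale_mean, pop$scale_sd)
        list(outer = base$outer * s, inner = base$inner * s,
             inner_offset = base$inner_offset * s)
      })
    ok <- switch(shape,
      bullet_lv = dims$r > 5 && dims$L > dims$r + 5,
      ellipsoid = all(unlist(dims) > 5),
      crescent_rv = all(dims$outer > 5))
    if (ok) return(list(dims = dims, redraws = redraws))
    redraws <- redraws + 1L
    if (redraws > 100L) stop("population parameters keep producing invalid dimensions")
  }
}

#' Generate a paired-measurement phantom cohort
#'
#' Emulates a three-method volumetry study on synthetic ventricles. Each
#' subject is a phantom with dimensions drawn from a population model;
#' three measurements are taken: `pdp` (Simpson's-rule slice summation on
#' the smooth mask, standing in for a clinical slice-based platform),
#' `vrps` (polygon summation on the smooth mesh — smoothed contour
#' including trabeculae/papillary muscles) and `vribp` (polygon summation
#' on the trabeculated inner-blood-pool mesh). Independent Gaussian
#' per-method noise and fixed per-method bias model measurement error.
#' Fully reproducible from `seed`.
#'
#' @param n number of subjects (>= 2).
#' @param seed integer RNG seed; drives dimension draws, per-subject
#'   trabeculation fields and measurement noise.
#' @param shape phantom shape for the cohort stratum.
#' @param population named list of population parameters (see
#'   `chambervol:::default_population`); `NULL` uses defaults sized so LV
#'   and RV strata volumes span the adult range (roughly 80-230 and
#'   80-255 cm^3).
#' @param trabeculation list with `amplitude_mean`, `amplitude_sd` (mm;
#'   per-subject amplitudes are drawn truncated at 0) and `frequency`.
#' @param method_noise per-method measurement noise SD in cm^3 (scalar or
#'   named vector for pdp/vrps/vribp).
#' @param method_bias per-method additive offset in cm^3.
#' @param mesh_resolution,voxel_spacing phantom discretisation settings.
#' @return a `data.frame` (class `phantom_cohort`) with columns
#'   `subject_id`, `shape`, `truth_cm3`, `pdp_cm3`, `vrps_cm3`,
#'   `vribp_cm3`; attributes record the full generating configuration.
#' @export
make_cohort <- function(n = 20, seed = 1, shape = c("bullet_lv", "ellipsoid",
                                                    "crescent_rv"),
                        population = NULL,
                        trabeculation = list(amplitude_mean = 2,
                                             amplitude_sd = 0.5,
                                             frequency = 6),
                        method_noise = 4.27, method_bias = 0,
                        mesh_resolution = 5000, voxel_spacing = 1) {
  shape <- match.arg(shape)
  if (n < 2) stop("need n >= 2 subjects")
  pop <- default_population(shape)
  if (!is.null(population)) pop[names(population)] <- population
  tr <- list(amplitude_mean = 2, amplitude_sd = 0.5, frequency = 6)
  tr[names(trabeculation)] <- trabeculation
  noise <- expand_method_vec(method_noise, "method_noise")
  bias <- expand_method_vec(method_bias, "method_bias")
  if (any(noise < 0)) stop("method_noise SDs must be >= 0")

  with_seed(seed, {
    draws <- lapply(seq_len(n), function(i) draw_dimensions(shape, pop))
    n_redraws <- sum(vapply(draws, `[[`, integer(1), "redraws"))
    amp <- pmax(0, stats::rnorm(n, tr$amplitude_mean, tr$amplitude_sd))
    trab_seeds <- sample.int(.Machine$integer.max - 1L, n)
    eps <- matrix(stats::rnorm(3L * n), n, 3L)   # drawn up-front: reproducible
    if (n_redraws > 0L)
      message(sprintf("redrew %d invalid dimension draw(s)", n_redraws))

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      spec <- phantom_spec(shape, dimensions = draws[[i]]$dims,
                           trabeculation = list(amplitude = amp[i],
                                                frequency = tr$frequency,
                                                seed = trab_seeds[i]),
                           mesh_resolution = mesh_resolution,
                           voxel_spacing = voxel_spacing)
      ph <- make_phantom(spec)
      rows[[i]] <- data.frame(
        subject_id = sprintf("S%02d", i),
        shape = shape,
        truth_cm3 = ph$truth_volume_cm3,
        pdp_cm3 = slice_volume(ph$smooth_mask)$volume_cm3 +
          bias[["pdp"]] + noise[["pdp"]] * eps[i, 1L],
        vrps_cm3 = mesh_volume(ph$smooth_mesh)$volume_cm3 +
          bias[["vrps"]] + noise[["vrps"]] * eps[i, 2L],
        vribp_cm3 = mesh_volume(ph$ibp_mesh)$volume_cm3 +
          bias[["vribp"]] + noise[["vribp"]] * eps[i, 3L])
    }
    out <- do.call(rbind, rows)
    attr(out, "config") <- list(n = n, seed = seed, shape = shape,
                                population = pop, trabeculation = tr,
                                method_noise = noise, method_bias = bias,
                                mesh_resolution = mesh_resolution,
                                voxel_spacing = voxel_spacing)
    class(out) <- c("phantom_cohort", "data.frame")
    out
  })
}

expand_method_vec <- function(x, what) {
  methods <- c("pdp", "vrps", "vribp")
  x <- unlist(x)
  if (length(x) == 1L && is.null(names(x))) x <- rep(x, 3L)
  if (is.null(names(x))) names(x) <- methods
  out <- c(pdp = 0, vrps = 0, vribp = 0)
  if (!all(names(x) %in% methods))
    stop(sprintf("'%s' names must be among pdp/vrps/vribp", what))
  out[names(x)] <- x
  out
}
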