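# Independent volume oracle: divergence theorem over the surface,
# V = sum_f A_f (c_f . n_f) / 3 with face centroid c_f and unit outward
# normal n_f. Shares no code path with the tetrahedron summation in the
# package (normals/areas/centroids only).
divergence_volume_mm3 <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  nvec <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # length = 2 * area
  centroid <- (p1 + p2 + p3) / 3
  sum(rowSums(centroid * nvec)) / 6   # (1/3) * centroid . (area * n_hat)
}

# Random closed, consistently oriented mesh: an icosphere deformed by a
# smooth random radial field (stays star-shaped, hence watertight with
# outward winding).
random_star_mesh <- function(radius = 10, subdivisions = 2, jitter = 0.3,
                             center = c(0, 0, 0)) {
  ico <- icosphere_mesh(1, subdivisions)
  u <- ico$vertices
  k <- matrix(rnorm(9), 3, 3)
  phase <- runif(3, 0, 2 * pi)
  field <- cos(u %*% k[, 1] * 2 + phase[1]) +
    cos(u %*% k[, 2] * 3 + phase[2]) +
    cos(u %*% k[, 3] * 4 + phase[3])
  r <- radius * (1 + jitter * as.vector(field) / 3)
  triangle_mesh(sweep(u * r, 2, center, "+"), ico$faces, name = "random_star")
}

# Brute-force Lin's concordance via the mean-squared-difference identity:
# rho_c = 1 - mean((x - y)^2) / (sx2 + sy2 + (mx - my)^2), n-denominator.
ccc_by_identity <- function(x, y) {
  n <- length(x)
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  1 - mean((x - y)^2) / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

local_tempfile <- function(ext) {
  path <- tempfile(fileext = ext)
  withr::defer(unlink(path), envir = parent.frame())
  path
}
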