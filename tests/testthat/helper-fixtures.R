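# Shared fixtures: meshes, random motions and the brute-force OBB oracle.

# unit cube as an indexed mesh (8 vertices, 12 faces)
make_cube_mesh <- function(edge = 1, origin = c(0, 0, 0), name = "cube") {
  V <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  colnames(V) <- NULL
  V <- sweep(V, 2, origin, `+`)
  F <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  triangle_mesh(V, F, name)
}

# a small irregular tetrahedron point set
tetra_points <- function() {
  rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 4))
}

# random proper rigid motion from the current RNG stream
random_rigid <- function(t_scale = 10) {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))[c(4, 1, 2, 3)]
  rigid_transform(quat_canonical(q), runif(3, -t_scale, t_scale))
}

# brute-force minimal-OBB volume over a 2-degree rotation grid:
# hemisphere of box z-axes (alpha, beta) x in-plane angle gamma in [0, 90)
obb_grid_oracle <- function(P, step = 2) {
  H <- P[convex_hull_3d(P)$vertices, , drop = FALSE]
  ext_dirs <- function(D) {
    pr <- D %*% t(H)
    cols <- lapply(seq_len(ncol(pr)), function(j) pr[, j])
    do.call(pmax, cols) - do.call(pmin, cols)
  }
  alpha <- seq(0, 360 - step, by = step) * pi / 180
  beta <- seq(0, 90, by = step) * pi / 180
  gam <- seq(0, 90 - step, by = step) * pi / 180
  ab <- expand.grid(a = alpha, b = beta)
  W <- cbind(cos(ab$a) * sin(ab$b), sin(ab$a) * sin(ab$b), cos(ab$b))
  Ew <- ext_dirs(W)
  E1 <- cbind(cos(ab$a) * cos(ab$b), sin(ab$a) * cos(ab$b), -sin(ab$b))
  E2 <- cbind(-sin(ab$a), cos(ab$a), 0)
  best <- Inf
  best_R <- NULL
  for (g in gam) {
    U1 <- cos(g) * E1 + sin(g) * E2
    U2 <- -sin(g) * E1 + cos(g) * E2
    vol <- Ew * ext_dirs(U1) * ext_dirs(U2)
    i <- which.min(vol)
    if (vol[i] < best) {
      best <- vol[i]
      best_R <- cbind(U1[i, ], U2[i, ], W[i, ])
    }
  }
  list(volume = best, R = best_R)
}

# center of the axis-aligned box of P in the frame of rotation R
obb_center_for_rotation <- function(P, R) {
  B <- P %*% R
  as.numeric(R %*% ((apply(B, 2, max) + apply(B, 2, min)) / 2))
}

# anisotropic seeded Gaussian cloud
gaussian_cloud <- function(seed, n = 60, scale = 5) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  matrix(rnorm(n * 3), n, 3) %*% A * scale
}

# all points inside the OBB within tol * diameter?
obb_contains_all <- function(ob, P, tol = 1e-7) {
  B <- sweep(P, 2, ob$center) %*% ob$axes
  slack <- sweep(abs(B), 2, ob$half_extents)
  max(slack) <= tol * fragdisp::mesh_diameter(P)
}

# minimal binary STL writer (for exercising the binary read path)
write_binary_stl <- function(mesh, path, truncate_bytes = 0) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "wb")
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(F))) {
    tri <- rbind(c(0, 0, 0), V[F[i, ], ])
    writeBin(as.numeric(t(tri)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  close(con)
  if (truncate_bytes > 0) {
    dat <- readBin(path, "raw", n = file.size(path) - truncate_bytes)
    writeBin(dat, path)
  }
  invisible(path)
}
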