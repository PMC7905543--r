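#' Convex hulls
#'
#' Small, dependency-free hull routines sized for fragment vertex clouds
#' (tens to a few thousand points). The 3D hull is an incremental
#' beneath-beyond construction; the 2D hull is Andrew's monotone chain.
#'
#' @name hulls
NULL

#' Rank of a centered point cloud
#'
#' @param points n x 3 matrix.
#' @param tol relative singular-value tolerance.
#' @return list with `rank` and singular values `d`.
#' @keywords internal
point_rank <- function(points, tol = 1e-9) {
  P <- sweep(as.matrix(points), 2, colMeans(points))
  d <- svd(P, nu = 0, nv = 0)$d
  r <- if (d[1] == 0) 0L else sum(d > tol * d[1])
  list(rank = r, d = d)
}

stop_degenerate <- function(rank) {
  what <- switch(as.character(rank),
                 "0" = "all points coincide (rank 0)",
                 "1" = "points are collinear (rank 1)",
                 "2" = "points are coplanar (rank 2)",
                 sprintf("rank %d", rank))
  stop(sprintf("degenerate point set: %s; a full 3D extent is required", what))
}

#' Incremental 3D convex hull
#'
#' @param points n x 3 numeric matrix, n >= 4, full rank.
#' @return list with `faces` (m x 3 index triples, outward-oriented),
#'   `normals` (m x 3 unit outward normals), `offsets` (m, so that
#'   `x . n <= offset` for all hull points), and `vertices` (indices of
#'   points on the hull).
#' @export
convex_hull_3d <- function(points) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < 4L) stop("convex hull in 3D needs at least 4 points")
  pr <- point_rank(P)
  if (pr$rank < 3L) stop_degenerate(pr$rank)
  diam <- mesh_diameter(P)
  eps <- 1e-10 * diam

  # --- initial simplex: spread-out extreme points
  i1 <- which.min(P[, 1])
  d1 <- rowSums(sweep(P, 2, P[i1, ])^2)
  i2 <- which.max(d1)
  e1 <- P[i2, ] - P[i1, ]
  # farthest from line (i1, i2)
  rel <- sweep(P, 2, P[i1, ])
  cr <- cbind(rel[, 2] * e1[3] - rel[, 3] * e1[2],
              rel[, 3] * e1[1] - rel[, 1] * e1[3],
              rel[, 1] * e1[2] - rel[, 2] * e1[1])
  i3 <- which.max(rowSums(cr^2))
  nrm0 <- cross3(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  h <- abs(rel %*% nrm0)
  i4 <- which.max(h)
  if (h[i4] <= eps * sqrt(sum(nrm0^2))) stop_degenerate(2L)

  simplex <- c(i1, i2, i3, i4)
  interior <- colMeans(P[simplex, ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, function(f) orient_face(f, P, interior)))
  geom <- face_geometry(faces, P)

  rest <- setdiff(seq_len(n), simplex)
  for (p in rest) {
    vis <- which(geom$normals %*% P[p, ] - geom$offsets > eps)
    if (length(vis) == 0L) next
    horizon <- horizon_edges(faces, vis)
    if (nrow(horizon) == 0L) next  # numerically flat; skip
    keep <- faces[-vis, , drop = FALSE]
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1, function(f) orient_face(f, P, interior)))
    faces <- rbind(keep, newf)
    geom <- face_geometry(faces, P)
  }
  list(faces = faces, normals = geom$normals, offsets = as.numeric(geom$offsets),
       vertices = sort(unique(as.integer(faces))))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# orient triple so its normal points away from `interior`
orient_face <- function(f, P, interior) {
  nrm <- cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
  if (sum(nrm * (interior - P[f[1], ])) > 0) f[c(1, 3, 2)] else f
}

face_geometry <- function(faces, P) {
  A <- P[faces[, 1], , drop = FALSE]
  B <- P[faces[, 2], , drop = FALSE]
  C <- P[faces[, 3], , drop = FALSE]
  u <- B - A; v <- C - A
  N <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N <- N / len
  list(normals = N, offsets = rowSums(N * A))
}

# boundary edges of the visible face set, directed as in the visible faces
horizon_edges <- function(faces, vis) {
  vf <- faces[vis, , drop = FALSE]
  ed <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  ed[cnt[key] == 1L, , drop = FALSE]
}

#' 2D convex hull (Andrew's monotone chain)
#' @param pts n x 2 matrix.
#' @return indices of hull points in counter-clockwise order.
#' @export
convex_hull_2d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) return(seq_len(n))
  ord <- order(pts[, 1], pts[, 2])
  cross2 <- function(o, a, b) {
    (pts[a, 1] - pts[o, 1]) * (pts[b, 2] - pts[o, 2]) -
      (pts[a, 2] - pts[o, 2]) * (pts[b, 1] - pts[o, 1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2L && cross2(h[length(h) - 1L], h[length(h)], i) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(ord)
  upper <- build(rev(ord))
  c(lower[-length(lower)], upper[-length(upper)])
}

#' Minimum-area enclosing rectangle of a 2D point set
#'
#' Rotating-calipers over hull edge directions: the minimal rectangle has a
#' side collinear with a hull edge.
#'
#' @param pts n x 2 matrix.
#' @return list with `area`, `angle` (radians, direction of the rectangle's
#'   first side), `extents` (2), `center` (2).
#' @export
min_area_rect <- function(pts) {
  pts <- as.matrix(pts)
  h <- convex_hull_2d(pts)
  H <- pts[h, , drop = FALSE]
  m <- nrow(H)
  if (m < 3L) {
    # degenerate in-plane spread: fall back to axis-aligned
    rng <- apply(pts, 2, range)
    ext <- rng[2, ] - rng[1, ]
    return(list(area = prod(ext), angle = 0, extents = ext,
                center = colMeans(rng)))
  }
  best <- NULL
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- H[j, ] - H[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-14) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- H %*% u
    pv <- H %*% v
    ext <- c(max(pu) - min(pu), max(pv) - min(pv))
    area <- prod(ext)
    if (is.null(best) || area < best$area) {
      ctr_uv <- c((max(pu) + min(pu)) / 2, (max(pv) + min(pv)) / 2)
      best <- list(area = area, angle = atan2(u[2], u[1]), extents = ext,
                   center = ctr_uv[1] * u + ctr_uv[2] * v)
    }
  }
  best
}
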