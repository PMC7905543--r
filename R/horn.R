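#' Horn's closed-form absolute orientation
#'
#' Least-squares rigid registration of two index-wise corresponding point
#' sets: the optimal rotation is the eigenvector belonging to the largest
#' eigenvalue of the symmetric 4x4 quaternion matrix built from the
#' cross-covariance of the centered sets; the translation follows from the
#' centroids. Unit weights throughout.
#'
#' @param P n x 3 matrix of source points (n >= 3, rank >= 2).
#' @param Q n x 3 matrix of target points, row i corresponding to row i of P.
#' @return object of class `registration_result`: `transform`
#'   (`rigid_transform` minimizing `sum ||R p_i + t - q_i||^2`) and
#'   `rms_residual` (mm).
#' @export
horn_register <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) {
    stop(sprintf("point set size mismatch: %d x %d vs %d x %d",
                 nrow(P), ncol(P), nrow(Q), ncol(Q)))
  }
  if (ncol(P) != 3L) stop("points must be n x 3")
  if (nrow(P) < 3L) stop("registration needs at least 3 corresponding points")
  pr <- point_rank(P)
  if (pr$rank < 2L) {
    stop(sprintf("ambiguous registration: source points have rank %d (< 2); the rotation about the point/line is undetermined",
                 pr$rank))
  }
  pbar <- colMeans(P); qbar <- colMeans(Q)
  X <- sweep(P, 2, pbar); Y <- sweep(Q, 2, qbar)
  S <- crossprod(X, Y)  # sum x_i y_i^T
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  eig <- eigen(N, symmetric = TRUE)
  q <- quat_canonical(eig$vectors[, 1])
  q <- q / sqrt(sum(q^2))
  R <- quat_to_matrix(q)
  t <- qbar - as.numeric(R %*% pbar)
  resid <- sweep(P %*% t(R), 2, t, `+`) - Q
  rms <- sqrt(mean(rowSums(resid^2)))
  structure(list(transform = rigid_transform(q, t), rms_residual = rms),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n")
  print(x$transform)
  cat(sprintf("  rms residual (mm): %.6g\n", x$rms_residual))
  invisible(x)
}
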