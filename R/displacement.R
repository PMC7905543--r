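#' Fragment displacement measure (TFS / TFA)
#'
#' The displacement of a fragment between two rigid poses is summarized by
#' two independent parameters: the transformation shift (TFS), the length in
#' mm of the displacement vector of the fragment center (center of the
#' minimal-volume oriented bounding box), and the transformation angle
#' (TFA), the rotation angle in degrees of the relative rigid motion,
#' recovered from the posed vertex sets by Horn's quaternion registration.
#'
#' @name displacement
NULL

#' Measure fragment displacement between two poses
#'
#' The relative motion `M = pose2 o pose1^-1` is recovered by registering
#' the vertex set posed by `pose1` onto the vertex set posed by `pose2`
#' (Horn). The fragment center `c1` is the OBB center in pose 1; its image
#' `c2 = M(c1)` defines `tfs = ||c2 - c1||`, and `tfa` is the rotation angle
#' of `M`. Mapping `c1` through `M` (rather than recomputing the OBB in
#' pose 2) makes TFS exactly invariant to OBB tie-breaking; with
#' `check_center = TRUE` the OBB is recomputed in pose 2 as a diagnostic and
#' a warning is raised if the two centers disagree.
#'
#' @param mesh `triangle_mesh` of the fragment (non-degenerate).
#' @param pose1 `rigid_transform`, pre-displacement pose.
#' @param pose2 `rigid_transform`, post-displacement pose.
#' @param center optional precomputed OBB center of `mesh` in its own frame
#'   (numeric(3)); avoids recomputing the OBB in batch pipelines.
#' @param check_center if `TRUE`, recompute the OBB center in pose 2 and
#'   warn if it differs from the mapped center by more than
#'   `1e-6 * diameter`.
#' @return object of class `displacement_result`: `tfs` (mm), `tfa`
#'   (degrees, in `[0, 180]`), `fragment_id`, `rms_residual` (mm,
#'   registration quality).
#' @export
measure_displacement <- function(mesh, pose1, pose2, center = NULL,
                                 check_center = FALSE) {
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  V1 <- rt_apply(pose1, mesh$vertices)
  V2 <- rt_apply(pose2, mesh$vertices)
  displacement_between(V1, V2, mesh$name,
                       center1 = if (is.null(center)) NULL else rt_apply(pose1, center),
                       check_center = check_center)
}

#' Displacement between two posed copies of the same fragment
#'
#' Low-level entry taking the two posed vertex sets directly (vertex order
#' is the correspondence). A rigidity check — preservation of pairwise
#' distances to within `1e-6 * diameter` — guards against vertex sets that
#' do not belong to one rigidly moved fragment.
#'
#' @param V1,V2 n x 3 matrices of corresponding posed vertices.
#' @param fragment_id identifier carried into the result.
#' @param center1 optional fragment center in pose 1 (numeric(3)); computed
#'   from the OBB of `V1` when `NULL`.
#' @param check_center see [measure_displacement()].
#' @return `displacement_result`.
#' @export
displacement_between <- function(V1, V2, fragment_id = "", center1 = NULL,
                                 check_center = FALSE) {
  V1 <- as.matrix(V1); V2 <- as.matrix(V2)
  if (!all(dim(V1) == dim(V2))) stop("posed vertex sets differ in size")
  check_rigid_pair(V1, V2)
  reg <- horn_register(V1, V2)
  M <- reg$transform
  c1 <- if (is.null(center1)) compute_obb(V1)$center else as.numeric(center1)
  c2 <- rt_apply(M, c1)
  if (check_center) {
    c2_direct <- compute_obb(V2)$center
    if (sqrt(sum((c2 - c2_direct)^2)) > 1e-6 * mesh_diameter(V1)) {
      warning("mapped center and recomputed pose-2 OBB center disagree beyond 1e-6 * diameter")
    }
  }
  structure(list(tfs = sqrt(sum((c2 - c1)^2)),
                 tfa = rotation_angle(M$q),
                 fragment_id = fragment_id,
                 rms_residual = reg$rms_residual),
            class = "displacement_result")
}

# pairwise-distance preservation check; subsamples large meshes
check_rigid_pair <- function(V1, V2, tol_factor = 1e-6, max_points = 150L) {
  n <- nrow(V1)
  idx <- if (n > max_points) round(seq(1L, n, length.out = max_points)) else seq_len(n)
  d1 <- stats::dist(V1[idx, , drop = FALSE])
  d2 <- stats::dist(V2[idx, , drop = FALSE])
  diam <- mesh_diameter(V1)
  if (max(abs(d1 - d2)) > tol_factor * diam) {
    stop(sprintf("non-rigid input: pairwise distances differ by up to %.3g mm (tolerance %.3g); the two vertex sets are not one rigidly moved fragment",
                 max(abs(d1 - d2)), tol_factor * diam))
  }
  invisible(TRUE)
}

#' @export
print.displacement_result <- function(x, ...) {
  cat(sprintf("<displacement '%s': TFS %.4f mm, TFA %.4f deg (rms %.3g mm)>\n",
              x$fragment_id, x$tfs, x$tfa, x$rms_residual))
  invisible(x)
}

#' Deviation of a rater's reduction from the gold standard
#'
#' Displacement of the fragment from its gold-standard (senior surgeon)
#' reduced pose to the rater's reduced pose.
#'
#' @param mesh `triangle_mesh` of the fragment.
#' @param pose_rater rater's final pose (`rigid_transform`).
#' @param pose_gold gold-standard final pose (`rigid_transform`).
#' @param center optional precomputed OBB center of `mesh` in its own frame.
#' @return `displacement_result`.
#' @export
deviation_from_gold <- function(mesh, pose_rater, pose_gold, center = NULL) {
  measure_displacement(mesh, pose_gold, pose_rater, center = center)
}
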