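#' Synthetic fracture cases and rater plans
#'
#' Generates multi-fragment distal-radius-like cases (convex polytope
#' fragments cut from a cylinder-like metaphysis solid by random planes)
#' and rater-specific reduction plans whose expected deviation from the
#' gold standard decreases linearly with years of experience. Everything is
#' deterministic for a fixed seed, so the full pipeline can be exercised
#' and slope recovery demonstrated without clinical data.
#'
#' @name synthetic-study
NULL

#' Packaged case demographics table
#'
#' Twenty distal radius fracture cases with age, sex, side, AO/OTA class,
#' total fragment count and the number of intra-articular fragments that
#' enter the statistics.
#'
#' @return data.frame with one row per case.
#' @export
table1_fixture <- function() {
  utils::read.csv(system.file("extdata", "table1_demographics.csv",
                              package = "fragdisp", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Packaged rater panel
#'
#' Nine raters: one senior surgeon (SS, the gold standard), two biomedical
#' engineers (BE, no clinical years), three senior and three junior
#' orthopedic residents, with clinical and 3D-planning experience in years.
#'
#' @return `rater_table` data.frame.
#' @export
table2_fixture <- function() {
  read_rater_table(system.file("extdata", "table2_raters.csv",
                               package = "fragdisp", mustWork = TRUE))
}

#' Number of fragments included in the statistics
#' @param table1 demographics table (see [table1_fixture()]).
#' @return integer sum of the included-fragment column.
#' @export
count_included_fragments <- function(table1) {
  if (!"included_fragments" %in% names(table1)) {
    stop("schema error: demographics table lacks column 'included_fragments'")
  }
  sum(table1$included_fragments)
}

#' Mean fragments per case
#' @param table1 demographics table.
#' @param which `"total"` or `"included"` fragment column.
#' @return arithmetic mean.
#' @export
mean_fragments <- function(table1, which = c("total", "included")) {
  which <- match.arg(which)
  col <- paste0(which, "_fragments")
  if (!col %in% names(table1)) {
    stop(sprintf("schema error: demographics table lacks column '%s'", col))
  }
  mean(table1[[col]])
}

#' Empirical fragment-count distribution of the packaged cases
#' @return named numeric vector: probability of 1..6 included fragments.
#' @keywords internal
fragment_count_probs <- function() {
  cnt <- tabulate(table1_fixture()$included_fragments, nbins = 6)
  stats::setNames(cnt / sum(cnt), 1:6)
}

#' Rater error model
#'
#' Expected per-fragment deviation magnitudes decrease linearly with
#' experience. The slope parameters are defined as the *expected univariate
#' regression slopes over the rater panel* — the quantities the study
#' pipeline estimates — not as raw additive coefficients: because planning
#' and clinical experience are correlated across a panel, the generator
#' solves, at construction, the 2x2 linear system for the additive
#' coefficients `(a_planning, a_clinical)` whose induced univariate OLS
#' slopes over the given panel equal the requested slopes. Deviation
#' magnitudes are drawn as folded normals `|N(mu, sd)|` (non-negative with
#' tunable spread), with
#' `mu = max(0, baseline - a_planning * py - a_clinical * cy)` and a
#' missing clinical value contributing zero.
#'
#' @param tfs_baseline expected TFS (mm) of a rater with no experience.
#' @param tfs_slope_planning,tfs_slope_clinical expected univariate TFS
#'   improvement, mm per year of 3D-planning / clinical experience.
#' @param tfa_baseline expected TFA (degrees) at zero experience.
#' @param tfa_slope_planning,tfa_slope_clinical expected univariate TFA
#'   improvement, degrees per year.
#' @param noise_sd_tfs,noise_sd_tfa folded-normal spread, mm / degrees.
#' @param panel `rater_table` used to calibrate the additive coefficients
#'   (gold-standard SS excluded); defaults to [table2_fixture()].
#' @param seed integer seed stored with the model (used by
#'   [simulate_study()]).
#' @return object of class `rater_error_model`.
#' @export
rater_error_model <- function(tfs_baseline = 6, tfs_slope_planning = 0.943,
                              tfs_slope_clinical = 0.560,
                              tfa_baseline = 14, tfa_slope_planning = 2.472,
                              tfa_slope_clinical = 1.394,
                              noise_sd_tfs = 0.8, noise_sd_tfa = 2.0,
                              panel = table2_fixture(), seed = 1L) {
  stopifnot(noise_sd_tfs >= 0, noise_sd_tfa >= 0,
            tfs_baseline >= 0, tfa_baseline >= 0)
  coef_tfs <- calibrate_slopes(tfs_slope_planning, tfs_slope_clinical, panel)
  coef_tfa <- calibrate_slopes(tfa_slope_planning, tfa_slope_clinical, panel)
  structure(list(tfs_baseline = tfs_baseline,
                 tfs_slope_planning = tfs_slope_planning,
                 tfs_slope_clinical = tfs_slope_clinical,
                 tfa_baseline = tfa_baseline,
                 tfa_slope_planning = tfa_slope_planning,
                 tfa_slope_clinical = tfa_slope_clinical,
                 noise_sd_tfs = noise_sd_tfs, noise_sd_tfa = noise_sd_tfa,
                 coef_tfs = coef_tfs, coef_tfa = coef_tfa,
                 seed = as.integer(seed)),
            class = "rater_error_model")
}

# additive coefficients whose induced univariate OLS slopes over the
# non-gold panel equal (slope_planning, slope_clinical)
calibrate_slopes <- function(slope_planning, slope_clinical, panel) {
  p <- panel[panel$profession != "SS", , drop = FALSE]
  py <- p$planning_years
  cy_eff <- ifelse(is.na(p$clinical_years), 0, p$clinical_years)
  S <- !is.na(p$clinical_years)
  fallback <- c(planning = slope_planning, clinical = slope_clinical)
  if (nrow(p) < 3L || sum(S) < 3L ||
      stats::var(py) <= 0 || stats::var(p$clinical_years[S]) <= 0) {
    return(fallback)
  }
  b1 <- stats::cov(cy_eff, py) / stats::var(py)          # cy on py, all raters
  b2 <- stats::cov(py[S], p$clinical_years[S]) /
    stats::var(p$clinical_years[S])                      # py on cy, raters with cy
  A <- matrix(c(1, b1, b2, 1), 2, 2, byrow = TRUE)
  if (abs(det(A)) < 1e-10) return(fallback)
  a <- solve(A, c(slope_planning, slope_clinical))
  c(planning = a[1], clinical = a[2])
}

#' Expected deviation magnitudes for one rater under a model
#' @param model `rater_error_model`.
#' @param profile one-row rater profile (list or data.frame row with
#'   `planning_years`, `clinical_years`).
#' @return list with `mu_tfs` (mm) and `mu_tfa` (degrees), truncated at 0.
#' @export
expected_deviation <- function(model, profile) {
  py <- profile$planning_years
  cy <- if (is.na(profile$clinical_years)) 0 else profile$clinical_years
  list(mu_tfs = max(0, model$tfs_baseline -
                      model$coef_tfs[["planning"]] * py -
                      model$coef_tfs[["clinical"]] * cy),
       mu_tfa = max(0, model$tfa_baseline -
                      model$coef_tfa[["planning"]] * py -
                      model$coef_tfa[["clinical"]] * cy))
}

## ---- convex polytope machinery (halfspace form A x <= b) -------------------

polytope_vertices <- function(A, b, tol = 1e-7) {
  m <- nrow(A)
  combs <- utils::combn(m, 3)
  V <- list()
  for (k in seq_len(ncol(combs))) {
    i <- combs[, k]
    M <- A[i, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- solve(M, b[i])
    if (all(A %*% x <= b + tol)) V[[length(V) + 1L]] <- x
  }
  if (length(V) == 0L) return(matrix(numeric(0), 0, 3))
  V <- do.call(rbind, V)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}

# triangle mesh of a polytope from its halfspace faces
polytope_mesh <- function(A, b, V, name = "", tol = 1e-6) {
  tris <- list()
  for (i in seq_len(nrow(A))) {
    on <- which(abs(V %*% A[i, ] - b[i]) < tol * max(1, abs(b[i])))
    if (length(on) < 3L) next
    Fv <- V[on, , drop = FALSE]
    ctr <- colMeans(Fv)
    bas <- orth_basis(A[i, ] / sqrt(sum(A[i, ]^2)))
    ang <- atan2((Fv - rep(ctr, each = nrow(Fv))) %*% bas$e2,
                 (Fv - rep(ctr, each = nrow(Fv))) %*% bas$e1)
    ordv <- on[order(ang)]
    for (j in seq_len(length(ordv) - 2L)) {
      tris[[length(tris) + 1L]] <- c(ordv[1], ordv[j + 1L], ordv[j + 2L])
    }
  }
  F <- do.call(rbind, tris)
  # orient all faces outward (positive signed volume contribution per face
  # is not guaranteed by construction; fix by centroid test)
  ctr <- colMeans(V)
  for (k in seq_len(nrow(F))) {
    a <- V[F[k, 1], ]; bb <- V[F[k, 2], ]; cc <- V[F[k, 3], ]
    if (sum(cross3(bb - a, cc - a) * (colMeans(rbind(a, bb, cc)) - ctr)) < 0) {
      F[k, ] <- F[k, c(1, 3, 2)]
    }
  }
  triangle_mesh(V, F, name)
}

mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
        a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
        a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

polytope_volume <- function(A, b, V) {
  if (nrow(V) < 4L) return(0)
  abs(mesh_volume(polytope_mesh(A, b, V)))
}

## ---- case generation -------------------------------------------------------

#' Generate a synthetic multi-fragment case
#'
#' A 12-sided prism (radius 12 mm, length 40 mm — a metaphysis-like convex
#' solid) is split by `n_fragments - 1` random planes into convex polytope
#' fragments. Gold-standard poses are the identity (fragments are generated
#' in reduced position); initial poses displace each fragment by a random
#' rigid motion (translation 2-15 mm, rotation 5-45 degrees).
#'
#' @param seed integer; the case is a pure function of `(seed, n_fragments)`.
#' @param n_fragments number of fragments, 1 to 6.
#' @param case_id identifier (default `"case<seed>"`).
#' @return object of class `synthetic_case`: `case_id`, `meshes` (named
#'   list of `triangle_mesh`), `gold_poses`, `initial_poses` (named lists of
#'   `rigid_transform`), `centers` (named list of OBB centers at gold pose).
#' @export
generate_case <- function(seed, n_fragments, case_id = paste0("case", seed)) {
  if (!is.numeric(n_fragments) || n_fragments < 1 || n_fragments > 6) {
    stop("n_fragments must be between 1 and 6")
  }
  n_fragments <- as.integer(n_fragments)
  with_seed(seed, {
    ang <- (seq_len(12) - 0.5) * pi / 6
    A <- rbind(cbind(cos(ang), sin(ang), 0), c(0, 0, 1), c(0, 0, -1))
    b <- c(rep(12, 12), 20, 20)
    pieces <- list(list(A = A, b = b, V = polytope_vertices(A, b)))
    vols <- polytope_volume(A, b, pieces[[1]]$V)
    while (length(pieces) < n_fragments) {
      tgt <- which.max(vols)
      pc <- pieces[[tgt]]
      done <- FALSE
      for (try in 1:50) {
        ctr <- colMeans(pc$V)
        spread <- apply(pc$V, 2, function(x) diff(range(x)))
        pt <- ctr + stats::runif(3, -0.25, 0.25) * spread
        nrm <- random_direction()
        d <- sum(nrm * pt)
        A1 <- rbind(pc$A, nrm); b1 <- c(pc$b, d)
        A2 <- rbind(pc$A, -nrm); b2 <- c(pc$b, -d)
        V1 <- polytope_vertices(A1, b1)
        V2 <- polytope_vertices(A2, b2)
        if (nrow(V1) < 4L || nrow(V2) < 4L) next
        if (point_rank(V1)$rank < 3L || point_rank(V2)$rank < 3L) next
        v1 <- polytope_volume(A1, b1, V1)
        v2 <- polytope_volume(A2, b2, V2)
        if (min(v1, v2) < 0.08 * vols[tgt]) next
        pieces[[tgt]] <- list(A = A1, b = b1, V = V1)
        pieces[[length(pieces) + 1L]] <- list(A = A2, b = b2, V = V2)
        vols[tgt] <- v1
        vols[length(pieces)] <- v2
        done <- TRUE
        break
      }
      if (!done) stop("failed to split the solid into the requested number of fragments")
    }
    meshes <- list(); gold <- list(); init <- list(); centers <- list()
    for (i in seq_along(pieces)) {
      fid <- paste0("f", i)
      m <- polytope_mesh(pieces[[i]]$A, pieces[[i]]$b, pieces[[i]]$V,
                         name = paste(case_id, fid, sep = "/"))
      meshes[[fid]] <- m
      gold[[fid]] <- rigid_transform()
      ctr <- obb_center(m)
      centers[[fid]] <- ctr
      q <- quat_from_axis_angle(random_direction(), stats::runif(1, 5, 45))
      shift <- stats::runif(1, 2, 15) * random_direction()
      rot_about_ctr <- rigid_transform(q, ctr - as.numeric(quat_to_matrix(q) %*% ctr))
      init[[fid]] <- rt_compose(rigid_transform(c(1, 0, 0, 0), shift), rot_about_ctr)
    }
    structure(list(case_id = case_id, meshes = meshes, gold_poses = gold,
                   initial_poses = init, centers = centers),
              class = "synthetic_case")
  })
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case '%s': %d fragment(s)>\n", x$case_id, length(x$meshes)))
  invisible(x)
}

# evaluate expr with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulate one rater's reduction plan for a case
#'
#' Each fragment's gold pose is perturbed by a rotation of folded-normal
#' magnitude about a uniform random axis through the fragment center,
#' followed by a translation of folded-normal magnitude in a uniform random
#' direction. Rotating about the center keeps the simulated TFS equal to
#' the translation magnitude, so TFS and TFA stay independently
#' controllable.
#'
#' @param case `synthetic_case`.
#' @param profile one-row rater profile (`planning_years`,
#'   `clinical_years`).
#' @param model `rater_error_model`.
#' @param seed optional integer; when given, the plan is a pure function of
#'   `(case, profile, model, seed)`; when `NULL`, draws come from the
#'   current RNG stream (as inside [simulate_study()]).
#' @return named list of `rigid_transform` poses, one per fragment.
#' @export
simulate_rater_plan <- function(case, profile, model, seed = NULL) {
  run <- function() {
    mu <- expected_deviation(model, profile)
    poses <- list()
    for (fid in names(case$meshes)) {
      tfs_mag <- abs(stats::rnorm(1, mu$mu_tfs, model$noise_sd_tfs))
      tfa_mag <- min(abs(stats::rnorm(1, mu$mu_tfa, model$noise_sd_tfa)), 179.9)
      ctr <- rt_apply(case$gold_poses[[fid]], case$centers[[fid]])
      q <- quat_from_axis_angle(random_direction(), tfa_mag)
      rot <- rigid_transform(q, ctr - as.numeric(quat_to_matrix(q) %*% ctr))
      shift <- rigid_transform(c(1, 0, 0, 0), tfs_mag * random_direction())
      poses[[fid]] <- rt_compose(shift, rt_compose(rot, case$gold_poses[[fid]]))
    }
    poses
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a complete inter-rater study
#'
#' Generates `n_cases` synthetic cases (fragment counts drawn from the
#' packaged demographics distribution unless given), assigns the
#' gold-standard rater its own gold poses, and simulates every other
#' rater's plan under the error model.
#'
#' @param model `rater_error_model`; its `seed` drives all randomness.
#' @param raters `rater_table` (default [table2_fixture()]).
#' @param n_cases number of cases (default 20).
#' @param fragment_counts optional integer vector of length `n_cases`
#'   (values 1-6); drawn from [fragment_count_probs()] when `NULL`.
#' @return list of class `synthetic_study`: `cases` (named list),
#'   `plans` (`plan_table` with a `pose` list column), `raters`, `model`.
#' @export
simulate_study <- function(model, raters = table2_fixture(), n_cases = 20,
                           fragment_counts = NULL) {
  raters <- rater_table(as.data.frame(raters))
  gold <- raters$rater_id[raters$profession == "SS"]
  with_seed(model$seed, {
    if (is.null(fragment_counts)) {
      pr <- fragment_count_probs()
      fragment_counts <- sample(1:6, n_cases, replace = TRUE, prob = pr)
    }
    stopifnot(length(fragment_counts) == n_cases,
              all(fragment_counts >= 1 & fragment_counts <= 6))
    case_seeds <- sample.int(2147483646L, n_cases)
    cases <- list()
    rid <- character(0); cid_col <- character(0); fid_col <- character(0)
    poses <- list()
    for (ci in seq_len(n_cases)) {
      cid <- sprintf("case%02d", ci)
      cs <- generate_case(case_seeds[ci], fragment_counts[ci], case_id = cid)
      cases[[cid]] <- cs
      for (fid in names(cs$meshes)) {
        rid <- c(rid, gold); cid_col <- c(cid_col, cid); fid_col <- c(fid_col, fid)
        poses[[length(poses) + 1L]] <- cs$gold_poses[[fid]]
      }
      for (ri in seq_len(nrow(raters))) {
        if (raters$rater_id[ri] == gold) next
        plan <- simulate_rater_plan(cs, raters[ri, ], model)
        for (fid in names(plan)) {
          rid <- c(rid, raters$rater_id[ri]); cid_col <- c(cid_col, cid)
          fid_col <- c(fid_col, fid)
          poses[[length(poses) + 1L]] <- plan[[fid]]
        }
      }
    }
    df <- data.frame(rater_id = rid, case_id = cid_col, fragment_id = fid_col,
                     stringsAsFactors = FALSE)
    df$pose <- poses
    meshes <- list()
    for (cs in cases) {
      for (fid in names(cs$meshes)) meshes[[mesh_key(cs$case_id, fid)]] <- cs$meshes[[fid]]
    }
    structure(list(cases = cases, plans = plan_table(df, gold),
                   meshes = meshes, raters = raters, model = model),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study: %d cases, %d fragments, %d raters (gold '%s')>\n",
              length(x$cases), length(x$meshes), nrow(x$raters),
              plan_gold(x$plans)))
  invisible(x)
}

#' Run the analysis pipeline on a simulated study
#'
#' Convenience wrapper: feeds a [simulate_study()] result through
#' [run_study()], reusing the generator's cached fragment centers.
#'
#' @param sim `synthetic_study`.
#' @param alpha significance level (default 0.05).
#' @return `study_result`.
#' @export
analyze_simulated_study <- function(sim, alpha = 0.05) {
  plans <- sim$plans
  gold <- plan_gold(plans)
  cf_key <- paste(plans$case_id, plans$fragment_id, sep = "/")
  gold_pose <- stats::setNames(plans$pose[plans$rater_id == gold],
                               cf_key[plans$rater_id == gold])
  other <- which(plans$rater_id != gold)
  out <- vector("list", length(other))
  for (i in seq_along(other)) {
    row <- other[i]
    cs <- sim$cases[[plans$case_id[row]]]
    fid <- plans$fragment_id[row]
    dev <- deviation_from_gold(cs$meshes[[fid]], plans$pose[[row]],
                               gold_pose[[cf_key[row]]],
                               center = cs$centers[[fid]])
    out[[i]] <- data.frame(rater_id = plans$rater_id[row],
                           case_id = plans$case_id[row],
                           fragment_id = fid, tfs = dev$tfs, tfa = dev$tfa,
                           rms_residual = dev$rms_residual,
                           stringsAsFactors = FALSE)
  }
  analyze_deviations(do.call(rbind, out), sim$raters, gold, alpha = alpha)
}

#' Write a simulated study to a self-contained directory
#'
#' Meshes as ASCII STL, poses as JSON, plans and raters as CSV — a layout
#' consumable by [read_plan_table()] / [run_study()] and by the command
#' line interface.
#'
#' @param sim `synthetic_study`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study_dir <- function(sim, dir) {
  for (d in file.path(dir, c("meshes", "poses"))) {
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  for (key in names(sim$meshes)) {
    fn <- paste0(gsub("/", "_", key), ".stl")
    write_mesh_stl(sim$meshes[[key]], file.path(dir, "meshes", fn))
  }
  plans <- sim$plans
  pose_path <- character(nrow(plans))
  for (i in seq_len(nrow(plans))) {
    fn <- sprintf("poses/%s_%s_%s.json", plans$rater_id[i], plans$case_id[i],
                  plans$fragment_id[i])
    write_pose(plans$pose[[i]], file.path(dir, fn))
    pose_path[i] <- fn
  }
  out <- data.frame(rater_id = plans$rater_id, case_id = plans$case_id,
                    fragment_id = plans$fragment_id, pose_path = pose_path,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(dir, "plans.csv"), row.names = FALSE)
  rt <- as.data.frame(sim$raters)
  utils::write.csv(rt, file.path(dir, "raters.csv"), row.names = FALSE)
  mesh_map <- data.frame(case_id = sub("/.*", "", names(sim$meshes)),
                         fragment_id = sub(".*/", "", names(sim$meshes)),
                         mesh_path = paste0("meshes/", gsub("/", "_", names(sim$meshes)), ".stl"),
                         stringsAsFactors = FALSE)
  utils::write.csv(mesh_map, file.path(dir, "meshes.csv"), row.names = FALSE)
  invisible(dir)
}
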