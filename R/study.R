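#' Inter-rater study pipeline
#'
#' Per-fragment deviations from the gold-standard plan are averaged per
#' rater and case, then aggregated to a per-rater mean and standard
#' deviation (the rater's average performance and consistency). Profession
#' groups are compared by one-way ANOVA with Bonferroni-corrected pairwise
#' post hoc t tests; the two experience variables are analyzed by
#' univariate ordinary least squares.
#'
#' @name study-analysis
NULL

#' Average fragment deviations of one rater on one case
#'
#' @param deviations list of `displacement_result` for the fragments of one
#'   (rater, case) pair.
#' @param rater_id,case_id identifiers carried into the summary.
#' @return list of class `case_summary`: `rater_id`, `case_id`, `mean_tfs`
#'   (mm), `mean_tfa` (degrees), `n_fragments`.
#' @export
aggregate_case <- function(deviations, rater_id = "", case_id = "") {
  if (length(deviations) < 1L) stop("cannot summarize a case with no fragment deviations")
  tfs <- vapply(deviations, `[[`, numeric(1), "tfs")
  tfa <- vapply(deviations, `[[`, numeric(1), "tfa")
  structure(list(rater_id = rater_id, case_id = case_id,
                 mean_tfs = mean(tfs), mean_tfa = mean(tfa),
                 n_fragments = length(deviations)),
            class = "case_summary")
}

#' Aggregate case summaries of one rater
#'
#' @param case_summaries list of `case_summary` for one rater (>= 2 cases;
#'   the gold-standard rater is excluded upstream).
#' @param profession profession code carried into the summary.
#' @return list of class `rater_summary`: `rater_id`, `profession`,
#'   `mean_tfs`, `sd_tfs` (mm), `mean_tfa`, `sd_tfa` (degrees), `n_cases`.
#'   SDs use the n-1 denominator over case-level means.
#' @export
aggregate_rater <- function(case_summaries, profession = "") {
  if (length(case_summaries) < 2L) {
    stop("per-rater standard deviation needs at least 2 case summaries")
  }
  tfs <- vapply(case_summaries, `[[`, numeric(1), "mean_tfs")
  tfa <- vapply(case_summaries, `[[`, numeric(1), "mean_tfa")
  structure(list(rater_id = case_summaries[[1]]$rater_id, profession = profession,
                 mean_tfs = mean(tfs), sd_tfs = stats::sd(tfs),
                 mean_tfa = mean(tfa), sd_tfa = stats::sd(tfa),
                 n_cases = length(case_summaries)),
            class = "rater_summary")
}

#' One-way fixed-effects ANOVA
#'
#' @param values numeric vector of rater-level values.
#' @param groups group labels, same length (>= 2 groups, each non-empty,
#'   at least one group with >= 2 values).
#' @return list: `F`, `df_between`, `df_within`, `p`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("ANOVA needs at least 2 groups")
  if (any(tabulate(groups) == 0L)) stop("every group must be non-empty")
  if (length(values) - nlevels(groups) < 1L) {
    stop("no within-group degrees of freedom: need at least one group with >= 2 values")
  }
  gm <- tapply(values, groups, mean)
  ssw <- sum((values - gm[groups])^2)
  if (ssw <= 1e-24 * max(1, sum(values^2))) {
    stop("degenerate-variance: zero within-group variance everywhere; the F statistic is undefined")
  }
  tab <- stats::anova(stats::lm(values ~ groups))
  list(F = tab$`F value`[1], df_between = tab$Df[1], df_within = tab$Df[2],
       p = tab$`Pr(>F)`[1])
}

#' Bonferroni-corrected pairwise post hoc t tests
#'
#' All pairwise two-sample t tests with pooled variance within each pair;
#' adjusted p is `min(1, k * p_raw)` with `k` the number of pairs.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return data.frame with columns `group1`, `group2`, `t`, `df`, `p_raw`,
#'   `p_adj`.
#' @export
bonferroni_posthoc <- function(values, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  k <- ncol(pairs)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    if (length(a) + length(b) < 3L) {
      stop(sprintf("insufficient degrees of freedom for pair %s vs %s (need n1 + n2 >= 3)",
                   pairs[1, i], pairs[2, i]))
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    rows[[i]] <- data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
                            t = unname(tt$statistic), df = unname(tt$parameter),
                            p_raw = tt$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, k * out$p_raw)
  out
}

#' Univariate experience regression
#'
#' Ordinary least squares `y = a + b x` of a per-rater outcome on years of
#' experience. Raters lacking the experience variable (NA in `x`) are
#' dropped, shrinking the degrees of freedom accordingly. A negative slope
#' means improvement with experience; the reported `improvement_per_year`
#' is `|b|` when `b < 0`, else 0.
#'
#' @param x years of experience per rater (NA allowed).
#' @param y outcome per rater (mm or degrees).
#' @return list: `slope`, `intercept`, `r_squared`, `F`, `df1`, `df2`, `p`,
#'   `n`, `improvement_per_year`.
#' @export
regress_experience <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("experience regression needs at least 3 raters with both values")
  if (stats::var(x) <= 0) stop("undefined slope: zero variance in the experience variable")
  if (stats::var(y) == 0) {
    # constant outcome: flat line, no explained variance
    return(list(slope = 0, intercept = y[1], r_squared = 0,
                F = 0, df1 = 1, df2 = length(x) - 2L, p = 1, n = length(x),
                improvement_per_year = 0))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       F = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
       p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
       n = length(x),
       improvement_per_year = max(0, -unname(stats::coef(fit)[2])))
}

#' Run the full inter-rater study
#'
#' Computes per-fragment deviations of every non-gold rater from the
#' gold-standard plan, aggregates them per case and per rater, and runs the
#' group and experience analyses: one-way ANOVA over profession groups on
#' the per-rater means and, separately, on the per-rater standard
#' deviations (consistency); Bonferroni post hoc pairwise t tests; and
#' univariate regressions of the per-rater means on 3D-planning years (all
#' non-gold raters) and on clinical years (raters possessing that value).
#'
#' @param plans `plan_table` (see [plan_table()]); poses either as a `pose`
#'   list column of `rigid_transform` or a `pose_path` column resolved via
#'   [read_pose()] relative to `pose_dir`.
#' @param raters `rater_table`; every rater in `plans` must have a profile.
#' @param meshes named list of `triangle_mesh`, names `"case/fragment"`
#'   (see [mesh_key()]).
#' @param pose_dir base directory for `pose_path` references (default ".").
#' @param alpha significance level recorded in the result (default 0.05).
#' @return object of class `study_result`: `rater_summaries` (data.frame),
#'   `case_summaries` (data.frame), `anova`, `posthoc`, `regressions`
#'   (named lists per outcome), `alpha`, `gold`. When the deviations carry
#'   no variability (every rater reproduces gold), the ANOVA/post
#'   hoc/regression slots are replaced by a `"no variability"` note.
#' @export
run_study <- function(plans, raters, meshes, pose_dir = ".", alpha = 0.05) {
  if (!inherits(plans, "plan_table")) stop("plans must be a plan_table")
  raters <- rater_table(as.data.frame(raters))
  gold <- plan_gold(plans)
  missing_prof <- setdiff(unique(plans$rater_id), raters$rater_id)
  if (length(missing_prof)) {
    stop(sprintf("rater(s) in plan table without a profile: %s",
                 paste(missing_prof, collapse = ", ")))
  }

  pose_of <- function(row) {
    if ("pose" %in% names(plans)) return(plans$pose[[row]])
    read_pose(file.path(pose_dir, plans$pose_path[row]))
  }
  cf_key <- paste(plans$case_id, plans$fragment_id, sep = "/")
  gold_rows <- which(plans$rater_id == gold)
  gold_pose <- stats::setNames(lapply(gold_rows, pose_of), cf_key[gold_rows])

  # fragment centers cached per (case, fragment) in the mesh's own frame
  centers <- new.env(parent = emptyenv())
  center_of <- function(key) {
    if (is.null(centers[[key]])) {
      m <- meshes[[key]]
      if (is.null(m)) stop(sprintf("no mesh supplied for '%s'", key))
      centers[[key]] <- obb_center(m)
    }
    centers[[key]]
  }

  other_rows <- which(plans$rater_id != gold)
  devs <- vector("list", length(other_rows))
  for (i in seq_along(other_rows)) {
    row <- other_rows[i]
    key <- cf_key[row]
    dev <- tryCatch(
      deviation_from_gold(meshes[[key]], pose_of(row), gold_pose[[key]],
                          center = center_of(key)),
      error = function(e) {
        stop(sprintf("rater '%s', case '%s', fragment '%s': %s",
                     plans$rater_id[row], plans$case_id[row],
                     plans$fragment_id[row], conditionMessage(e)))
      })
    devs[[i]] <- data.frame(rater_id = plans$rater_id[row],
                            case_id = plans$case_id[row],
                            fragment_id = plans$fragment_id[row],
                            tfs = dev$tfs, tfa = dev$tfa,
                            rms_residual = dev$rms_residual,
                            stringsAsFactors = FALSE)
  }
  devdf <- do.call(rbind, devs)
  analyze_deviations(devdf, raters, gold, alpha = alpha)
}

#' Group and experience analyses from a per-fragment deviation table
#'
#' The statistical half of [run_study()], exposed separately so that
#' precomputed deviations can be analyzed directly.
#'
#' @param devdf data.frame with columns `rater_id`, `case_id`, `tfs`, `tfa`
#'   (one row per fragment; the gold rater's rows, if present, are dropped).
#' @param raters `rater_table`.
#' @param gold gold-standard rater_id (excluded from all analyses).
#' @param alpha significance level recorded in the result.
#' @return `study_result`; see [run_study()].
#' @export
analyze_deviations <- function(devdf, raters, gold, alpha = 0.05) {
  devdf <- devdf[devdf$rater_id != gold, , drop = FALSE]
  raters <- raters[order(raters$rater_id), , drop = FALSE]

  # per (rater, case) summaries, in deterministic key order
  sp <- split(devdf, list(devdf$rater_id, devdf$case_id), drop = TRUE)
  cs <- lapply(sp, function(d) {
    devs <- lapply(seq_len(nrow(d)), function(i) list(tfs = d$tfs[i], tfa = d$tfa[i]))
    aggregate_case(devs, rater_id = d$rater_id[1], case_id = d$case_id[1])
  })
  case_df <- do.call(rbind, lapply(cs, function(s) {
    data.frame(rater_id = s$rater_id, case_id = s$case_id,
               mean_tfs = s$mean_tfs, mean_tfa = s$mean_tfa,
               n_fragments = s$n_fragments, stringsAsFactors = FALSE)
  }))
  case_df <- case_df[order(case_df$rater_id, case_df$case_id), , drop = FALSE]
  rownames(case_df) <- NULL

  prof <- stats::setNames(raters$profession, raters$rater_id)
  rs <- lapply(split(case_df, case_df$rater_id), function(d) {
    aggregate_rater(lapply(seq_len(nrow(d)), function(i) {
      list(rater_id = d$rater_id[i], case_id = d$case_id[i],
           mean_tfs = d$mean_tfs[i], mean_tfa = d$mean_tfa[i])
    }), profession = unname(prof[d$rater_id[1]]))
  })
  rater_df <- do.call(rbind, lapply(rs, function(s) {
    data.frame(rater_id = s$rater_id, profession = s$profession,
               mean_tfs = s$mean_tfs, sd_tfs = s$sd_tfs,
               mean_tfa = s$mean_tfa, sd_tfa = s$sd_tfa,
               n_cases = s$n_cases, stringsAsFactors = FALSE)
  }))
  rater_df <- rater_df[order(rater_df$rater_id), , drop = FALSE]
  rownames(rater_df) <- NULL

  outcomes <- list(tfs_mean = rater_df$mean_tfs, tfs_sd = rater_df$sd_tfs,
                   tfa_mean = rater_df$mean_tfa, tfa_sd = rater_df$sd_tfa)
  groups <- rater_df$profession

  no_var <- all(abs(c(devdf$tfs, devdf$tfa)) < 1e-12)
  if (no_var) {
    note <- "no variability: every rater reproduces the gold-standard plan exactly"
    anova_out <- posthoc_out <- reg_out <- note
  } else {
    anova_out <- lapply(outcomes, function(v) {
      tryCatch(oneway_anova(v, groups), error = function(e) conditionMessage(e))
    })
    posthoc_out <- lapply(outcomes, function(v) {
      tryCatch(bonferroni_posthoc(v, groups), error = function(e) conditionMessage(e))
    })
    yrs <- raters[match(rater_df$rater_id, raters$rater_id), ]
    reg_out <- list(
      tfs_planning = tryCatch(regress_experience(yrs$planning_years, rater_df$mean_tfs),
                              error = function(e) conditionMessage(e)),
      tfa_planning = tryCatch(regress_experience(yrs$planning_years, rater_df$mean_tfa),
                              error = function(e) conditionMessage(e)),
      tfs_clinical = tryCatch(regress_experience(yrs$clinical_years, rater_df$mean_tfs),
                              error = function(e) conditionMessage(e)),
      tfa_clinical = tryCatch(regress_experience(yrs$clinical_years, rater_df$mean_tfa),
                              error = function(e) conditionMessage(e)))
  }

  structure(list(rater_summaries = rater_df, case_summaries = case_df,
                 anova = anova_out, posthoc = posthoc_out,
                 regressions = reg_out, alpha = alpha, gold = gold),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %d raters (gold '%s' excluded), alpha = %g>\n",
              nrow(x$rater_summaries), x$gold, x$alpha))
  print(x$rater_summaries, digits = 4)
  if (is.character(x$anova)) {
    cat(sprintf("note: %s\n", x$anova))
  } else {
    for (nm in names(x$anova)) {
      a <- x$anova[[nm]]
      if (is.character(a)) {
        cat(sprintf("ANOVA %-8s: %s\n", nm, a))
      } else {
        cat(sprintf("ANOVA %-8s: F(%d, %d) = %.3f, p = %.4g\n",
                    nm, a$df_between, a$df_within, a$F, a$p))
      }
    }
    for (nm in names(x$regressions)) {
      r <- x$regressions[[nm]]
      if (is.character(r)) {
        cat(sprintf("regression %-12s: %s\n", nm, r))
      } else {
        cat(sprintf("regression %-12s: slope %.4f/yr, R^2 %.3f, F(%d, %d) = %.3f, p = %.4g\n",
                    nm, r$slope, r$r_squared, r$df1, r$df2, r$F, r$p))
      }
    }
  }
  invisible(x)
}

#' Key naming a fragment mesh within a study
#' @param case_id,fragment_id identifiers.
#' @return string `"case/fragment"` used to index the `meshes` list.
#' @export
mesh_key <- function(case_id, fragment_id) paste(case_id, fragment_id, sep = "/")
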