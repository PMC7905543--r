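#' Planning and rater tables
#'
#' CSV dialect: comma-separated, UTF-8, header row required. Plans list one
#' pose file per (rater, case, fragment); raters carry the profession group
#' and the two experience variables. Empty cells mean "absent" (biomedical
#' engineers have no clinical years).
#'
#' @name tables
NULL

PROFESSIONS <- c("SS", "BE", "SOR", "JOR")

#' Read a reduction-plan table
#'
#' @param path CSV with columns `rater_id,case_id,fragment_id,pose_path`.
#' @param gold rater_id of the designated gold-standard rater.
#' @return object of class `plan_table`: a data.frame of the rows plus
#'   attribute `gold`.
#' @export
read_plan_table <- function(path, gold) {
  if (!file.exists(path)) stop(sprintf("plan table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  plan_table(df, gold)
}

#' Construct and validate a plan table
#'
#' @param df data.frame with columns `rater_id`, `case_id`, `fragment_id`
#'   and either `pose_path` (file references) or `pose` (list column of
#'   `rigid_transform`).
#' @param gold rater_id of the gold-standard rater; every (case, fragment)
#'   planned by any other rater must also be planned by the gold rater.
#' @return `plan_table`.
#' @export
plan_table <- function(df, gold) {
  need <- c("rater_id", "case_id", "fragment_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("plan table lacks column(s): %s", paste(miss, collapse = ", ")))
  if (!("pose_path" %in% names(df)) && !("pose" %in% names(df))) {
    stop("plan table needs a 'pose_path' or 'pose' column")
  }
  key <- paste(df$rater_id, df$case_id, df$fragment_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate (rater, case, fragment) key(s) in plan table at row(s): %s",
                 paste(dup, collapse = ", ")))
  }
  if (!gold %in% df$rater_id) stop(sprintf("gold-standard rater '%s' has no rows in plan table", gold))
  gold_cf <- paste(df$case_id, df$fragment_id, sep = "\r")[df$rater_id == gold]
  other <- df$rater_id != gold
  cf <- paste(df$case_id, df$fragment_id, sep = "\r")
  missing_gold <- other & !(cf %in% gold_cf)
  if (any(missing_gold)) {
    rows <- which(missing_gold)
    stop(sprintf("plan table row(s) %s reference (case, fragment) pairs without a gold-standard ('%s') plan",
                 paste(rows, collapse = ", "), gold))
  }
  structure(df, gold = gold, class = c("plan_table", "data.frame"))
}

#' Gold-standard rater of a plan table
#' @param plans `plan_table`.
#' @return rater_id string.
#' @export
plan_gold <- function(plans) attr(plans, "gold")

#' Read a rater table
#'
#' @param path CSV with columns
#'   `rater_id,profession,clinical_years,planning_years`; an empty
#'   `clinical_years` cell means the rater has none (biomedical engineers).
#' @return data.frame of rater profiles (class `rater_table`).
#' @export
read_rater_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("rater table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = c("character", "character", "character", "character"))
  rater_table(data.frame(rater_id = df$rater_id,
                         profession = df$profession,
                         clinical_years = suppressWarnings(as.numeric(df$clinical_years)),
                         planning_years = suppressWarnings(as.numeric(df$planning_years)),
                         stringsAsFactors = FALSE))
}

#' Construct and validate a rater table
#'
#' @param df data.frame with columns `rater_id`, `profession` (one of SS,
#'   BE, SOR, JOR; exactly one SS), `clinical_years` (NA allowed),
#'   `planning_years`.
#' @return `rater_table` data.frame.
#' @export
rater_table <- function(df) {
  need <- c("rater_id", "profession", "clinical_years", "planning_years")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("rater table lacks column(s): %s", paste(miss, collapse = ", ")))
  bad <- which(!df$profession %in% PROFESSIONS)
  if (length(bad)) {
    stop(sprintf("unknown profession code(s) %s at row(s): %s (expected %s)",
                 paste(unique(df$profession[bad]), collapse = ", "),
                 paste(bad, collapse = ", "), paste(PROFESSIONS, collapse = "/")))
  }
  if (sum(df$profession == "SS") != 1L) {
    stop(sprintf("exactly one senior-surgeon (SS) rater is required, found %d",
                 sum(df$profession == "SS")))
  }
  if (anyDuplicated(df$rater_id)) stop("duplicate rater_id in rater table")
  for (col in c("clinical_years", "planning_years")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (!is.finite(v) | v < 0))
    if (length(bad)) stop(sprintf("%s must be finite and >= 0; bad row(s): %s",
                                  col, paste(bad, collapse = ", ")))
  }
  bad <- which(is.na(df$planning_years))
  if (length(bad)) stop(sprintf("planning_years missing at row(s): %s", paste(bad, collapse = ", ")))
  structure(df, class = c("rater_table", "data.frame"))
}

#' Write study results to disk
#'
#' Emits `study_result.json` (full machine-readable result, numbers at full
#' precision) and `rater_summaries.csv` (per-rater table).
#'
#' @param result `study_result` from [run_study()].
#' @param dir output directory (created if absent).
#' @return named character vector of the two paths, invisibly.
#' @export
write_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "study_result.json")
  csv_path <- file.path(dir, "rater_summaries.csv")
  out <- unclass(result)
  out$rater_summaries <- as.data.frame(result$rater_summaries)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  utils::write.csv(result$rater_summaries, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Re-read study results written by [write_results()]
#' @param dir directory passed to [write_results()].
#' @return list with the parsed JSON (`result`) and the CSV (`rater_summaries`).
#' @export
read_results <- function(dir) {
  list(result = jsonlite::fromJSON(file.path(dir, "study_result.json")),
       rater_summaries = utils::read.csv(file.path(dir, "rater_summaries.csv"),
                                         stringsAsFactors = FALSE))
}
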