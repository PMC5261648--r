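# Cohort file formats: plain CSV with a fixed written schema (the lingua
# franca of longitudinal obstetric datasets).  GA is stored in days;
# conversion to weeks happens only inside design construction.

FG_SUBJECT_COLS <- c("subject_id", "country", "maternal_age_y", "height_cm",
                     "weight_kg", "parity", "fetal_sex")
FG_SCAN_COLS <- c("subject_id", "ga_days", "bpd_mm", "hc_mm", "ac_mm",
                  "fl_mm", "hl_mm")

check_schema <- function(d, expected, what) {
  extra <- setdiff(names(d), expected)
  if (length(extra))
    fg_stop("fg_schema", "%s table has unrecognised column(s): %s",
            what, paste(extra, collapse = ", "))
  missing <- setdiff(expected, names(d))
  if (length(missing))
    fg_stop("fg_schema", "%s table is missing column(s): %s",
            what, paste(missing, collapse = ", "))
  d[expected]
}

#' Read a cohort from subject and scan CSV files
#'
#' Validates the written schema (exact column sets), referential integrity
#' (every scan's subject must exist; no duplicate subject/GA pairs) and
#' plausible units (maternal height 120-200 cm, GA 50-300 days, positive
#' biometry — implausible values warn, they do not error).
#'
#' @param subjects_file,scans_file CSV paths.
#' @return List with typed \code{subjects} and \code{scans} data frames.
#' @export
read_cohort <- function(subjects_file, scans_file) {
  subjects <- check_schema(utils::read.csv(subjects_file,
                                           stringsAsFactors = FALSE),
                           FG_SUBJECT_COLS, "subjects")
  scans <- check_schema(utils::read.csv(scans_file, stringsAsFactors = FALSE),
                        FG_SCAN_COLS, "scans")
  orphans <- setdiff(scans$subject_id, subjects$subject_id)
  if (length(orphans))
    fg_stop("fg_integrity", "scans reference unknown subject(s): %s",
            paste(utils::head(orphans, 10), collapse = ", "))
  dup <- duplicated(scans[c("subject_id", "ga_days")])
  if (any(dup))
    fg_stop("fg_integrity", "duplicate (subject_id, ga_days) pair(s): %s",
            paste(utils::head(scans$subject_id[dup], 10), collapse = ", "))
  if (any(subjects$height_cm < 120 | subjects$height_cm > 200, na.rm = TRUE))
    warning("maternal heights outside 120-200 cm", call. = FALSE)
  if (any(scans$ga_days < 50 | scans$ga_days > 300, na.rm = TRUE))
    warning("gestational ages outside 50-300 days", call. = FALSE)
  bio <- as.matrix(scans[c("bpd_mm", "hc_mm", "ac_mm", "fl_mm", "hl_mm")])
  if (any(bio <= 0 | bio > 500, na.rm = TRUE))
    warning("biometric values outside the physiological range", call. = FALSE)
  list(subjects = subjects, scans = scans)
}

#' Write a cohort as subject and scan CSV files
#'
#' @param cohort list with \code{subjects} and \code{scans} (e.g. from
#'   [simulate_cohort()]); only the schema columns are written.
#' @param dir output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             scans = file.path(dir, "scans.csv"))
  utils::write.csv(cohort$subjects[FG_SUBJECT_COLS], paths["subjects"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$scans[FG_SCAN_COLS], paths["scans"],
                   row.names = FALSE, quote = FALSE)
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    keep <- cfg[!vapply(cfg, is.list, logical(1))]
    writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(dir, "sim_config.json"))
  }
  invisible(paths)
}
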