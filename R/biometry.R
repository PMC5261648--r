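#' Estimated fetal weight, Hadlock formula 3
#'
#' Computes estimated fetal weight (EFW) in grams from head circumference,
#' abdominal circumference and femur length using Hadlock's third
#' regression formula,
#' \deqn{\log_{10} W = 1.326 - 0.00326\,AC \cdot FL + 0.0107\,HC
#'       + 0.0438\,AC + 0.158\,FL,}
#' with lengths in cm (inputs here are in mm, the storage unit of fetal
#' biometry, and are converted internally).
#'
#' @param hc_mm head circumference in mm.
#' @param ac_mm abdominal circumference in mm.
#' @param fl_mm femur length in mm.
#' @return Estimated fetal weight in grams, at full precision (round only at
#'   presentation time).  Vectorised over its arguments.
#' @examples
#' efw_hadlock3(342, 363, 73)  # ~3727 g, term fetus
#' efw_hadlock3(100, 81, 13)   # ~91 g, 14 weeks
#' @export
efw_hadlock3 <- function(hc_mm, ac_mm, fl_mm) {
  for (v in list(hc_mm, ac_mm, fl_mm))
    if (!is.numeric(v) || anyNA(v) || any(v <= 0))
      fg_stop("fg_invalid_measurement",
              "all biometric inputs must be positive and non-missing")
  hc <- hc_mm / 10; ac <- ac_mm / 10; fl <- fl_mm / 10
  10^(1.326 - 0.00326 * ac * fl + 0.0107 * hc + 0.0438 * ac + 0.158 * fl)
}

#' Fetal head proportion ratios
#'
#' The unit-free ratios FL/HC and FL/BPD used to assess relative fetal head
#' size (e.g. suspected hydrocephaly or microcephaly).
#'
#' @param scans data frame with columns \code{fl_mm}, \code{hc_mm},
#'   \code{bpd_mm} (a single scan record or many).
#' @return Data frame with columns \code{fl_hc} and \code{fl_bpd}.
#' @export
head_ratios <- function(scans) {
  need <- c("fl_mm", "hc_mm", "bpd_mm")
  miss <- setdiff(need, names(scans))
  if (length(miss))
    fg_stop("fg_missing_measurement", "missing measurement column(s): %s",
            paste(miss, collapse = ", "))
  for (v in need)
    if (anyNA(scans[[v]]) || any(scans[[v]] <= 0))
      fg_stop("fg_missing_measurement",
              "%s must be present and positive for all scans", v)
  data.frame(fl_hc = scans$fl_mm / scans$hc_mm,
             fl_bpd = scans$fl_mm / scans$bpd_mm)
}

# Add derived per-scan quantities (EFW and head ratios) to a scans table.
add_derived_biometry <- function(scans) {
  if (is.null(scans$efw_g))
    scans$efw_g <- efw_hadlock3(scans$hc_mm, scans$ac_mm, scans$fl_mm)
  if (is.null(scans$fl_hc) || is.null(scans$fl_bpd)) {
    hr <- head_ratios(scans)
    scans$fl_hc <- hr$fl_hc
    scans$fl_bpd <- hr$fl_bpd
  }
  scans
}
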