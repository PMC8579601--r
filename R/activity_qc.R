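#' Accelerometer summary QC
#'
#' Applies the physical-activity inclusion filters to wear-time-adjusted
#' 7-day average acceleration records: good wear-time, good calibration, no
#' data-problem indicators, and mean acceleration not above 100
#' milligravities (exactly 100 mg is retained; the exclusion is strictly
#' "> 100"). Records with negative acceleration are rejected as malformed.
#'
#' @param records data.frame with columns participant_id, mean_accel (mg),
#'   good_wear_time (logical or "Yes"/"No"), good_calibration (ditto),
#'   problem_indicators (character; empty string or NA means none).
#' @param accel_max exclusion threshold in milligravities (default 100).
#' @return list with `records` (input plus logical `included`),
#'   `exclusions` (per-reason counts; a record can fail several rules) and
#'   `n_included`.
#' @export
qc_pa <- function(records, accel_max = 100) {
  req <- c("participant_id", "mean_accel", "good_wear_time",
           "good_calibration", "problem_indicators")
  .assert(all(req %in% names(records)),
          paste("records must have columns:", paste(req, collapse = ", ")))
  if (any(!is.na(records$mean_accel) & records$mean_accel < 0))
    stop("malformed record: negative mean_accel", call. = FALSE)

  as_yes <- function(x) if (is.logical(x)) x else x %in% c("Yes", "yes", "TRUE")
  wear <- as_yes(records$good_wear_time)
  calib <- as_yes(records$good_calibration)
  no_problem <- is.na(records$problem_indicators) |
    !nzchar(trimws(records$problem_indicators))
  accel_ok <- !is.na(records$mean_accel) & records$mean_accel <= accel_max

  records$included <- wear & calib & no_problem & accel_ok
  exclusions <- data.frame(
    reason = c("bad_wear_time", "bad_calibration", "problem_indicator",
               "accel_above_threshold"),
    n = c(sum(!wear), sum(!calib), sum(!no_problem), sum(!accel_ok)))
  list(records = records, exclusions = exclusions,
       n_included = sum(records$included))
}
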