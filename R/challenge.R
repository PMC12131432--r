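# The standardized cold-challenge session: timepoint schedule, thermography
# reference aggregation and return-to-baseline classification.

#' The seven-timepoint cold-challenge schedule
#'
#' One basal assessment before immersion, then assessments immediately
#' after the cold challenge and every 2 minutes up to 10 minutes: seven
#' assessments in total.
#'
#' @return A data frame of class `timepoint_schedule` with columns `label`
#'   (`basal`, `0min`, ..., `10min`) and `minutes` (`NA` for basal, then
#'   0, 2, 4, 6, 8, 10).
#' @export
protocol_schedule <- function() {
  sched <- data.frame(
    label = c("basal", "0min", "2min", "4min", "6min", "8min", "10min"),
    minutes = c(NA, 0, 2, 4, 6, 8, 10),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("timepoint_schedule", "data.frame")
  sched
}

assert_schedule <- function(schedule) {
  if (!is.data.frame(schedule) ||
      !all(c("label", "minutes") %in% names(schedule))) {
    artix_error("artix_bad_schedule",
                "schedule must be a data frame with label and minutes")
  }
  invisible(schedule)
}

#' Read a thermal frame from headerless CSV
#'
#' @param path CSV file containing an H x W matrix of temperatures in degC.
#' @return Numeric matrix.
#' @export
read_thermal_frame <- function(path) {
  fr <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(fr) <- NULL
  storage.mode(fr) <- "double"
  if (any(fr < 0 | fr > 45, na.rm = TRUE)) {
    artix_warn("artix_implausible_temperature",
               "thermal frame contains values outside the plausible 0-45 degC range")
  }
  fr
}

#' Mean temperature of one finger region
#'
#' @param frame H x W matrix of temperatures (degC).
#' @param region A `finger_region` or binary mask on the same grid.
#' @return Arithmetic mean of the frame values inside the region.
#' @export
thermal_finger_mean <- function(frame, region) {
  if (!is.matrix(frame)) {
    artix_error("artix_bad_input", "thermal frame must be a matrix")
  }
  mask <- as_binary_mask(if (is.list(region)) region$mask else region)
  if (!identical(dim(mask), dim(frame))) {
    artix_error("artix_shape_mismatch",
                "region does not lie within the thermal frame grid")
  }
  if (!any(mask)) artix_error("artix_empty_region", "region is empty")
  mean(frame[mask])
}

#' Aggregate eight finger temperatures into the subject-level value
#'
#' The thermography reference value is the mean of the mean temperatures of
#' the second to fifth fingers of both hands -- exactly eight values.
#'
#' @param finger_means Numeric vector of 8 per-finger means (degC).
#' @return Their arithmetic mean.
#' @export
subject_thermal_value <- function(finger_means) {
  if (length(finger_means) != 8L || !is.numeric(finger_means)) {
    artix_error("artix_bad_input",
                "exactly 8 finger means are required (digits II-V, both hands)")
  }
  mean(finger_means)
}

# pull a named series out of a session or accept a bare named vector
.series_of <- function(session, measure) {
  if (inherits(session, "challenge_session")) session[[measure]]
  else session
}

#' Did a subject return to baseline at the tenth minute?
#'
#' True iff the 10-minute value meets or exceeds the basal (pre-immersion)
#' value -- subjects who overshoot the baseline count as returned.
#'
#' @param session A `challenge_session`, or a named numeric series with
#'   entries `basal` and `10min`.
#' @param measure `"artix"` or `"thermal"` (ignored for bare vectors).
#' @return Logical.
#' @export
returned_to_baseline <- function(session, measure = c("artix", "thermal")) {
  measure <- match.arg(measure)
  v <- .series_of(session, measure)
  if (!all(c("basal", "10min") %in% names(v)) ||
      is.na(v[["basal"]]) || is.na(v[["10min"]])) {
    artix_error("artix_missing_timepoint",
                "both the basal and the 10-minute value are required")
  }
  unname(v[["10min"]] >= v[["basal"]])
}

#' Return-to-baseline counts by group
#'
#' Tabulates how many subjects of each group returned to their baseline
#' value at the tenth minute, for either measure.
#'
#' @param sessions List of `challenge_session` objects.
#' @param measure `"artix"` or `"thermal"`.
#' @return A data frame with one row per group: `group`, `n`, `returned`,
#'   `not_returned`, `proportion`.
#' @export
cohort_return_table <- function(sessions, measure = c("artix", "thermal")) {
  measure <- match.arg(measure)
  stopifnot(length(sessions) >= 1L)
  grp <- vapply(sessions, function(s) s$group, character(1))
  ret <- vapply(sessions, returned_to_baseline, logical(1), measure = measure)
  present <- intersect(c("RP", "HC"), unique(grp))
  if (length(present) < 2L) {
    artix_warn("artix_partial_table",
               "only one group present; returning a partial table")
  }
  out <- do.call(rbind, lapply(present, function(g) {
    r <- sum(ret[grp == g]); n <- sum(grp == g)
    data.frame(group = g, n = n, returned = r, not_returned = n - r,
               proportion = r / n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
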