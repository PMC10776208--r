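#' Normative deficit classification against a control group
#'
#' Per test, the deficit threshold is the control mean minus 1.5 control
#' standard deviations *on the performance scale*: for `higher_better`
#' tests a patient is classified as having a clinically relevant deficit
#' when the score is strictly below `mean - 1.5 * SD`, for
#' `lower_better` (time-scored) tests when it is strictly above
#' `mean + 1.5 * SD`. Boundary equality is non-deficit. Patient and
#' control groups are additionally compared with a two-sided two-sample
#' test.
#'
#' @param patient_scores patient score data frame (first column
#'   `subject_id`).
#' @param control_scores control score data frame in the same layout.
#' @param battery test battery table giving each test's direction.
#' @param sd_multiplier threshold distance in control SDs (default 1.5).
#' @param group_test `"t"` (default, Welch two-sided) or `"wilcoxon"` for
#'   the patient-vs-control comparison.
#' @return a `norm_table` data frame, one row per test: control mean/SD,
#'   direction, native-unit `deficit_threshold`, `n_deficit`,
#'   `deficit_rate_pct`, mean percent deviation of patients from the
#'   control mean, and the group-difference statistic and p-value.
#' @export
deficit_classify <- function(patient_scores, control_scores,
                             battery = cognitive_battery(),
                             sd_multiplier = 1.5,
                             group_test = c("t", "wilcoxon")) {
  group_test <- match.arg(group_test)
  tests <- intersect(setdiff(names(patient_scores), "subject_id"),
                     setdiff(names(control_scores), "subject_id"))
  if (!length(tests)) stop("no shared test columns", call. = FALSE)
  rows <- lapply(tests, function(tn) {
    spec <- test_spec(tn, battery)
    ctrl <- control_scores[[tn]]
    ctrl <- ctrl[!is.na(ctrl)]
    if (length(ctrl) < 10) {
      stop("need at least 10 controls for test '", tn, "'", call. = FALSE)
    }
    m <- mean(ctrl); s <- sd(ctrl)
    if (s == 0) {
      stop("control SD is zero for test '", tn, "'", call. = FALSE)
    }
    pat <- patient_scores[[tn]]
    pat <- pat[!is.na(pat)]
    if (direction_sign(spec) > 0) {
      thr <- m - sd_multiplier * s
      deficit <- pat < thr
    } else {
      thr <- m + sd_multiplier * s
      deficit <- pat > thr
    }
    gt <- if (group_test == "t") {
      t.test(pat, ctrl)
    } else suppressWarnings(wilcox.test(pat, ctrl, exact = FALSE))
    data.frame(
      test_id = tn, direction = spec$direction,
      control_mean = m, control_sd = s,
      deficit_threshold = thr,
      n_patients = length(pat), n_deficit = sum(deficit),
      deficit_rate_pct = 100 * mean(deficit),
      mean_deviation_pct = 100 * (mean(pat) - m) / m,
      statistic = unname(gt$statistic), p = gt$p.value,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "sd_multiplier") <- sd_multiplier
  attr(out, "group_test") <- group_test
  class(out) <- c("norm_table", "data.frame")
  out
}
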