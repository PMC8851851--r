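# Statistics for coculture growth assays (transformed-cell counts per
# microscopic field) and Western-blot densitometry: percent of control,
# SEM, fold ratios, and t-tests against the control condition.

sem <- function(x) {
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Percent-of-control summary for a treated condition
#'
#' Scales each treated replicate to `100 * value / mean(control)` and
#' reports the percent mean, its SEM (sample sd over sqrt(n)), and the
#' two-tailed Student's t-test p-value computed between the raw treated and
#' control measurements (not the percents, avoiding double scaling).
#'
#' @param treated,control Numeric replicate measurements (>= 2 each for the
#'   test; measurements must be non-negative).
#' @return One-row tibble: `percent_mean`, `percent_sem`, `p.value`,
#'   `n_treated`, `n_control`.
#' @export
#' @examples
#' percent_of_control(c(10, 9, 11, 10), c(200, 210, 190, 200))
percent_of_control <- function(treated, control) {
  if (any(treated < 0) || any(control < 0)) {
    stop("measurements must be non-negative", call. = FALSE)
  }
  cm <- mean(control)
  if (cm <= 0) stop("control mean must be positive", call. = FALSE)
  pct <- 100 * treated / cm
  tt <- student_t_test(treated, control)
  tibble(percent_mean = mean(pct), percent_sem = sem(pct),
         p.value = tt$p.value,
         n_treated = length(treated), n_control = length(control))
}

#' Loading-normalized densitometry as percent of a reference
#'
#' Per replicate lane, `100 * (signal / loading) / reference_mean`, the
#' arithmetic used to compare band intensities across blots after
#' normalizing to a loading control and a reference condition.
#'
#' @param signal Band signals (non-negative, arbitrary units).
#' @param loading Loading-control signals, same length, all positive.
#' @param reference_mean Mean loading-normalized signal of the reference
#'   condition (positive).
#' @return Numeric vector of percent values, one per lane.
#' @export
#' @examples
#' densitometry_percent(c(50, 55), c(100, 100), reference_mean = 1)
densitometry_percent <- function(signal, loading, reference_mean) {
  if (length(signal) != length(loading)) {
    stop("signal and loading must have the same length", call. = FALSE)
  }
  if (any(signal < 0)) stop("negative signal value", call. = FALSE)
  if (any(loading <= 0)) {
    lane <- which(loading <= 0)[1]
    stop(sprintf("non-positive loading value in lane %d", lane),
         call. = FALSE)
  }
  if (reference_mean <= 0) {
    stop("reference_mean must be positive", call. = FALSE)
  }
  100 * (signal / loading) / reference_mean
}

#' Fold ratio of condition means
#'
#' `mean(a) / mean(b)`, the plain ratio used to compare growth between
#' coculture conditions.
#'
#' @param a,b Non-empty numeric measurement vectors; `mean(b)` must be
#'   positive.
#' @return A single fold ratio.
#' @export
#' @examples
#' fold_vs_condition(c(140, 160), c(2, 2))  # 75
fold_vs_condition <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("measurement vectors must be non-empty", call. = FALSE)
  }
  if (mean(b) <= 0) stop("mean of b must be positive", call. = FALSE)
  mean(a) / mean(b)
}

#' Per-condition assay summary against a control
#'
#' Summarizes a tidy assay table (`condition`, `replicate`, `value`) against
#' a named control condition: percent-of-control mean and SEM, t-test
#' p-value versus control (on raw values), and fold versus control.
#'
#' @param data Tibble with columns `condition`, `replicate`, `value`.
#' @param control Name of the control condition.
#' @return Tibble with one row per condition.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   condition = rep(c("alone", "with_MEC"), each = 4),
#'   replicate = rep(1:4, 2),
#'   value = c(200, 210, 190, 200, 10, 9, 11, 10))
#' assay_summary(d, control = "alone")
assay_summary <- function(data, control) {
  if (!all(c("condition", "replicate", "value") %in% names(data))) {
    stop("assay table needs columns condition, replicate, value",
         call. = FALSE)
  }
  if (!control %in% data$condition) {
    stop(sprintf("control condition '%s' not present", control),
         call. = FALSE)
  }
  if (any(data$value < 0)) {
    stop("measurements must be non-negative", call. = FALSE)
  }
  ctrl <- data$value[data$condition == control]
  data |>
    group_by(.data$condition) |>
    summarise(res = list(percent_of_control(.data$value, ctrl)),
              fold_vs_control = fold_vs_condition(.data$value, ctrl),
              .groups = "drop") |>
    tidyr::unnest("res") |>
    relocate("condition", "percent_mean", "percent_sem", "p.value",
             "fold_vs_control")
}
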