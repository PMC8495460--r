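# Intravital fluorescence pharmacokinetics: baseline subtraction, trace QC,
# log-linear half-life estimation over a fixed decay window, aggregation,
# and trace AUC.

#' Intensity-versus-time trace from one region of interest
#'
#' @param times sampling times in minutes, strictly increasing.
#' @param values mean ROI fluorescence (arbitrary units).
#' @param roi_id,animal_id identifiers.
#' @return A data frame of class `intensity_trace` with columns `time_min`,
#'   `intensity`, `roi_id`, `animal_id`.
#' @export
intensity_trace <- function(times, values, roi_id = "roi1",
                            animal_id = "animal1") {
  assert_that(length(times) == length(values),
              "`times` and `values` must have equal length")
  assert_that(all(diff(times) > 0), "`times` must be strictly increasing")
  structure(
    data.frame(time_min = as.numeric(times), intensity = as.numeric(values),
               roi_id = roi_id, animal_id = animal_id),
    class = c("intensity_trace", "data.frame")
  )
}

#' Subtract the autofluorescence baseline from a trace
#'
#' Shifts all intensities by the pre-injection (first-image) autofluorescence
#' level. Negative results are permitted — they are noise around zero — and
#' are only handled at fitting time, where non-positive values are dropped
#' point-wise before the log.
#'
#' @param trace an [intensity_trace()].
#' @param baseline_value baseline intensity; default is the first sample of
#'   the trace.
#' @return The baseline-subtracted [intensity_trace()].
#' @export
subtract_baseline <- function(trace, baseline_value = trace$intensity[1L]) {
  stopifnot(inherits(trace, "intensity_trace"))
  assert_that(is.finite(baseline_value), "`baseline_value` must be finite")
  trace$intensity <- trace$intensity - baseline_value
  trace
}

#' Quality-control screen for a plasma-disappearance trace
#'
#' Operationalizes the two exclusion criteria used for intravital ear-vein
#' recordings: absence of an initial signal increase after injection, and
#' apparent focal (Z-) drift. A trace fails `no_initial_increase` when its
#' post-injection peak is less than `rise_threshold` times the pre-injection
#' baseline level; it fails `z_drift` when the linear trend fitted to the
#' pre-injection baseline segment exceeds `drift_slope_bound` in magnitude.
#' Thresholds are configurable; the defaults encode "at least a doubling over
#' baseline" and "essentially flat baseline".
#'
#' @param trace an [intensity_trace()] on the raw (not baseline-subtracted)
#'   scale.
#' @param injection_time minutes; samples strictly before this are the
#'   baseline segment.
#' @param rise_threshold minimum peak/baseline fold increase (default 2).
#' @param drift_slope_bound maximum tolerated |slope| of the baseline
#'   segment, intensity units per minute, relative to the baseline level
#'   (default 0.05, i.e. 5% of baseline per minute).
#' @return A list of class `trace_qc`: `passed` (logical) and `reasons`
#'   (character subset of `c("no_initial_increase", "z_drift")`); `passed` is
#'   `TRUE` iff `reasons` is empty.
#' @export
qc_trace <- function(trace, injection_time = 1, rise_threshold = 2,
                     drift_slope_bound = 0.05) {
  stopifnot(inherits(trace, "intensity_trace"))
  assert_that(min(trace$time_min) <= injection_time &&
                max(trace$time_min) > injection_time,
              "trace must span the injection time")
  pre <- trace$time_min < injection_time
  baseline <- if (any(pre)) mean(trace$intensity[pre]) else trace$intensity[1L]
  peak <- max(trace$intensity[!pre])
  reasons <- character(0L)
  if (!(baseline > 0) || peak / baseline < rise_threshold) {
    reasons <- c(reasons, "no_initial_increase")
  }
  if (sum(pre) >= 3L) {
    slope <- unname(coef(lm(intensity ~ time_min, data = trace[pre, ]))[2L])
    if (abs(slope) > drift_slope_bound * abs(baseline)) {
      reasons <- c(reasons, "z_drift")
    }
  }
  structure(list(passed = length(reasons) == 0L, reasons = reasons),
            class = "trace_qc")
}

#' @export
print.trace_qc <- function(x, ...) {
  cat(if (x$passed) "trace QC: passed\n"
      else paste0("trace QC: excluded (", paste(x$reasons, collapse = ", "), ")\n"))
  invisible(x)
}

#' Log-linear half-life estimation over a fixed decay window
#'
#' Ordinary least squares of `log(intensity)` on time over the constant decay
#' phase of a baseline-subtracted trace, by default 15-40 min after recording
#' start. For a mono-exponential decay the log-trace is exactly linear, and
#' the half-life is `t_half = ln 2 / |slope|`. Non-positive intensities
#' inside the window (noise around the baseline) are dropped point-wise
#' before the log. The estimator is scale invariant: multiplying the trace
#' by a positive constant changes the intercept only.
#'
#' @param trace a baseline-subtracted [intensity_trace()].
#' @param window `c(start, end)` minutes of the regression window.
#' @return An object of class `half_life_fit` with fields `t_half` (min),
#'   `slope` (1/min, on natural-log intensity), `intercept`, `r_squared`,
#'   `window`, `n_points`, `valid` (FALSE when the fitted slope is
#'   non-negative, i.e. no decay), and the underlying `lm` fit. Supports
#'   `print()`, `coef()` and `predict()`.
#' @examples
#' tr <- simulate_decay_trace(55.9, baseline = 5, amplitude = 100)
#' fit <- fit_half_life(subtract_baseline(tr, 5))
#' fit
#' coef(fit)
#' @export
fit_half_life <- function(trace, window = c(15, 40)) {
  stopifnot(inherits(trace, "intensity_trace"))
  assert_that(length(window) == 2L && window[1L] < window[2L],
              "`window` must be c(start, end) with start < end")
  inw <- trace$time_min >= window[1L] & trace$time_min <= window[2L]
  usable <- inw & trace$intensity > 0
  assert_that(sum(usable) >= 3L,
              "fewer than 3 in-window points with positive intensity",
              class = "hepaclear_degenerate_input")
  d <- data.frame(t = trace$time_min[usable],
                  ly = log(trace$intensity[usable]))
  fit <- lm(ly ~ t, data = d)
  slope <- unname(coef(fit)[2L])
  valid <- is.finite(slope) && slope < 0
  if (!valid) warning("non-negative decay slope; half-life estimate flagged invalid")
  structure(
    list(t_half = if (valid) log(2) / abs(slope) else NA_real_,
         slope = slope, intercept = unname(coef(fit)[1L]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         window = window, n_points = sum(usable), valid = valid,
         fit = fit, roi_id = trace$roi_id[1L], animal_id = trace$animal_id[1L]),
    class = "half_life_fit"
  )
}

#' @export
print.half_life_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("Half-life fit (%g-%g min window, %d points): t1/2 = %.2f min, slope = %.4g /min, R^2 = %.4f\n",
                x$window[1L], x$window[2L], x$n_points, x$t_half, x$slope,
                x$r_squared))
  } else {
    cat("Half-life fit: INVALID (non-negative decay slope)\n")
  }
  invisible(x)
}

#' @export
coef.half_life_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope, t_half = object$t_half)
}

#' @rdname fit_half_life
#' @param object a `half_life_fit`.
#' @param times minutes at which to predict the fitted (baseline-subtracted)
#'   intensity.
#' @param ... unused.
#' @export
predict.half_life_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$fit$model$t
  exp(object$intercept + object$slope * times)
}

#' Aggregate individual half-life estimates
#'
#' @param fits a list of `half_life_fit` objects (invalid fits are skipped
#'   with a warning).
#' @return A list with `mean` (min), `sem` (standard error of the mean; 0
#'   with `n = 1`), `n`, and the individual half-lives `t_half`.
#' @export
aggregate_half_life <- function(fits) {
  if (inherits(fits, "half_life_fit")) fits <- list(fits)
  valid <- vapply(fits, function(f) isTRUE(f$valid), logical(1L))
  if (any(!valid)) {
    warning(sprintf("dropping %d invalid half-life estimate(s)", sum(!valid)))
  }
  th <- vapply(fits[valid], function(f) f$t_half, numeric(1L))
  assert_that(length(th) >= 1L, "no valid half-life estimate to aggregate")
  list(mean = mean(th),
       sem = if (length(th) > 1L) sd(th) / sqrt(length(th)) else 0,
       n = length(th), t_half = th)
}

#' Trapezoidal area under a trace over a time window
#'
#' Used for normalized elimination-curve comparisons, where a larger AUC
#' indicates slower elimination (impaired excretory function).
#'
#' @param trace an [intensity_trace()].
#' @param window `c(start, end)` minutes; default spans the whole trace.
#' @param normalize if `TRUE`, divide the trace by its in-window maximum
#'   before integrating (used when absolute units differ between animals).
#' @return AUC in value x minutes.
#' @export
trace_auc <- function(trace, window = range(trace$time_min),
                      normalize = FALSE) {
  stopifnot(inherits(trace, "intensity_trace"))
  inw <- trace$time_min >= window[1L] & trace$time_min <= window[2L]
  assert_that(sum(inw) >= 2L, "need at least 2 in-window points")
  y <- trace$intensity[inw]
  if (normalize) {
    assert_that(max(y) > 0, "cannot normalize a non-positive trace")
    y <- y / max(y)
  }
  trapz(trace$time_min[inw], y)
}
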