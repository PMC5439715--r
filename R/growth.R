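#' Fit an exponential growth rate to a trajectory
#'
#' Ordinary least squares of `ln(value)` on time, restricted to points at or
#' above a size threshold. This mirrors the standard practice of fitting
#' xenograft volumes only above a detection threshold (200 mm^3 by convention),
#' so the lag/engraftment phase does not bias the rate. Duplicate time points
#' are averaged in log space before fitting.
#'
#' @param traj Data frame with columns `time` (days) and `value` (cell count
#'   or tumor volume, > 0).
#' @param min_value Threshold in the units of `value`; points below it are
#'   excluded. Default 200 (mm^3 convention for xenografts).
#' @return A `growth_fit` object: `rate` (1/day), `log_intercept`,
#'   `r_squared`, `doubling_time` (days; `NA` when rate <= 0), `n_points`.
#'   Supports [tidy()], [glance()], [ggplot2::autoplot()].
#' @examples
#' tr <- data.frame(time = 0:10, value = 100 * exp(0.2 * (0:10)))
#' fit_exponential_growth(tr, min_value = 0)
#' @export
fit_exponential_growth <- function(traj, min_value = 200) {
  traj <- as.data.frame(traj)
  if (!all(c("time", "value") %in% names(traj))) {
    stop("`traj` needs columns `time` and `value`", call. = FALSE)
  }
  keep <- stats::complete.cases(traj[, c("time", "value")])
  traj <- traj[keep, , drop = FALSE]
  if (any(traj$value <= 0)) {
    stop("`value` must be positive (log fit)", call. = FALSE)
  }
  pts <- traj[traj$value >= min_value, , drop = FALSE]
  pts <- dplyr::tibble(time = pts$time, logv = log(pts$value)) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(logv = mean(.data$logv), .groups = "drop")
  if (nrow(pts) < 3) {
    stop(sprintf(
      "insufficient data: %d point(s) at or above min_value = %g (need >= 3)",
      nrow(pts), min_value), call. = FALSE)
  }
  fit <- stats::lm(logv ~ time, data = pts)
  rate <- unname(stats::coef(fit)[["time"]])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((pts$logv - mean(pts$logv))^2)
  rsq <- if (tss <= .Machine$double.eps) 1 else 1 - rss / tss
  structure(
    list(
      rate = rate,
      log_intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r_squared = rsq,
      doubling_time = if (rate > 0) log(2) / rate else NA_real_,
      n_points = nrow(pts),
      min_value = min_value,
      data = pts
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Exponential growth fit\n")
  cat(sprintf("  rate = %.5g /day  (doubling time %.4g days)\n",
              x$rate, x$doubling_time))
  cat(sprintf("  R^2 = %.4f on %d points >= %g\n",
              x$r_squared, x$n_points, x$min_value))
  invisible(x)
}

#' @rdname fit_exponential_growth
#' @param x,object A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  dplyr::tibble(
    term = c("rate", "log_intercept"),
    estimate = c(x$rate, x$log_intercept)
  )
}

#' @rdname fit_exponential_growth
#' @export
glance.growth_fit <- function(x, ...) {
  dplyr::tibble(
    rate = x$rate, doubling_time = x$doubling_time,
    r.squared = x$r_squared, n.points = x$n_points,
    min_value = x$min_value
  )
}

#' @rdname fit_exponential_growth
#' @export
autoplot.growth_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$logv)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$log_intercept,
                         slope = object$rate, linetype = 2) +
    ggplot2::labs(x = "Time (days)", y = "ln(value)",
                  title = sprintf("Exponential fit: rate %.3g /day, R² %.3f",
                                  object$rate, object$r_squared))
}

#' Cumulative population doublings over serial passages
#'
#' For a serially passaged culture (harvested, counted, re-plated every few
#' days), each passage contributes `log2(harvested / plated)` doublings; the
#' cumulative sum tracks long-term proliferative capacity, and the
#' per-interval rate (doublings/day) shows suppression and recovery after an
#' insult such as irradiation.
#'
#' @param passages Data frame with columns `plated`, `harvested` (counts > 0)
#'   and `day` (strictly increasing; the day the passage was harvested).
#' @return A tibble with one row per passage: `day`, `doublings`,
#'   `cumulative_doublings`, `interval_days` (the first interval runs from
#'   day 0), `doubling_rate` (doublings/day).
#' @examples
#' cumulative_population_doublings(
#'   data.frame(plated = 1e5, harvested = 4e5, day = c(4, 8, 12))
#' )
#' @export
cumulative_population_doublings <- function(passages) {
  passages <- as.data.frame(passages)
  need <- c("plated", "harvested", "day")
  if (!all(need %in% names(passages))) {
    stop("`passages` needs columns plated, harvested, day", call. = FALSE)
  }
  if (any(passages$plated <= 0 | passages$harvested <= 0)) {
    stop("counts must be positive", call. = FALSE)
  }
  if (is.unsorted(passages$day, strictly = TRUE)) {
    stop("`day` must be strictly increasing", call. = FALSE)
  }
  dplyr::tibble(
    day = passages$day,
    doublings = log2(passages$harvested / passages$plated),
    cumulative_doublings = cumsum(.data$doublings),
    interval_days = c(passages$day[1], diff(passages$day)),
    doubling_rate = .data$doublings / .data$interval_days
  )
}
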