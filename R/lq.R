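#' Linear-quadratic surviving fraction
#'
#' Evaluates the linear-quadratic (LQ) model of clonogenic radiation survival,
#' \eqn{S(D) = \exp(-\alpha D - \beta D^2)}, the standard two-parameter
#' description of reproductive cell kill by single-track (\eqn{\alpha}) and
#' two-track (\eqn{\beta}) lesions.
#'
#' @param params An `lq_fit` object or a list/vector with elements `alpha`
#'   (1/Gy) and `beta` (1/Gy^2), both non-negative.
#' @param dose Radiation dose in Gy; vectorised, must be >= 0.
#' @return Numeric vector of surviving fractions in (0, 1].
#' @examples
#' lq_surviving_fraction(list(alpha = 0.335, beta = 0.0154), dose = c(0, 8))
#' @export
lq_surviving_fraction <- function(params, dose) {
  ab <- as_lq_params(params)
  if (!is.numeric(dose) || any(!is.finite(dose))) {
    stop("`dose` must be finite numeric (Gy)", call. = FALSE)
  }
  if (any(dose < 0)) stop("`dose` must be non-negative", call. = FALSE)
  exp(-ab[["alpha"]] * dose - ab[["beta"]] * dose^2)
}

as_lq_params <- function(params) {
  if (inherits(params, "lq_fit")) {
    return(c(alpha = params$alpha, beta = params$beta))
  }
  p <- unlist(params)
  if (!all(c("alpha", "beta") %in% names(p))) {
    stop("`params` must carry `alpha` and `beta`", call. = FALSE)
  }
  if (p[["alpha"]] < 0 || p[["beta"]] < 0) {
    stop("`alpha` and `beta` must be non-negative", call. = FALSE)
  }
  c(alpha = p[["alpha"]], beta = p[["beta"]])
}

new_lq_fit <- function(alpha, beta, method, data = NULL) {
  structure(
    list(alpha = alpha, beta = beta, method = method, data = data),
    class = "lq_fit"
  )
}

#' Fit the linear-quadratic survival model
#'
#' Estimates \eqn{(\alpha, \beta)} of \eqn{S(D)=\exp(-\alpha D - \beta D^2)}
#' from clonogenic-assay records. Two modes are exposed because published
#' survival pairs are often all that is available:
#'
#' * `method = "interpolate"`: exact solution of the 2x2 linear system in
#'   \eqn{-\ln S} through two distinct non-zero doses. With noise-free inputs
#'   this is an identity: re-evaluating the fitted curve at the input doses
#'   reproduces the input survivals to machine precision.
#' * `method = "least_squares"`: weighted least squares of \eqn{-\ln S} on
#'   \eqn{(D, D^2)} with the constraint \eqn{\alpha,\beta \ge 0}, weights equal
#'   to colony counts (Poisson-motivated). Requires >= 3 distinct non-zero
#'   doses.
#'
#' Surviving fractions are normalised to the plating efficiency estimated from
#' the 0 Gy records (pooled colonies / pooled cells plated), so S(0) = 1 by
#' construction: survival is the fraction of plated cells retaining clonogenic
#' capacity relative to the unirradiated control.
#'
#' @param records Data frame with columns `dose` (Gy), `cells_plated`,
#'   `colonies`; or columns `dose` and `survival` (already-normalised
#'   surviving fractions, accepted for `method = "interpolate"` and weighted
#'   equally for `least_squares`).
#' @param method `"interpolate"` or `"least_squares"`.
#' @return An `lq_fit` object with elements `alpha`, `beta`, `method` and the
#'   per-dose survival table used; supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @seealso [lq_surviving_fraction()], [gen_clonogenic()]
#' @examples
#' pts <- data.frame(dose = c(8, 16), survival = c(0.0255, 0.00009))
#' fit <- fit_lq(pts, method = "interpolate")
#' lq_surviving_fraction(fit, 8)
#' @export
fit_lq <- function(records, method = c("least_squares", "interpolate")) {
  method <- match.arg(method)
  records <- as.data.frame(records)

  if (all(c("dose", "survival") %in% names(records))) {
    surv <- dplyr::tibble(
      dose = records$dose,
      survival = records$survival,
      weight = if ("colonies" %in% names(records)) records$colonies else 1
    )
  } else if (all(c("dose", "cells_plated", "colonies") %in% names(records))) {
    if (any(records$colonies < 0 | records$colonies > records$cells_plated)) {
      stop("`colonies` must lie in [0, cells_plated]", call. = FALSE)
    }
    zero <- records$dose == 0
    if (!any(zero)) {
      stop("0 Gy records are required to estimate plating efficiency",
           call. = FALSE)
    }
    pe <- sum(records$colonies[zero]) / sum(records$cells_plated[zero])
    if (pe <= 0) stop("plating efficiency is zero at 0 Gy", call. = FALSE)
    surv <- records |>
      dplyr::filter(.data$dose > 0) |>
      dplyr::group_by(.data$dose) |>
      dplyr::summarise(
        survival = sum(.data$colonies) / (sum(.data$cells_plated) * pe),
        weight = sum(.data$colonies),
        expected_scale = sum(.data$cells_plated) * pe,
        .groups = "drop"
      )
  } else {
    stop("`records` needs (dose, cells_plated, colonies) or (dose, survival)",
         call. = FALSE)
  }

  surv <- dplyr::filter(surv, .data$dose > 0)
  if (method == "least_squares") {
    # a zero-colony dose has zero weight in the Poisson-motivated objective,
    # so it is dropped rather than breaking the log transform
    surv <- dplyr::filter(surv, .data$survival > 0)
  }
  if (nrow(surv) == 0 || any(surv$survival <= 0)) {
    stop("survival must be positive at every fitted dose (zero colonies at ",
         "some dose); pool replicates or drop the dose", call. = FALSE)
  }
  y <- -log(surv$survival)

  if (method == "interpolate") {
    d <- unique(surv$dose)
    if (length(d) != 2) {
      stop("`interpolate` needs exactly two distinct non-zero doses",
           call. = FALSE)
    }
    # collapse replicate survivals in log space per dose
    yy <- vapply(d, function(dd) mean(y[surv$dose == dd]), numeric(1))
    A <- cbind(d, d^2)
    if (abs(det(A)) < .Machine$double.eps * max(abs(A))^2) {
      stop("singular system: doses do not identify (alpha, beta)",
           call. = FALSE)
    }
    ab <- solve(A, yy)
    if (any(ab < 0)) {
      warning("interpolated parameters not both non-negative; ",
              "returning the exact solution unclamped")
    }
    return(new_lq_fit(ab[[1]], ab[[2]], "interpolate", surv))
  }

  if (length(unique(surv$dose)) < 3) {
    stop("`least_squares` needs >= 3 distinct non-zero doses", call. = FALSE)
  }
  X <- cbind(D = surv$dose, D2 = surv$dose^2)
  w <- pmax(surv$weight, .Machine$double.eps)
  ab <- nnls_2col(X, y, w)
  if (!is.null(surv$expected_scale)) {
    # Fisher-scoring reweighting: replace observed-count weights by the
    # expected colony counts under the current fit. Using observed counts as
    # weights correlates weight with response and biases S upward; two
    # reweighted passes remove that.
    for (i in 1:2) {
      w <- pmax(surv$expected_scale *
                  exp(-(ab[[1]] * surv$dose + ab[[2]] * surv$dose^2)),
                .Machine$double.eps)
      ab <- nnls_2col(X, y, w)
    }
  }
  new_lq_fit(ab[[1]], ab[[2]], "least_squares", surv)
}

# Active-set non-negative weighted least squares for the two-column LQ design.
nnls_2col <- function(X, y, w) {
  wls <- function(cols) {
    XtWX <- crossprod(X[, cols, drop = FALSE] * w, X[, cols, drop = FALSE])
    XtWy <- crossprod(X[, cols, drop = FALSE] * w, y)
    drop(solve(XtWX, XtWy))
  }
  b <- wls(c(1, 2))
  if (all(b >= 0)) return(b)
  # clamp each coefficient in turn, keep the feasible fit with lower RSS
  cand <- list(c(max(0, wls(1)), 0), c(0, max(0, wls(2))), c(0, 0))
  rss <- vapply(cand, function(bb) sum(w * (y - X %*% bb)^2), numeric(1))
  cand[[which.min(rss)]]
}

#' @export
print.lq_fit <- function(x, ...) {
  cat("Linear-quadratic survival fit (", x$method, ")\n", sep = "")
  cat(sprintf("  alpha = %.6g 1/Gy\n  beta  = %.6g 1/Gy^2\n", x$alpha, x$beta))
  if (!is.null(x$data)) {
    cat(sprintf("  fitted on %d dose point(s)\n", nrow(x$data)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_lq
#' @param x,object An `lq_fit` object.
#' @param ... Unused.
#' @export
tidy.lq_fit <- function(x, ...) {
  dplyr::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    unit = c("1/Gy", "1/Gy^2")
  )
}

#' @rdname fit_lq
#' @export
glance.lq_fit <- function(x, ...) {
  rsq <- NA_real_
  if (!is.null(x$data) && nrow(x$data) > 2) {
    y <- -log(x$data$survival)
    yhat <- x$alpha * x$data$dose + x$beta * x$data$dose^2
    rsq <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }
  dplyr::tibble(
    alpha = x$alpha, beta = x$beta, method = x$method,
    r.squared = rsq, n.doses = if (is.null(x$data)) NA_integer_
    else nrow(x$data)
  )
}

#' @rdname fit_lq
#' @param max_dose Upper end of the dose axis for the plotted curve (Gy).
#' @export
autoplot.lq_fit <- function(object, max_dose = NULL, ...) {
  if (is.null(max_dose)) {
    max_dose <- if (is.null(object$data)) 16 else max(object$data$dose) * 1.1
  }
  curve <- dplyr::tibble(dose = seq(0, max_dose, length.out = 200)) |>
    dplyr::mutate(survival = lq_surviving_fraction(object, .data$dose))
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$dose, y = .data$survival)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dose (Gy)", y = "Surviving fraction",
                  title = "Linear-quadratic clonogenic survival")
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(data = object$data)
  }
  p
}
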