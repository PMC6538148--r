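#' Ordinary least-squares line fit of a normalized growth curve
#'
#' Fits `y = p1 * x + p2` by OLS.
#'
#' @param curve A `"normalized_curve"` (see [normalize_curve()]) or any list
#'   with `norm_times` and `norm_volumes`.
#' @return List with `p1`, `p2`, `sse`.
#' @export
fit_linear <- function(curve) {
  x <- curve$norm_times; y <- curve$norm_volumes
  if (length(unique(x)) < 2L)
    stop("need at least 2 distinct time points for a line fit", call. = FALSE)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  list(p1 = unname(cf[2L]), p2 = unname(cf[1L]),
       sse = sum(stats::residuals(fit)^2))
}

# Multi-start candidates for the exponential fit. exp1 is sensitive to its
# starting point; the log-slope start is exact on noise-free exponentials,
# the others rescue curves with non-positive values or near-flat data.
.exp_starts <- function(x, y) {
  starts <- list()
  pos <- y > 0
  if (sum(pos) >= 2L) {
    lf <- stats::lm(log(y[pos]) ~ x[pos])
    starts[[length(starts) + 1L]] <- c(a = exp(unname(stats::coef(lf)[1L])),
                                       b = unname(stats::coef(lf)[2L]))
  }
  a0 <- if (!is.na(y[1L]) && y[1L] > 0) y[1L] else 1e-6
  starts[[length(starts) + 1L]] <- c(a = a0, b = 1)
  starts[[length(starts) + 1L]] <- c(a = max(y, 1e-6), b = 1)
  starts[[length(starts) + 1L]] <- c(a = 0.01, b = 3)
  starts
}

#' Nonlinear least-squares exponential fit
#'
#' Fits `y = a * exp(b * x)` by Levenberg-Marquardt least squares with
#' multi-start initialization (log-linear slope start plus fixed fallbacks);
#' the converged candidate with the smallest sum of squared errors wins.
#' Fitting is in the original space — no log transform — so curves with
#' non-positive normalized volumes are admissible.
#'
#' @param curve As in [fit_linear()]; at least 3 points.
#' @return List with `a`, `b`, `sse`.
#' @export
fit_exponential <- function(curve) {
  x <- curve$norm_times; y <- curve$norm_volumes
  if (length(x) < 3L)
    stop("need at least 3 points for the exponential fit", call. = FALSE)
  best <- NULL
  for (st in .exp_starts(x, y)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = list(a = st[["a"]], b = st[["b"]]),
                         fn = function(p) y - p$a * exp(p$b * x),
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.finite(sse) && (is.null(best) || sse < best$sse - 1e-10))
      best <- list(a = fit$par$a, b = fit$par$b, sse = sse)
  }
  if (is.null(best))
    stop("exponential fit failed to converge from all starts", call. = FALSE)
  best
}

#' Classify growth kinetics as linear or exponential
#'
#' A curve is called exponential when its nonlinear sum of squared errors is
#' strictly less than 0.6 times the linear one; the 0.6 factor was chosen so
#' that curves passing it fit the exponential model with r^2 > 0.85.
#'
#' @param sse_lin,sse_exp Non-negative sums of squared errors of the linear
#'   and exponential fits.
#' @param factor The selection factor (default 0.6).
#' @return `"exponential"` or `"linear"`.
#' @export
#' @examples
#' classify_curve(1.0, 0.5)  # exponential
#' classify_curve(1.0, 0.7)  # linear
classify_curve <- function(sse_lin, sse_exp, factor = 0.6) {
  if (sse_lin < 0 || sse_exp < 0)
    stop("sums of squares must be non-negative", call. = FALSE)
  if (sse_exp < factor * sse_lin) "exponential" else "linear"
}

#' Fit both growth models to one normalized curve
#'
#' Runs [fit_linear()] and [fit_exponential()], classifies the curve via
#' [classify_curve()], and reports the r^2 of the selected model.
#'
#' @inheritParams fit_linear
#' @param factor Selection factor passed to [classify_curve()].
#' @return A list of class `"growth_fit"`: `p1`, `p2`, `a`, `b`, `sse_lin`,
#'   `sse_exp`, `classification`, `r2`, `case_id`.
#' @export
growth_fit <- function(curve, factor = 0.6) {
  lin <- fit_linear(curve)
  ex <- fit_exponential(curve)
  cls <- classify_curve(lin$sse, ex$sse, factor)
  y <- curve$norm_volumes
  sstot <- sum((y - mean(y))^2)
  sse_sel <- if (cls == "exponential") ex$sse else lin$sse
  r2 <- if (sstot > 0) 1 - sse_sel / sstot else NA_real_
  structure(list(p1 = lin$p1, p2 = lin$p2, a = ex$a, b = ex$b,
                 sse_lin = lin$sse, sse_exp = ex$sse,
                 classification = cls, r2 = r2,
                 case_id = curve$case_id %||% NA_character_),
            class = "growth_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pooled exponential fit over several normalized curves
#'
#' Pools every (normalized time, normalized volume) point of the supplied
#' curves into one regression and fits the single exponential model
#' `y = a * exp(b * x)`.
#'
#' @param curves List of `"normalized_curve"` objects (at least one).
#' @return List of class `"pooled_fit"`: `a`, `b`, `sse`, `r2`, `n_curves`,
#'   `n_points`.
#' @export
pooled_fit <- function(curves) {
  if (length(curves) < 1L) stop("need at least one curve", call. = FALSE)
  x <- unlist(lapply(curves, `[[`, "norm_times"))
  y <- unlist(lapply(curves, `[[`, "norm_volumes"))
  fit <- fit_exponential(list(norm_times = x, norm_volumes = y))
  sstot <- sum((y - mean(y))^2)
  structure(list(a = fit$a, b = fit$b, sse = fit$sse,
                 r2 = if (sstot > 0) 1 - fit$sse / sstot else NA_real_,
                 n_curves = length(curves), n_points = length(x)),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("<pooled_fit> y = %.5g * exp(%.4g x) over %d curves (%d points), sse %.4g, r2 %.4f\n",
              x$a, x$b, x$n_curves, x$n_points, x$sse, x$r2))
  invisible(x)
}
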