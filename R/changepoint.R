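#' Change-point detector configuration
#'
#' The detector penalizes each accepted change point by
#' `threshold_numerator / v0`, where `v0` is the case's baseline volume. The
#' default numerator of 500 equals 5% of the rounded median baseline volume
#' (10,000 pixel^3) of the cohort the method was calibrated on, so a typical
#' case pays a penalty of 0.05 per change point. Every segment must contain at
#' least `min_segment` samples.
#'
#' @param threshold_numerator Positive scalar; per-change-point penalty is
#'   `threshold_numerator / v0`. Default 500.
#' @param min_segment Minimum samples per segment (default 2).
#' @param cost_statistic Segment cost functional: `"rms_log"` (default), the
#'   segment length times the log mean square — a change in the
#'   root-mean-square level — or `"mean_shift"`, the within-segment sum of
#'   squares about the mean.
#' @return A list of class `"cp_config"`.
#' @export
cp_config <- function(threshold_numerator = 500, min_segment = 2L,
                      cost_statistic = c("rms_log", "mean_shift")) {
  cost_statistic <- match.arg(cost_statistic)
  if (!is.numeric(threshold_numerator) || threshold_numerator <= 0)
    stop("`threshold_numerator` must be positive", call. = FALSE)
  min_segment <- as.integer(min_segment)
  if (min_segment < 1L) stop("`min_segment` must be >= 1", call. = FALSE)
  structure(list(threshold_numerator = threshold_numerator,
                 min_segment = min_segment,
                 cost_statistic = cost_statistic),
            class = "cp_config")
}

#' Cost of fitting one segment at a constant statistical level
#'
#' For `"rms_log"` the cost of a segment `x` of length `n` is
#' `n * log(mean(x^2))`: splitting a series at a change in the
#' root-mean-square level lowers the summed cost. For `"mean_shift"` it is the
#' residual sum of squares about the segment mean.
#'
#' @param x Nonempty numeric vector; strictly positive under `"rms_log"`.
#' @param statistic `"rms_log"` or `"mean_shift"`.
#' @return Scalar cost.
#' @export
#' @examples
#' segment_cost(c(1, 1, 1, 1))            # 0
#' segment_cost(c(2, 2, 2))               # 3 * log 4
segment_cost <- function(x, statistic = c("rms_log", "mean_shift")) {
  statistic <- match.arg(statistic)
  if (length(x) == 0L) stop("empty segment", call. = FALSE)
  if (statistic == "rms_log") {
    if (any(x <= 0)) stop("rms_log cost requires positive values", call. = FALSE)
    length(x) * log(mean(x^2))
  } else {
    sum((x - mean(x))^2)
  }
}

# Segment-cost lookup C[i, j] = cost of x[i..j] for all admissible segments,
# from cumulative sums (O(n^2) total).
.cost_table <- function(x, statistic) {
  n <- length(x)
  cs2 <- cumsum(x^2)
  cs1 <- cumsum(x)
  C <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    j <- i:n
    len <- j - i + 1
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    if (statistic == "rms_log") {
      C[i, j] <- len * log(s2 / len)
    } else {
      s1 <- cs1[j] - if (i > 1) cs1[i - 1] else 0
      C[i, j] <- s2 - s1^2 / len
    }
  }
  C
}

#' Offline penalized change-point detection
#'
#' Finds the set of change points minimizing the total segment cost plus a
#' penalty of `threshold_numerator / v0` per change point, subject to every
#' segment holding at least `min_segment` samples. Solved exactly by dynamic
#' programming (series are tens of scans long), so a split is accepted only
#' when it improves the residual cost by more than the penalty.
#'
#' @param x Numeric vector: the volume subsequence from the baseline scan to
#'   the current visit, inclusive. Must be positive under the `"rms_log"`
#'   statistic.
#' @param v0 Baseline volume (pixel^3), positive; sets the penalty scale.
#' @param config A [cp_config()].
#' @return Integer vector of change-point positions, each the 1-based index in
#'   `x` of the first sample of a new segment, in increasing order; empty when
#'   no split improves the penalized objective (including when
#'   `length(x) < 2 * min_segment`, where no split is feasible).
#' @export
#' @examples
#' x <- c(10000, 10000, 10000, 20000, 20000, 20000)
#' detect_changepoints(x, v0 = 10000)  # 4: the step onset
detect_changepoints <- function(x, v0, config = cp_config()) {
  stopifnot(inherits(config, "cp_config"))
  if (!is.numeric(v0) || length(v0) != 1L || v0 <= 0)
    stop("`v0` must be a positive scalar", call. = FALSE)
  n <- length(x)
  m <- config$min_segment
  if (n < 2L * m) return(integer(0))
  if (config$cost_statistic == "rms_log" && any(x <= 0))
    stop("volumes must be positive for the rms_log statistic", call. = FALSE)
  pen <- config$threshold_numerator / v0
  C <- .cost_table(x, config$cost_statistic)

  # F[t + 1]: optimal penalized cost of x[1..t]; prev[t + 1]: argmin boundary
  F <- rep(Inf, n + 1L)
  prev <- integer(n + 1L)
  F[1L] <- -pen
  for (t in seq_len(n)) {
    if (t < m) next
    starts <- c(0L, seq_len(t - 1L))           # segment x[(s+1)..t]
    starts <- starts[t - starts >= m & (starts == 0L | starts >= m)]
    cand <- F[starts + 1L] + C[cbind(starts + 1L, t)] + pen
    k <- which.min(cand)
    F[t + 1L] <- cand[k]
    prev[t + 1L] <- starts[k]
  }
  # backtrack boundaries
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    s <- prev[t + 1L]
    if (s > 0L) cps <- c(s + 1L, cps)
    t <- s
  }
  cps
}

#' Online growth detection simulating clinic visits
#'
#' Sweeps the visits in time order starting at the baseline scan; at each
#' visit the offline detector is run on the volumes observed so far only
#' (past measurements — what a physician has in clinic). The first visit at
#' which a change point appears is the alert visit; the time to growth (TTG)
#' is the interval from the baseline scan to the first change-point sample as
#' localized at that visit, and the volume change at detection is the
#' fractional change from baseline to that sample. The change-point location
#' is frozen at the alert visit; re-estimation on the full series is available
#' via [detect_changepoints()].
#'
#' @param series A [volume_series()].
#' @param baseline A `"baseline_result"`; computed via [find_baseline()] if
#'   omitted.
#' @param config A [cp_config()].
#' @return A list of class `"detection_result"`: `detected` (logical),
#'   `alert_visit` and `changepoint_index` (1-based indices into the full
#'   series; `NA` if undetected), `ttg_months`, `delta_v` (fraction),
#'   `baseline_index`, `v0`, `case_id`.
#' @export
detect_growth_online <- function(series, baseline = find_baseline(series),
                                 config = cp_config()) {
  stopifnot(inherits(series, "volume_series"))
  b <- baseline$baseline_index
  v0 <- baseline$v0
  vols <- series$volumes[b:length(series$volumes)]
  m <- config$min_segment
  res <- list(detected = FALSE, alert_visit = NA_integer_,
              changepoint_index = NA_integer_, ttg_months = NA_real_,
              delta_v = NA_real_, baseline_index = b, v0 = v0,
              case_id = series$case_id)
  if (length(vols) >= 2L * m) {
    for (w in (2L * m):length(vols)) {
      cps <- detect_changepoints(vols[seq_len(w)], v0, config)
      if (length(cps) > 0L) {
        cp <- b + cps[1L] - 1L
        res$detected <- TRUE
        res$alert_visit <- b + w - 1L
        res$changepoint_index <- cp
        res$ttg_months <- series$times[cp] - series$times[b]
        res$delta_v <- percent_change(series$volumes[cp], v0)
        break
      }
    }
  }
  structure(res, class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(paste0("<detection_result> case %s: growth detected at visit %d",
                       " (change point at sample %d), TTG %.1f months, dV %+.0f%%\n"),
                x$case_id, x$alert_visit, x$changepoint_index,
                x$ttg_months, 100 * x$delta_v))
  } else {
    cat(sprintf("<detection_result> case %s: stable (no change point)\n", x$case_id))
  }
  invisible(x)
}

#' Run the online detector over a cohort
#'
#' @param cases A list of [volume_series()] objects.
#' @param config A [cp_config()].
#' @return A named list of `"detection_result"` objects (names are case ids).
#' @export
detect_cohort <- function(cases, config = cp_config()) {
  out <- lapply(cases, detect_growth_online, config = config)
  names(out) <- vapply(cases, function(s) s$case_id, character(1))
  out
}
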