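#' Longitudinal tumor-volume series
#'
#' Constructs the pipeline's central record: one case's time-ordered tumor
#' volumes with clinical annotations. Times are months from the first scan;
#' volumes are in cubic pixels (the canonical unit of the volumetry: per-slice
#' pixel counts times the inter-slice distance).
#'
#' @param case_id Opaque case identifier (coerced to character).
#' @param times Numeric vector of months from the first scan, strictly
#'   increasing, all `>= 0`.
#' @param volumes Numeric vector of tumor volumes (pixel^3), all positive,
#'   same length as `times`.
#' @param pathology One of `"oligodendroglioma"`, `"astrocytoma"`, `"mixed"`,
#'   `"imaging_abnormality"`, or `NA` when unknown.
#' @param group Surveillance group: `"progression"`, `"stable"`,
#'   `"imaging_abnormality"`, or `NA`.
#' @param had_resection Logical; `TRUE` if the tumor was surgically resected
#'   (the baseline rule then searches for the first post-operative minimum).
#' @param vc_detection_time Months at which growth was called by visual
#'   comparison of the radiology reports, or `NA` if never / unknown. This is
#'   clinical annotation data, never recomputed.
#' @param earliest_baseline_time Optional earliest time (months) the baseline
#'   may be placed, e.g. the completion of temozolomide chemotherapy; `NA`
#'   for no constraint.
#'
#' @return An object of class `"volume_series"`.
#' @seealso [find_baseline()], [normalize_curve()], [detect_growth_online()]
#' @export
#' @examples
#' vs <- volume_series("case1", times = c(0, 4, 9, 14),
#'                     volumes = c(12000, 9000, 9500, 15000),
#'                     had_resection = TRUE)
#' find_baseline(vs)
volume_series <- function(case_id, times, volumes,
                          pathology = NA_character_,
                          group = NA_character_,
                          had_resection = FALSE,
                          vc_detection_time = NA_real_,
                          earliest_baseline_time = NA_real_) {
  times <- as.numeric(times)
  volumes <- as.numeric(volumes)
  if (length(times) != length(volumes))
    stop("`times` and `volumes` must have the same length", call. = FALSE)
  if (length(times) < 1L)
    stop("a volume series needs at least one scan", call. = FALSE)
  if (anyNA(times) || anyNA(volumes))
    stop("`times` and `volumes` must not contain NA", call. = FALSE)
  if (any(times < 0))
    stop("times are months from the first scan and must be >= 0", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(volumes <= 0))
    stop("`volumes` must be positive", call. = FALSE)
  if (!is.na(pathology))
    pathology <- match.arg(pathology, c("oligodendroglioma", "astrocytoma",
                                        "mixed", "imaging_abnormality"))
  if (!is.na(group))
    group <- match.arg(group, c("progression", "stable", "imaging_abnormality"))
  structure(
    list(case_id = as.character(case_id), times = times, volumes = volumes,
         pathology = pathology, group = group,
         had_resection = isTRUE(had_resection),
         vc_detection_time = as.numeric(vc_detection_time),
         earliest_baseline_time = as.numeric(earliest_baseline_time)),
    class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series> case %s: %d scans over %.1f months%s\n",
              x$case_id, length(x$times), diff(range(x$times)),
              if (isTRUE(x$had_resection)) " (post-resection)" else ""))
  if (!is.na(x$group)) cat("  group:", x$group,
                           if (!is.na(x$pathology)) paste0("(", x$pathology, ")") else "",
                           "\n")
  invisible(x)
}

#' Whether a series meets the minimum-scan inclusion criterion
#'
#' Analysis requires at least 4 MRI scans per case.
#'
#' @param series A [volume_series()].
#' @param min_scans Minimum number of scans (default 4).
#' @return Logical scalar.
#' @export
meets_inclusion <- function(series, min_scans = 4L) {
  stopifnot(inherits(series, "volume_series"))
  length(series$times) >= min_scans
}

#' Determine the baseline scan of a volume series
#'
#' For resected tumors the baseline is the first volume minimum after surgery:
#' the earliest scan that is not exceeded downward by any earlier scan
#' (a running minimum) and that is immediately followed by a strict volume
#' increase. This excludes FLAIR changes still resolving post-operatively.
#' A plateau at the minimum resolves to its last point before the rise; a
#' series that never rises again resolves to its final point. Tumors never
#' resected (e.g. the imaging-abnormality group) use the first scan.
#'
#' When `earliest_baseline_time` is set on the series (patients whose follow-up
#' starts after completing chemotherapy), the search is restricted to scans at
#' or after that time.
#'
#' @param series A [volume_series()].
#' @return A list of class `"baseline_result"` with `baseline_index` (1-based
#'   position in the series), `v0` (baseline volume, pixel^3) and
#'   `baseline_time` (months).
#' @export
#' @examples
#' vs <- volume_series("a", c(0, 3, 7, 11, 15), c(50, 30, 20, 25, 40) * 1000,
#'                     had_resection = TRUE)
#' find_baseline(vs)  # third scan, v0 = 20000
find_baseline <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  v <- series$volumes
  t <- series$times
  first <- 1L
  if (!is.na(series$earliest_baseline_time)) {
    ok <- which(t >= series$earliest_baseline_time)
    if (length(ok) == 0L)
      stop("no scans at or after `earliest_baseline_time`", call. = FALSE)
    first <- ok[1L]
  }
  idx <- first
  if (isTRUE(series$had_resection)) {
    v_sub <- v[first:length(v)]
    n <- length(v_sub)
    pick <- n  # fall back to the last scan if the series never rises
    for (i in seq_len(n)) {
      is_running_min <- i == 1L || all(v_sub[seq_len(i - 1L)] >= v_sub[i])
      rises_next <- i < n && v_sub[i + 1L] > v_sub[i]
      if (is_running_min && rises_next) { pick <- i; break }
    }
    idx <- first + pick - 1L
  }
  structure(list(baseline_index = idx, v0 = v[idx], baseline_time = t[idx]),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result> scan %d: v0 = %.0f px^3 at month %.1f\n",
              x$baseline_index, x$v0, x$baseline_time))
  invisible(x)
}

#' Fractional volume change from baseline
#'
#' @param v Volume at the time point of interest (pixel^3).
#' @param v0 Baseline volume (pixel^3), must be positive.
#' @return `(v - v0) / v0`, a dimensionless fraction (0.5 = +50%).
#' @export
percent_change <- function(v, v0) {
  if (any(v0 <= 0)) stop("baseline volume must be positive", call. = FALSE)
  (v - v0) / v0
}

#' Normalize a growth curve for model fitting
#'
#' Drops scans before the baseline, then maps volumes to
#' `(v - v0) / v_last` (baseline exactly 0; negative values allowed for
#' shrinking series) and times to `(t - t_baseline) / (t_last - t_baseline)`
#' (last scan exactly 1).
#'
#' @param series A [volume_series()].
#' @param baseline A `"baseline_result"` from [find_baseline()]; computed if
#'   omitted.
#' @return A list of class `"normalized_curve"` with `norm_times`,
#'   `norm_volumes` and the originating `case_id`.
#' @export
normalize_curve <- function(series, baseline = find_baseline(series)) {
  stopifnot(inherits(series, "volume_series"))
  b <- baseline$baseline_index
  t <- series$times[b:length(series$times)]
  v <- series$volumes[b:length(series$volumes)]
  if (length(t) < 2L)
    stop("need at least 2 scans at/after baseline to normalize", call. = FALSE)
  span <- t[length(t)] - t[1L]
  if (span <= 0)
    stop("all times equal after baseline; cannot normalize", call. = FALSE)
  v_last <- v[length(v)]
  structure(list(norm_times = (t - t[1L]) / span,
                 norm_volumes = (v - v[1L]) / v_last,
                 case_id = series$case_id),
            class = "normalized_curve")
}
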