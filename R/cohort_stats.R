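#' Two-tailed Mann-Whitney-Wilcoxon p-value
#'
#' Exact-distribution p-value when the combined sample size is at most 20 and
#' there are no ties; normal approximation (with tie and continuity
#' correction) otherwise. Thin wrapper over [stats::wilcox.test()] fixing
#' those conventions.
#'
#' @param x,y Nonempty numeric samples.
#' @return Two-tailed p-value in (0, 1].
#' @export
#' @examples
#' mann_whitney_p(1:3, 4:6)  # 0.1
mann_whitney_p <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 20L
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)$p.value)
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation ([stats::quantile()] type 7, the common
#' statistical default); the convention is configurable because published
#' tables rarely state theirs.
#'
#' @param values Nonempty numeric vector.
#' @param type Quantile algorithm (see [stats::quantile()]).
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values, type = 7) {
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = type, names = FALSE)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}

# "14 (11-20)" display used by the report writers
.fmt_med_iqr <- function(m, digits = 0, pct = FALSE) {
  if (anyNA(m)) return("NA")
  s <- function(v) formatC(v * if (pct) 100 else 1, format = "f", digits = digits)
  sprintf("%s%s (%s%s-%s%s)", s(m[1L]), if (pct) "%" else "",
          s(m[2L]), if (pct) "%" else "", s(m[3L]), if (pct) "%" else "")
}

.fmt_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) "<0.001" else formatC(p, format = "f", digits = 3)
}

# per-pathology summary rows for the progression group
.progression_rows <- function(cases, detections) {
  per_case <- lapply(cases, function(s) {
    d <- detections[[s$case_id]]
    vc_t <- s$vc_detection_time
    b <- find_baseline(s)
    vc_ttg <- NA_real_; vc_dv <- NA_real_
    if (!is.na(vc_t)) {
      vc_ttg <- vc_t - b$baseline_time
      at <- which(s$times >= vc_t)
      if (length(at) > 0L)
        vc_dv <- percent_change(s$volumes[at[1L]], b$v0)
    } else {
      warning(sprintf("case %s: no visual-comparison annotation; excluded from dG and VC columns",
                      s$case_id), call. = FALSE)
    }
    data.frame(pathology = s$pathology,
               detected = d$detected,
               ttg_cad = if (d$detected) d$ttg_months else NA_real_,
               dv_cad = if (d$detected) d$delta_v else NA_real_,
               ttg_vc = vc_ttg, dv_vc = vc_dv,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, per_case)
  groups <- c(split(df, df$pathology), list(all = df))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    cad <- d[d$detected, , drop = FALSE]
    vc <- d[!is.na(d$ttg_vc), , drop = FALSE]
    both <- d[d$detected & !is.na(d$ttg_vc), , drop = FALSE]
    ttg_cad <- if (nrow(cad)) median_iqr(cad$ttg_cad) else rep(NA_real_, 3)
    ttg_vc <- if (nrow(vc)) median_iqr(vc$ttg_vc) else rep(NA_real_, 3)
    dv_cad <- if (nrow(cad)) median_iqr(cad$dv_cad) else rep(NA_real_, 3)
    dv_vc <- if (nrow(vc) && !all(is.na(vc$dv_vc))) {
      median_iqr(vc$dv_vc[!is.na(vc$dv_vc)])
    } else rep(NA_real_, 3)
    p_ttg <- if (nrow(cad) && nrow(vc)) mann_whitney_p(cad$ttg_cad, vc$ttg_vc) else NA_real_
    p_dv <- if (nrow(cad) && sum(!is.na(vc$dv_vc))) {
      mann_whitney_p(cad$dv_cad, vc$dv_vc[!is.na(vc$dv_vc)])
    } else NA_real_
    data.frame(pathology = g, n = nrow(d),
               delta_g = sum(both$ttg_cad < both$ttg_vc),
               ttg_cad_median = ttg_cad[1L], ttg_cad_q1 = ttg_cad[2L], ttg_cad_q3 = ttg_cad[3L],
               ttg_vc_median = ttg_vc[1L], ttg_vc_q1 = ttg_vc[2L], ttg_vc_q3 = ttg_vc[3L],
               p_ttg = p_ttg,
               dv_cad_median = dv_cad[1L], dv_cad_q1 = dv_cad[2L], dv_cad_q3 = dv_cad[3L],
               dv_vc_median = dv_vc[1L], dv_vc_q1 = dv_vc[2L], dv_vc_q3 = dv_vc[3L],
               p_dv = p_dv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-pathology rows for the clinically stable group: CAD-only columns plus
# follow-up intervals of the CAD-growth and CAD-stable subsets
.stable_rows <- function(cases, detections) {
  per_case <- lapply(cases, function(s) {
    d <- detections[[s$case_id]]
    b <- find_baseline(s)
    data.frame(pathology = s$pathology, detected = d$detected,
               ttg_cad = if (d$detected) d$ttg_months else NA_real_,
               dv_cad = if (d$detected) d$delta_v else NA_real_,
               fu = s$times[length(s$times)] - b$baseline_time,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, per_case)
  groups <- c(split(df, df$pathology), list(all = df))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    grown <- d[d$detected, , drop = FALSE]
    still <- d[!d$detected, , drop = FALSE]
    ttg <- if (nrow(grown)) median_iqr(grown$ttg_cad) else rep(NA_real_, 3)
    dv <- if (nrow(grown)) median_iqr(grown$dv_cad) else rep(NA_real_, 3)
    fug <- if (nrow(grown)) median_iqr(grown$fu) else rep(NA_real_, 3)
    fus <- if (nrow(still)) median_iqr(still$fu) else rep(NA_real_, 3)
    data.frame(pathology = g, n = nrow(d), cad_g = nrow(grown),
               ttg_cad_median = ttg[1L], ttg_cad_q1 = ttg[2L], ttg_cad_q3 = ttg[3L],
               fu_g_median = fug[1L], fu_g_q1 = fug[2L], fu_g_q3 = fug[3L],
               fu_s_median = fus[1L], fu_s_q1 = fus[2L], fu_s_q3 = fus[3L],
               dv_cad_median = dv[1L], dv_cad_q1 = dv[2L], dv_cad_q3 = dv[3L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  grown <- df[df$detected, , drop = FALSE]
  attr(out, "p_ttg_vs_fu") <- if (nrow(grown) > 0L)
    mann_whitney_p(grown$ttg_cad, grown$fu) else NA_real_
  out
}

#' Cohort summary statistics
#'
#' Groups the cases by surveillance group and pathology and computes the
#' comparative statistics of the study design: for the clinical-progression
#' group, per-pathology (plus "all") counts, the number of cases where
#' computer-assisted detection preceded the visual-comparison call (`delta_g`),
#' median (IQR) time to growth and fractional volume change at detection for
#' both arms, and two-tailed Mann-Whitney-Wilcoxon p-values; for the
#' clinically stable group, CAD-only detection counts, TTG, follow-up
#' intervals of the grown/stable subsets, and volume change; for the
#' imaging-abnormality group, detection counts only.
#'
#' Cases in the progression group lacking a visual-comparison annotation are
#' excluded (with a warning) from `delta_g` and the VC columns. CAD medians
#' are over CAD-detected cases, since undetected cases carry no TTG.
#'
#' @param cases List of [volume_series()] objects.
#' @param detections Named list of `"detection_result"` objects from
#'   [detect_cohort()]; computed with the default [cp_config()] if omitted.
#' @return An object of class `"cohort_stats"`: data frames `progression` and
#'   `stable` (rows per pathology present plus `"all"`; empty groups omitted)
#'   and a list `imaging_abnormality` with `n` and `n_detected`.
#' @export
cohort_summary <- function(cases, detections = detect_cohort(cases)) {
  grp <- vapply(cases, function(s) s$group, character(1))
  if (anyNA(grp))
    stop("every case needs a `group` annotation for the cohort summary", call. = FALSE)
  prog <- cases[grp == "progression"]
  stab <- cases[grp == "stable"]
  abn <- cases[grp == "imaging_abnormality"]
  out <- list(
    progression = if (length(prog)) .progression_rows(prog, detections) else NULL,
    stable = if (length(stab)) .stable_rows(stab, detections) else NULL,
    imaging_abnormality = list(
      n = length(abn),
      n_detected = sum(vapply(abn, function(s) detections[[s$case_id]]$detected,
                              logical(1)))))
  structure(out, class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  if (!is.null(x$progression)) {
    cat("Clinical progression group\n")
    p <- x$progression
    for (i in seq_len(nrow(p))) {
      cat(sprintf("  %-22s n=%2d dG=%2d  TTG CAD %s vs VC %s (p %s)  dV CAD %s vs VC %s (p %s)\n",
                  p$pathology[i], p$n[i], p$delta_g[i],
                  .fmt_med_iqr(unlist(p[i, c("ttg_cad_median", "ttg_cad_q1", "ttg_cad_q3")])),
                  .fmt_med_iqr(unlist(p[i, c("ttg_vc_median", "ttg_vc_q1", "ttg_vc_q3")])),
                  .fmt_p(p$p_ttg[i]),
                  .fmt_med_iqr(unlist(p[i, c("dv_cad_median", "dv_cad_q1", "dv_cad_q3")]), pct = TRUE),
                  .fmt_med_iqr(unlist(p[i, c("dv_vc_median", "dv_vc_q1", "dv_vc_q3")]), pct = TRUE),
                  .fmt_p(p$p_dv[i])))
    }
  }
  if (!is.null(x$stable)) {
    cat("Clinically stable group\n")
    s <- x$stable
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-22s n=%2d CAD G=%2d  TTG %s  FU G %s  FU S %s  dV %s\n",
                  s$pathology[i], s$n[i], s$cad_g[i],
                  .fmt_med_iqr(unlist(s[i, c("ttg_cad_median", "ttg_cad_q1", "ttg_cad_q3")])),
                  .fmt_med_iqr(unlist(s[i, c("fu_g_median", "fu_g_q1", "fu_g_q3")])),
                  .fmt_med_iqr(unlist(s[i, c("fu_s_median", "fu_s_q1", "fu_s_q3")])),
                  .fmt_med_iqr(unlist(s[i, c("dv_cad_median", "dv_cad_q1", "dv_cad_q3")]), pct = TRUE)))
    }
  }
  if (x$imaging_abnormality$n > 0L)
    cat(sprintf("Imaging abnormality group: growth detected in %d of %d\n",
                x$imaging_abnormality$n_detected, x$imaging_abnormality$n))
  invisible(x)
}
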