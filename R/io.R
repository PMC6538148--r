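#' Read a longitudinal volume table with case annotations
#'
#' The canonical on-disk format is two comma-separated tables with header
#' rows. The volume table has columns `case_id`, `time_months`, `volume_px3`
#' (one row per scan); the annotation table has `case_id`, `pathology`,
#' `group`, `had_resection`, and optional `vc_detection_time` and
#' `earliest_baseline_time` (one row per case; empty cells for absent
#' annotations). Validation failures are reported with the offending case and
#' row numbers.
#'
#' @param path Volume table file.
#' @param annotation_path Annotation table file; `NULL` for unannotated series.
#' @return Named list of [volume_series()], ordered by case id.
#' @export
read_volume_table <- function(path, annotation_path = NULL) {
  vt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "time_months", "volume_px3")
  if (!all(need %in% names(vt)))
    stop("volume table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
    if (!"case_id" %in% names(ann))
      stop("annotation table must have a case_id column", call. = FALSE)
    ann$case_id <- as.character(ann$case_id)
    orphans <- setdiff(unique(as.character(vt$case_id)), ann$case_id)
    if (length(orphans) > 0L)
      stop("volume rows without annotation for case(s): ",
           paste(orphans, collapse = ", "), call. = FALSE)
  }
  vt$case_id <- as.character(vt$case_id)
  vt$.row <- seq_len(nrow(vt))
  out <- list()
  for (id in sort(unique(vt$case_id))) {
    rows <- vt[vt$case_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_months), , drop = FALSE]
    if (anyDuplicated(rows$time_months))
      stop(sprintf("case %s: duplicated times (rows %s)", id,
                   paste(rows$.row, collapse = ",")), call. = FALSE)
    a <- if (!is.null(ann)) ann[match(id, ann$case_id), ] else NULL
    getf <- function(col, default) {
      if (!is.null(a) && col %in% names(a) && !is.na(a[[col]])) a[[col]] else default
    }
    s <- tryCatch(
      volume_series(id,
                    times = rows$time_months, volumes = rows$volume_px3,
                    pathology = getf("pathology", NA_character_),
                    group = getf("group", NA_character_),
                    had_resection = as.logical(getf("had_resection", FALSE)),
                    vc_detection_time = as.numeric(getf("vc_detection_time", NA_real_)),
                    earliest_baseline_time = as.numeric(getf("earliest_baseline_time", NA_real_))),
      error = function(e)
        stop(sprintf("case %s (rows %s): %s", id,
                     paste(range(rows$.row), collapse = "-"),
                     conditionMessage(e)), call. = FALSE))
    out[[id]] <- s
  }
  out
}

#' Write a cohort to the volume-table format
#'
#' Inverse of [read_volume_table()]; writers are deterministic (cases sorted
#' by id, volumes as integers, months to 2 decimals), so identical inputs
#' yield byte-identical files.
#'
#' @param cases Named list of [volume_series()].
#' @param path Volume table destination.
#' @param annotation_path Optional annotation table destination.
#' @export
write_volume_table <- function(cases, path, annotation_path = NULL) {
  ids <- sort(vapply(cases, function(s) s$case_id, character(1)))
  cases <- cases[match(ids, vapply(cases, function(s) s$case_id, character(1)))]
  vt <- do.call(rbind, lapply(cases, function(s) {
    data.frame(case_id = s$case_id,
               time_months = formatC(s$times, format = "f", digits = 2),
               volume_px3 = formatC(round(s$volumes), format = "d"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(vt, path, row.names = FALSE, quote = FALSE)
  if (!is.null(annotation_path)) {
    fmt_na <- function(x, f) ifelse(is.na(x), "", f(x))
    ann <- do.call(rbind, lapply(cases, function(s) {
      data.frame(case_id = s$case_id,
                 pathology = ifelse(is.na(s$pathology), "", s$pathology),
                 group = ifelse(is.na(s$group), "", s$group),
                 had_resection = s$had_resection,
                 vc_detection_time = fmt_na(s$vc_detection_time,
                                            function(x) formatC(x, format = "f", digits = 2)),
                 earliest_baseline_time = fmt_na(s$earliest_baseline_time,
                                                 function(x) formatC(x, format = "f", digits = 2)),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(ann, annotation_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an axial mask stack from a NIfTI volume
#'
#' Voxels above `threshold` (or equal to `label`, if given) are tumor. The
#' inter-slice distance and pixel area default to the NIfTI header voxel
#' dimensions and can be overridden.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param label Optional integer label to select from a labeled volume.
#' @param threshold Binarization threshold for non-labeled volumes (default 0.5).
#' @param slice_distance,pixel_area Overrides for the header-derived spacings.
#' @return A [mask_series()].
#' @export
read_mask_nifti <- function(path, label = NULL, threshold = 0.5,
                            slice_distance = NULL, pixel_area = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume", call. = FALSE)
  pd <- RNifti::pixdim(img)
  if (is.null(slice_distance))
    slice_distance <- if (length(pd) >= 3L && pd[3L] > 0) pd[3L] else 1
  if (is.null(pixel_area))
    pixel_area <- if (length(pd) >= 2L && all(pd[1:2] > 0)) pd[1L] * pd[2L] else 1
  mask <- if (is.null(label)) arr > threshold else arr == label
  mask_series(mask, pixel_area = pixel_area, slice_distance = slice_distance)
}

#' Read an axial mask stack from per-slice PNG files
#'
#' @param paths PNG files in anatomical order; any nonzero pixel (first
#'   channel) is tumor.
#' @param pixel_area,slice_distance Spacings (default 1; PNG carries none).
#' @return A [mask_series()].
#' @export
read_mask_png_stack <- function(paths, pixel_area = 1, slice_distance = 1) {
  slices <- lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    a > 0
  })
  mask_series(slices, pixel_area = pixel_area, slice_distance = slice_distance)
}

#' Write detection and cohort reports
#'
#' Emits a per-case detection table (CSV), summary tables for the progression
#' and stable groups (tab-separated, in the published two-table shape with
#' `median (q1-q3)` cells and a `<0.001` p-value floor), and, when a pooled
#' exponential fit is supplied, a JSON report of its coefficients. Output is
#' deterministic: rows ordered by case id, volumes as integers, months and
#' fractions to 2 decimals.
#'
#' @param detections Named list of `"detection_result"` objects.
#' @param dir Output directory (created if needed).
#' @param summary Optional `"cohort_stats"` from [cohort_summary()].
#' @param pooled Optional `"pooled_fit"` from [pooled_fit()].
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(detections, dir, summary = NULL, pooled = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  if (length(detections) > 0L)
    detections <- detections[order(names(detections))]
  det <- do.call(rbind, lapply(detections, function(d) {
    data.frame(case_id = d$case_id, detected = d$detected,
               alert_visit = d$alert_visit,
               changepoint_index = d$changepoint_index,
               ttg_months = ifelse(is.na(d$ttg_months), "",
                                   formatC(d$ttg_months, format = "f", digits = 2)),
               delta_v = ifelse(is.na(d$delta_v), "",
                                formatC(d$delta_v, format = "f", digits = 2)),
               baseline_index = d$baseline_index,
               v0 = formatC(round(d$v0), format = "d"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(det)) det <- data.frame(case_id = character(0), detected = logical(0),
                                      alert_visit = integer(0), changepoint_index = integer(0),
                                      ttg_months = character(0), delta_v = character(0),
                                      baseline_index = integer(0), v0 = character(0))
  p <- file.path(dir, "detections.csv")
  utils::write.csv(det, p, row.names = FALSE, quote = FALSE, na = "")
  paths <- c(paths, p)

  if (!is.null(summary)) {
    if (!is.null(summary$progression)) {
      pr <- summary$progression
      tab <- data.frame(
        pathology = pr$pathology, n = pr$n, delta_g = pr$delta_g,
        ttg_cad = vapply(seq_len(nrow(pr)), function(i)
          .fmt_med_iqr(unlist(pr[i, c("ttg_cad_median", "ttg_cad_q1", "ttg_cad_q3")])), ""),
        ttg_vc = vapply(seq_len(nrow(pr)), function(i)
          .fmt_med_iqr(unlist(pr[i, c("ttg_vc_median", "ttg_vc_q1", "ttg_vc_q3")])), ""),
        p_ttg = vapply(pr$p_ttg, .fmt_p, ""),
        dv_cad = vapply(seq_len(nrow(pr)), function(i)
          .fmt_med_iqr(unlist(pr[i, c("dv_cad_median", "dv_cad_q1", "dv_cad_q3")]), pct = TRUE), ""),
        dv_vc = vapply(seq_len(nrow(pr)), function(i)
          .fmt_med_iqr(unlist(pr[i, c("dv_vc_median", "dv_vc_q1", "dv_vc_q3")]), pct = TRUE), ""),
        p_dv = vapply(pr$p_dv, .fmt_p, ""),
        stringsAsFactors = FALSE)
      p <- file.path(dir, "progression_summary.tsv")
      utils::write.table(tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(summary$stable)) {
      st <- summary$stable
      tab <- data.frame(
        pathology = st$pathology, n = st$n, cad_g = st$cad_g,
        cad_ttg = vapply(seq_len(nrow(st)), function(i)
          .fmt_med_iqr(unlist(st[i, c("ttg_cad_median", "ttg_cad_q1", "ttg_cad_q3")])), ""),
        fu_g = vapply(seq_len(nrow(st)), function(i)
          .fmt_med_iqr(unlist(st[i, c("fu_g_median", "fu_g_q1", "fu_g_q3")])), ""),
        fu_s = vapply(seq_len(nrow(st)), function(i)
          .fmt_med_iqr(unlist(st[i, c("fu_s_median", "fu_s_q1", "fu_s_q3")])), ""),
        cad_dv = vapply(seq_len(nrow(st)), function(i)
          .fmt_med_iqr(unlist(st[i, c("dv_cad_median", "dv_cad_q1", "dv_cad_q3")]), pct = TRUE), ""),
        stringsAsFactors = FALSE)
      p <- file.path(dir, "stable_summary.tsv")
      utils::write.table(tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  }

  if (!is.null(pooled)) {
    p <- file.path(dir, "pooled_fit.json")
    jsonlite::write_json(
      list(model = "a * exp(b * x)", a = pooled$a, b = pooled$b,
           sse = pooled$sse, r2 = pooled$r2,
           n_curves = pooled$n_curves, n_points = pooled$n_points),
      p, auto_unbox = TRUE, digits = 6)
    paths <- c(paths, p)
  }
  invisible(paths)
}
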