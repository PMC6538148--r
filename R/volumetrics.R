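#' Axial binary-mask stack
#'
#' Ordered axial tumor masks with in-plane pixel area and the distance between
#' consecutive images. The study's volumetry works in pixel units, so both
#' default to 1 and the canonical volume unit is pixel^3; supply physical
#' spacings for mm^3.
#'
#' @param slices A list of logical (or 0/1) matrices, all of the same
#'   dimensions, ordered along the through-plane axis; or a 3D array whose
#'   third index is the slice.
#' @param pixel_area In-plane area of one pixel (default 1).
#' @param slice_distance Distance between consecutive axial images, in the
#'   same linear unit as the pixel edge (default 1); must be positive.
#' @return Object of class `"mask_series"`.
#' @export
mask_series <- function(slices, pixel_area = 1, slice_distance = 1) {
  if (is.array(slices) && length(dim(slices)) == 3L)
    slices <- lapply(seq_len(dim(slices)[3L]), function(k) slices[, , k])
  if (!is.list(slices) || length(slices) == 0L)
    stop("`slices` must be a nonempty list of matrices or a 3D array", call. = FALSE)
  slices <- lapply(slices, function(m) {
    if (!is.matrix(m)) stop("each slice must be a matrix", call. = FALSE)
    storage.mode(m) <- "logical"
    m
  })
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("all slices must share in-plane dimensions", call. = FALSE)
  if (!is.numeric(slice_distance) || slice_distance <= 0)
    stop("`slice_distance` must be positive", call. = FALSE)
  if (!is.numeric(pixel_area) || pixel_area <= 0)
    stop("`pixel_area` must be positive", call. = FALSE)
  structure(list(slices = slices, pixel_area = pixel_area,
                 slice_distance = slice_distance),
            class = "mask_series")
}

#' Per-slice tumor areas of a mask stack
#'
#' @param masks A [mask_series()].
#' @return Numeric vector of per-slice areas (pixel count times `pixel_area`).
#' @export
slice_areas <- function(masks) {
  stopifnot(inherits(masks, "mask_series"))
  vapply(masks$slices, function(m) sum(m) * masks$pixel_area, numeric(1))
}

#' Tumor volume of a mask stack
#'
#' The volume is the sum of the tumor areas over all axial images multiplied
#' by the distance between images.
#'
#' @param masks A [mask_series()].
#' @return Volume (pixel^3 with default spacings).
#' @export
#' @examples
#' sl <- matrix(FALSE, 8, 8); sl[3:5, 3:5] <- TRUE
#' compute_volume(mask_series(list(sl), slice_distance = 5))  # 9 * 5 = 45
compute_volume <- function(masks) {
  sum(slice_areas(masks)) * masks$slice_distance
}

#' Combine ranked segmentation regions into the tumor mask
#'
#' Automated segmentation produces several candidate regions per image (eight
#' in the study's pipeline), each summarized by its maximal intensity. The
#' final tumor margins are the union of exactly the regions whose maximal
#' intensity lies strictly above the gray-matter level; a region tied with the
#' gray matter is excluded (conservative reading of "above").
#'
#' @param segments List of segments, each a list with `mask` (logical matrix
#'   or 3D array; all must share dimensions) and `max_intensity` (scalar, in
#'   the image's intensity units).
#' @param gray_matter_level Intensity of normal gray matter, same units.
#' @return A logical mask with the common dimensions; all-`FALSE` when no
#'   segment qualifies.
#' @export
combine_segments <- function(segments, gray_matter_level) {
  if (!is.list(segments) || length(segments) == 0L)
    stop("`segments` must be a nonempty list", call. = FALSE)
  dims <- lapply(segments, function(s) dim(s$mask))
  if (any(vapply(dims, function(d) !identical(d, dims[[1L]]), logical(1))))
    stop("all segment masks must share dimensions", call. = FALSE)
  out <- array(FALSE, dim = dims[[1L]])
  for (s in segments)
    if (s$max_intensity > gray_matter_level) out <- out | (s$mask != 0)
  out
}

#' Per-slice growth profile between two time points
#'
#' Element-wise fractional area change per axial slice, plus a flag for
#' nonhomogeneous 3D growth: growth concentrated away from the slice holding
#' the largest tumor component at baseline. Bidimensional surveillance reads
#' only that largest slice, so nonhomogeneous growth is exactly the mode it
#' misses.
#'
#' @param masks_t0,masks_t1 Two [mask_series()] with equal slice counts and
#'   matched anatomical ordering, or two plain numeric vectors of per-slice
#'   areas.
#' @return List of class `"slice_growth_profile"`: `fractional_change`
#'   (per-slice `(a1 - a0) / a0`; `Inf` marks a slice empty at baseline but
#'   not at follow-up, 0 a slice empty at both), `max_growth_slice`,
#'   `largest_baseline_slice` (ties to the lowest index), and `nonhomogeneous`
#'   (`TRUE` when the two differ).
#' @export
slice_growth_profile <- function(masks_t0, masks_t1) {
  a0 <- if (inherits(masks_t0, "mask_series")) slice_areas(masks_t0) else as.numeric(masks_t0)
  a1 <- if (inherits(masks_t1, "mask_series")) slice_areas(masks_t1) else as.numeric(masks_t1)
  if (length(a0) != length(a1))
    stop("slice counts differ between time points", call. = FALSE)
  if (length(a0) == 0L) stop("empty mask series", call. = FALSE)
  fc <- ifelse(a0 > 0, (a1 - a0) / a0, ifelse(a1 > 0, Inf, 0))
  max_growth <- which.max(fc)               # ties -> lowest index
  largest_base <- which.max(a0)
  # homogeneous growth means the largest slice grows as fast as any other
  # (ties within rounding noise), so only a strictly faster off-slice flags
  nonhom <- fc[largest_base] < max(fc) - 1e-9
  structure(list(fractional_change = fc,
                 max_growth_slice = max_growth,
                 largest_baseline_slice = largest_base,
                 nonhomogeneous = nonhom),
            class = "slice_growth_profile")
}

#' Index of the slice with the largest tumor component
#'
#' @param masks A [mask_series()].
#' @return 1-based slice index (ties broken to the lowest index).
#' @export
largest_slice <- function(masks) {
  which.max(slice_areas(masks))
}

# pixel-center coordinates of a logical mask, one row per TRUE pixel
.mask_coords <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask", call. = FALSE)
  w
}

# boundary pixels: TRUE pixels with an 8-neighbor outside the mask (or on the
# image edge); any maximal chord has both endpoints here
.boundary_coords <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- pad[2:(nr + 1L), 2:(nc + 1L)]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    interior <- interior & pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  which(mask & !interior, arr.ind = TRUE)
}

#' Bidimensional product of the two largest perpendicular diameters
#'
#' The conventional 2D trial measurement: on one axial section, the longest
#' diameter `d1` (maximal distance between two tumor pixel centers) times the
#' maximal tumor extent `d2` measured perpendicular to it. Perpendicularity is
#' taken within 1 degree; ties resolve to the larger `d2`. Distances are
#' between pixel centers, and a single-pixel mask is assigned diameter 1 pixel
#' so products never vanish on nonempty masks.
#'
#' @param mask A logical matrix (one axial slice).
#' @return `d1 * d2` in pixel^2, with attributes `d1` and `d2`.
#' @export
#' @examples
#' m <- matrix(FALSE, 25, 25)
#' m[outer((1:25 - 13)^2, (1:25 - 13)^2, "+") <= 64] <- TRUE  # disk r = 8
#' bidimensional_product(m)  # about (2r)^2
bidimensional_product <- function(mask) {
  xy <- .mask_coords(mask)
  if (nrow(xy) == 1L) {
    out <- 1
    attr(out, "d1") <- 1; attr(out, "d2") <- 1
    return(out)
  }
  # maximal chords end on the mask boundary, which is small even for large
  # masks, so the pair scans below are cheap
  bd <- .boundary_coords(mask)
  dx <- outer(bd[, 1L], bd[, 1L], "-")
  dy <- outer(bd[, 2L], bd[, 2L], "-")
  dist2 <- dx^2 + dy^2
  best <- which(dist2 == max(dist2), arr.ind = TRUE)[1L, ]
  d1 <- sqrt(dist2[best[1L], best[2L]])
  u <- c(dx[best[1L], best[2L]], dy[best[1L], best[2L]]) / d1
  # pairs whose connecting line is within 1 degree of perpendicular to d1
  len <- sqrt(dist2)
  cosang <- abs(dx * u[1L] + dy * u[2L]) / ifelse(len > 0, len, 1)
  perp <- len > 0 & cosang <= sin(pi / 180)  # |cos(90 deg +/- 1 deg)| = sin(1 deg)
  d2 <- if (any(perp)) max(len[perp]) else 1
  out <- max(d1, 1) * max(d2, 1)
  attr(out, "d1") <- max(d1, 1)
  attr(out, "d2") <- max(d2, 1)
  out
}

#' Bidimensional progression call
#'
#' Growth under the conventional 2D rule: progression when the product of the
#' two largest perpendicular diameters increases by at least
#' `progression_fraction` (default 25%, inclusive).
#'
#' @param product_baseline,product_current Bidimensional products (pixel^2),
#'   positive.
#' @param progression_fraction Fractional increase declaring progression
#'   (default 0.25).
#' @return Logical.
#' @export
bidim_progression <- function(product_baseline, product_current,
                              progression_fraction = 0.25) {
  if (product_baseline <= 0)
    stop("baseline product must be positive", call. = FALSE)
  if (progression_fraction <= 0)
    stop("`progression_fraction` must be positive", call. = FALSE)
  (product_current / product_baseline - 1) >= progression_fraction
}

#' Measure increase under homogeneous per-dimension growth
#'
#' If a tumor grows by the same fraction `d` along each of `n_dims`
#' dimensions, the measured product (2D) or volume (3D) grows by
#' `(1 + d)^n_dims - 1`. This is the arithmetic relating bidimensional
#' progression thresholds to volumetric ones: 12% per dimension is 25% in a
#' 2D product but 41% in volume, and a 3-fold volume needs only 44% per
#' dimension.
#'
#' @param per_dimension_increase Fractional increase per dimension, `> -1`.
#' @param n_dims 2 or 3.
#' @return Fractional increase of the product/volume.
#' @export
#' @examples
#' homogeneous_scaling(0.12, 2)  # 0.2544
#' homogeneous_scaling(0.12, 3)  # 0.4049
homogeneous_scaling <- function(per_dimension_increase, n_dims) {
  if (!n_dims %in% c(2L, 3L)) stop("`n_dims` must be 2 or 3", call. = FALSE)
  if (any(per_dimension_increase <= -1))
    stop("`per_dimension_increase` must be > -1", call. = FALSE)
  (1 + per_dimension_increase)^n_dims - 1
}
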