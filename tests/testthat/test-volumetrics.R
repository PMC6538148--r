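test_that("combine_segments unions exactly the regions above the gray-matter level", {
  sq <- function(rows) { m <- matrix(FALSE, 6, 6); m[rows, ] <- TRUE; m }
  segs <- lapply(seq_len(8), function(i)
    list(mask = sq(i %% 6 + 1), max_intensity = c(200, 180, 150, 120, 100, 90, 80, 70)[i]))
  out <- combine_segments(segs, gray_matter_level = 110)
  expected <- segs[[1]]$mask | segs[[2]]$mask | segs[[3]]$mask | segs[[4]]$mask
  expect_identical(out != 0, expected)

  # all below: empty mask, not an error
  expect_equal(sum(combine_segments(segs, gray_matter_level = 500)), 0)

  # tie at the gray level is excluded (strictly above)
  one <- list(list(mask = sq(1), max_intensity = 110))
  expect_equal(sum(combine_segments(one, gray_matter_level = 110)), 0)

  expect_error(combine_segments(list(), 100), "nonempty")
})

test_that("compute_volume is the slice-area sum times the inter-slice distance", {
  one <- areas_as_masks(10, slice_distance = 5)
  expect_equal(compute_volume(one), 50)

  fig <- areas_as_masks(c(268, 1174, 1240, 962, 246), slice_distance = 5)
  expect_equal(compute_volume(fig), 19450)

  empty <- areas_as_masks(c(0, 0, 0))
  expect_equal(compute_volume(empty), 0)

  expect_error(mask_series(list(matrix(TRUE, 2, 2)), slice_distance = 0), "positive")
})

test_that("volume scales with in-plane magnification and slice distance", {
  base <- mask_series(list(raster_rect(6, 4)), slice_distance = 2)
  mag <- mask_series(list(raster_rect(18, 12, n = 24)), slice_distance = 2)
  expect_equal(compute_volume(mag), 9 * compute_volume(base))
  thick <- mask_series(list(raster_rect(6, 4)), slice_distance = 6)
  expect_equal(compute_volume(thick), 3 * compute_volume(base))
})

test_that("slice growth profile flags growth away from the largest baseline slice", {
  a0 <- c(268, 1174, 1240, 962, 246)
  a1 <- c(718, 1262, 1764, 994, 282)
  prof <- slice_growth_profile(a0, a1)
  expect_equal(prof$fractional_change, (a1 - a0) / a0)
  expect_equal(prof$fractional_change[1], 1.679, tolerance = 1e-3)
  expect_equal(prof$max_growth_slice, 1)       # +168% on the end slice
  expect_equal(prof$largest_baseline_slice, 3) # area 1240
  expect_true(prof$nonhomogeneous)

  ident <- slice_growth_profile(a0, a0)
  expect_equal(ident$fractional_change, rep(0, 5))
  expect_false(ident$nonhomogeneous)

  unif <- slice_growth_profile(a0, a0 * 1.1)
  expect_equal(unif$fractional_change, rep(0.1, 5))
  expect_false(unif$nonhomogeneous)

  # growth applied only off the largest slice must raise the flag
  off <- a0; off[5] <- a0[5] * 1.5
  expect_true(slice_growth_profile(a0, off)$nonhomogeneous)

  expect_error(slice_growth_profile(a0, a1[-1]), "slice counts")

  # empty baseline slice with nonzero follow-up: sentinel, not an error
  s <- slice_growth_profile(c(0, 100), c(10, 100))
  expect_identical(s$fractional_change[1], Inf)
  expect_identical(slice_growth_profile(c(0, 100), c(0, 100))$fractional_change[1], 0)
})

test_that("bidimensional product matches geometry and the all-pairs oracle", {
  disk <- raster_disk(8)
  p <- bidimensional_product(disk)
  expect_equal(as.numeric(p), (2 * 8)^2, tolerance = 0.05)

  ell <- raster_ellipse(10, 5)
  p_ell <- bidimensional_product(ell)
  expect_equal(as.numeric(p_ell), oracle_bidim(ell))
  expect_equal(as.numeric(p_ell), 200, tolerance = 0.05)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(as.numeric(bidimensional_product(single)), 1)

  expect_error(bidimensional_product(matrix(FALSE, 4, 4)), "empty")

  # thin line: no perpendicular extent beyond one pixel
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  lp <- bidimensional_product(line)
  expect_equal(attr(lp, "d2"), 1)
})

test_that("bidimensional product is rotation-tolerant on digitized ellipses", {
  # the ellipse must be large enough that pixel-pair angles sample the
  # 1-degree perpendicularity band; a 60x30 semi-axis fixture does
  ref <- as.numeric(bidimensional_product(raster_ellipse(60, 30, 0)))
  for (th in c(15, 30, 45, 60, 75, 90) * pi / 180) {
    p <- as.numeric(bidimensional_product(raster_ellipse(60, 30, th)))
    expect_lt(abs(p - ref) / ref, 0.05)
  }
})

test_that("bidimensional product agrees with the all-pairs oracle on random blobs", {
  set.seed(42)
  for (i in 1:10) {
    m <- raster_disk(4) | raster_ellipse(6, 3, runif(1, 0, pi), n = 13)
    expect_equal(as.numeric(bidimensional_product(m)), oracle_bidim(m))
  }
})

test_that("2D progression rule is an inclusive 25% product increase", {
  expect_true(bidim_progression(40, 50))    # exactly +25%
  expect_false(bidim_progression(40, 49))
  expect_true(bidim_progression(100, 125, progression_fraction = 0.25))
  expect_error(bidim_progression(0, 10), "positive")
})

test_that("homogeneous scaling reproduces the 2D/3D conversion arithmetic", {
  expect_equal(homogeneous_scaling(0.12, 2), 1.12^2 - 1)
  expect_equal(homogeneous_scaling(0.12, 3), 1.12^3 - 1)
  expect_equal(homogeneous_scaling(0, 3), 0)
  expect_error(homogeneous_scaling(0.1, 4), "2 or 3")
  expect_error(homogeneous_scaling(-1.2, 3), "-1")
})

test_that("per-dimension scaling of a cuboid mask changes the volume by (1+d)^3", {
  d <- 0.5
  base <- mask_series(replicate(10, raster_rect(20, 12, n = 32), simplify = FALSE))
  grown <- mask_series(replicate(15, raster_rect(30, 18, n = 32), simplify = FALSE))
  ratio <- compute_volume(grown) / compute_volume(base)
  expect_equal(ratio, (1 + d)^3, tolerance = 0.02)
})

test_that("largest_slice ties break to the lowest index", {
  ms <- areas_as_masks(c(5, 9, 9, 3))
  expect_equal(largest_slice(ms), 2)
})
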