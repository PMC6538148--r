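# Small rasterized shapes used across the volumetrics tests.

raster_disk <- function(r, n = 2 * r + 5) {
  c0 <- (n + 1) / 2
  m <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+") <= r^2
  m
}

# filled ellipse with semi-axes (a, b), rotated by theta radians
raster_ellipse <- function(a, b, theta = 0, n = ceiling(2 * max(a, b)) + 7) {
  c0 <- (n + 1) / 2
  x <- outer(seq_len(n) - c0, rep(1, n))
  y <- outer(rep(1, n), seq_len(n) - c0)
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  (xr / a)^2 + (yr / b)^2 <= 1
}

raster_rect <- function(w, h, n = max(w, h) + 6) {
  m <- matrix(FALSE, n, n)
  m[seq_len(w), seq_len(h)] <- TRUE
  m
}

# a mask series whose k-th slice is a run of `areas[k]` pixels
areas_as_masks <- function(areas, slice_distance = 1, n = max(areas)) {
  slices <- lapply(areas, function(a) {
    m <- matrix(FALSE, 1, n)
    if (a > 0) m[1, seq_len(a)] <- TRUE
    m
  })
  mask_series(slices, slice_distance = slice_distance)
}

# step series: v_lo for n_lo scans then v_hi, at regular monthly intervals
step_series <- function(v_lo, v_hi, n_lo, n_hi, dt = 3, id = "step") {
  n <- n_lo + n_hi
  volume_series(id, times = seq(0, by = dt, length.out = n),
                volumes = c(rep(v_lo, n_lo), rep(v_hi, n_hi)))
}
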