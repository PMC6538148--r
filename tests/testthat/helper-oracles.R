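# Independent brute-force oracles. These deliberately avoid the package's
# algorithms (dynamic programming, wilcox.test, boundary-pair search) so tests
# compare two routes to the same quantity.

# all admissible change-point sets for n samples with min segment m:
# positions are 1-based indices of the first sample of a new segment
enumerate_cp_sets <- function(n, m) {
  res <- list(integer(0))
  grow <- function(prefix, start) {
    p <- start
    while (p <= n - m + 1L) {
      cand <- c(prefix, p)
      res[[length(res) + 1L]] <<- cand
      grow(cand, p + m)
      p <- p + 1L
    }
  }
  if (n >= 2L * m) grow(integer(0), m + 1L)
  res
}

# exhaustive penalized minimum over all admissible change-point sets
oracle_changepoints <- function(x, penalty, min_segment = 2L,
                                statistic = "rms_log") {
  n <- length(x)
  sets <- enumerate_cp_sets(n, min_segment)
  set_cost <- function(cps) {
    bounds <- c(1L, cps, n + 1L)
    tot <- 0
    for (k in seq_len(length(bounds) - 1L))
      tot <- tot + segment_cost(x[bounds[k]:(bounds[k + 1L] - 1L)], statistic)
    tot + penalty * length(cps)
  }
  costs <- vapply(sets, set_cost, numeric(1))
  sets[[which.min(costs)]]
}

# exact two-tailed Mann-Whitney p by enumerating every assignment of ranks
oracle_mww_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))  # U statistic, no ties by construction
  }
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2L, u_of)
  u0 <- sum(outer(x, y, ">"))
  min(1, 2 * min(mean(us <= u0), mean(us >= u0)))
}

# all-pairs bidimensional product for small masks (the spec's stated oracle)
oracle_bidim <- function(mask) {
  xy <- which(mask != 0, arr.ind = TRUE)
  if (nrow(xy) == 1L) return(1)
  dx <- outer(xy[, 1L], xy[, 1L], "-")
  dy <- outer(xy[, 2L], xy[, 2L], "-")
  len <- sqrt(dx^2 + dy^2)
  d1 <- max(len)
  best <- which(len == d1, arr.ind = TRUE)[1L, ]
  u <- c(dx[best[1L], best[2L]], dy[best[1L], best[2L]]) / d1
  cosang <- abs(dx * u[1L] + dy * u[2L]) / ifelse(len > 0, len, 1)
  perp <- len > 0 & cosang <= sin(pi / 180)
  d2 <- if (any(perp)) max(len[perp]) else 1
  max(d1, 1) * max(d2, 1)
}
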