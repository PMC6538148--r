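#' Configuration for a synthetic volume trajectory
#'
#' Encodes one case's true trajectory shape plus per-scan measurement noise.
#' Defaults mirror the surveillance setting the pipeline targets: a baseline
#' volume of 10,000 pixel^3 (the rounded cohort median implied by the
#' detector's 500 numerator being 5% of it), per-scan fractional volume noise
#' with mean 0.99% and SD 26.54% (the calibration measured on true-negative
#' stable curves), and clinic visits every 2-6 months.
#'
#' @param kind Trajectory shape: `"stationary"`, `"linear_growth"`,
#'   `"exponential_growth"`, `"postop_decay_then_stationary"`, or
#'   `"postop_decay_then_growth"`. The `postop_*` kinds prepend a strictly
#'   decreasing post-surgical limb ending at the trend baseline, so the first
#'   volume minimum equals the trend's starting volume.
#' @param v0 Baseline (trend) volume, pixel^3; default 10000.
#' @param noise_mean Mean per-scan fractional volume change of the measurement
#'   noise; default 0.0099.
#' @param noise_sd SD of the per-scan fractional change; default 0.2654.
#' @param onset_month Months after baseline at which growth starts; default 12.
#' @param growth_rate Linear slope (pixel^3/month) or exponential rate
#'   (1/month) depending on shape. Defaults: 600 pixel^3/month linear,
#'   0.06/month exponential — rates at which growth becomes visually
#'   conspicuous (roughly 170% above baseline) within a typical multi-year
#'   follow-up, matching the surveillance setting the cohort statistics
#'   describe.
#' @param growth_shape For `"postop_decay_then_growth"`: `"exponential"`
#'   (default) or `"linear"`. Ignored for kinds that fix the shape.
#' @param visit_interval_range Months between consecutive visits, drawn
#'   uniformly; default `c(2, 6)`.
#' @param n_visits Total number of visits (default 12, at least 4).
#' @param n_pre For `postop_*` kinds, number of visits on the decaying
#'   post-surgical limb before the baseline visit (default 3).
#' @param postop_start_fold Volume at the first post-surgical scan as a
#'   multiple of `v0` (default 2).
#' @param seed Optional integer; the same seed reproduces the same series.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(kind = c("stationary", "linear_growth",
                                      "exponential_growth",
                                      "postop_decay_then_stationary",
                                      "postop_decay_then_growth"),
                             v0 = 10000, noise_mean = 0.0099,
                             noise_sd = 0.2654, onset_month = 12,
                             growth_rate = NULL,
                             growth_shape = c("exponential", "linear"),
                             visit_interval_range = c(2, 6),
                             n_visits = 12L, n_pre = 3L,
                             postop_start_fold = 2, seed = NULL) {
  kind <- match.arg(kind)
  growth_shape <- match.arg(growth_shape)
  if (kind == "linear_growth") growth_shape <- "linear"
  if (kind == "exponential_growth") growth_shape <- "exponential"
  if (is.null(growth_rate))
    growth_rate <- if (growth_shape == "linear") 600 else 0.06
  if (v0 <= 0) stop("`v0` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  n_visits <- as.integer(n_visits)
  if (n_visits < 4L) stop("`n_visits` must be at least 4", call. = FALSE)
  if (length(visit_interval_range) != 2L || any(visit_interval_range <= 0) ||
      visit_interval_range[1L] > visit_interval_range[2L])
    stop("`visit_interval_range` must be an increasing positive pair", call. = FALSE)
  n_pre <- as.integer(n_pre)
  if (startsWith(kind, "postop") && (n_pre < 1L || n_pre >= n_visits - 1L))
    stop("`n_pre` must leave at least 2 visits from baseline on", call. = FALSE)
  if (postop_start_fold <= 1) stop("`postop_start_fold` must exceed 1", call. = FALSE)
  structure(list(kind = kind, v0 = v0, noise_mean = noise_mean,
                 noise_sd = noise_sd, onset_month = onset_month,
                 growth_rate = growth_rate, growth_shape = growth_shape,
                 visit_interval_range = visit_interval_range,
                 n_visits = n_visits, n_pre = n_pre,
                 postop_start_fold = postop_start_fold, seed = seed),
            class = "synthetic_config")
}

# evaluate with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# noiseless trend volumes at months-from-baseline tau (tau < 0: postop limb)
.trend <- function(cfg, tau) {
  v <- rep(cfg$v0, length(tau))
  grows <- cfg$kind %in% c("linear_growth", "exponential_growth",
                           "postop_decay_then_growth")
  if (grows) {
    dt <- pmax(0, tau - cfg$onset_month)
    v <- if (cfg$growth_shape == "linear") cfg$v0 + cfg$growth_rate * dt
         else cfg$v0 * exp(cfg$growth_rate * dt)
  }
  if (any(tau < 0)) {
    # geometric decay from postop_start_fold * v0 down to v0 at tau = 0
    pre <- tau < 0
    frac <- -tau[pre] / max(-tau[pre])            # 0 (at baseline) .. 1 (first scan)
    v[pre] <- cfg$v0 * cfg$postop_start_fold^frac
  }
  v
}

#' Simulate one longitudinal volume series
#'
#' Draws visit times as cumulative uniform inter-visit intervals, evaluates
#' the configured noiseless trend, and applies multiplicative per-scan noise
#' `v * (1 + e)` with `e ~ Normal(noise_mean, noise_sd)` truncated at -0.9 so
#' volumes stay positive. With `seed` set in the config, output is
#' reproducible.
#'
#' @param cfg A [synthetic_config()].
#' @param case_id Identifier for the generated series.
#' @return A [volume_series()] with `had_resection` set for `postop_*` kinds;
#'   the true baseline time and volume are attached as attributes
#'   `true_baseline_time` and `true_v0`, and the growth onset (months from
#'   first scan) as `true_onset_time` for growing kinds.
#' @export
simulate_trajectory <- function(cfg, case_id = "synthetic") {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(cfg$seed, {
    iv <- stats::runif(cfg$n_visits - 1L, cfg$visit_interval_range[1L],
                       cfg$visit_interval_range[2L])
    times <- c(0, cumsum(iv))
    postop <- startsWith(cfg$kind, "postop")
    t_base <- if (postop) times[cfg$n_pre + 1L] else 0
    trend <- .trend(cfg, times - t_base)
    eps <- pmax(stats::rnorm(cfg$n_visits, cfg$noise_mean, cfg$noise_sd), -0.9)
    vols <- trend * (1 + eps)
    out <- volume_series(case_id, times, vols, had_resection = postop)
    attr(out, "true_baseline_time") <- t_base
    attr(out, "true_v0") <- cfg$v0
    if (cfg$kind %in% c("linear_growth", "exponential_growth",
                        "postop_decay_then_growth"))
      attr(out, "true_onset_time") <- t_base + cfg$onset_month
    out
  })
}

#' Simulate a three-group surveillance cohort
#'
#' Generates progression, clinically stable, and imaging-abnormality groups
#' with pathology labels, and attaches a synthetic visual-comparison (VC)
#' detection time to progression cases: the first visit at which the observed
#' volume reaches `(1 + vc_fold)` times the true baseline volume. The
#' fold-change rule is an explicit, declared stand-in for the human
#' visual-comparison read (calibrated to the roughly 174% median volume change
#' at which visual comparison historically called growth); it is fixture
#' machinery, not a model of radiologists.
#'
#' @param n_progression,n_stable,n_abnormal Group sizes (defaults 34, 22, 7,
#'   the shape of the cohort the method was reported on).
#' @param configs Optional list with elements `progression`, `stable`,
#'   `abnormal`, each a [synthetic_config()] used as the template for that
#'   group (its `seed` is ignored; per-case seeds derive from `seed`).
#'   Defaults: progression cases are post-operative growers (about 30%
#'   exponential, the remainder linear); stable cases are post-operative
#'   stationary; abnormality cases are never-resected stationary.
#' @param seed Master seed; per-case seeds and shape assignments derive from
#'   it.
#' @param vc_fold Fold-change over baseline defining the synthetic VC call
#'   (default 1.74).
#' @param exponential_fraction Fraction of progression cases given exponential
#'   shape (default `14/47`).
#' @return Named list of [volume_series()] with group, pathology and
#'   `vc_detection_time` annotations.
#' @export
simulate_cohort <- function(n_progression = 34L, n_stable = 22L,
                            n_abnormal = 7L, configs = NULL, seed = 1L,
                            vc_fold = 1.74,
                            exponential_fraction = 14 / 47) {
  # progression cases carry longer follow-up (~5 years of visits): the group
  # is defined retrospectively by visual comparison having called growth
  # within follow-up, so the series must cover the VC call
  base_cfgs <- list(
    progression = synthetic_config("postop_decay_then_growth", n_visits = 16L),
    stable = synthetic_config("postop_decay_then_stationary"),
    abnormal = synthetic_config("stationary"))
  for (nm in names(configs)) base_cfgs[[nm]] <- configs[[nm]]
  # pathology mix follows the reported cohort composition
  path_prog <- rep(c("oligodendroglioma", "astrocytoma", "mixed"),
                   length.out = n_progression)
  path_stab <- rep(c("oligodendroglioma", "astrocytoma", "mixed"),
                   length.out = n_stable)
  .with_seed(seed, {
    case_seeds <- sample.int(.Machine$integer.max, n_progression + n_stable + n_abnormal)
    is_exp <- stats::runif(n_progression) < exponential_fraction
    cases <- list()
    k <- 0L
    for (i in seq_len(n_progression)) {
      k <- k + 1L
      cfg <- base_cfgs$progression
      cfg$growth_shape <- if (is_exp[i]) "exponential" else "linear"
      cfg$growth_rate <- if (is_exp[i]) 0.06 else 600
      cfg$seed <- case_seeds[k]
      s <- simulate_trajectory(cfg, sprintf("prog_%02d", i))
      s$group <- "progression"
      s$pathology <- path_prog[i]
      v0 <- attr(s, "true_v0")
      hit <- which(s$volumes >= (1 + vc_fold) * v0)
      s$vc_detection_time <- if (length(hit)) s$times[hit[1L]] else NA_real_
      cases[[s$case_id]] <- s
    }
    for (i in seq_len(n_stable)) {
      k <- k + 1L
      cfg <- base_cfgs$stable
      cfg$seed <- case_seeds[k]
      s <- simulate_trajectory(cfg, sprintf("stab_%02d", i))
      s$group <- "stable"
      s$pathology <- path_stab[i]
      cases[[s$case_id]] <- s
    }
    for (i in seq_len(n_abnormal)) {
      k <- k + 1L
      cfg <- base_cfgs$abnormal
      cfg$seed <- case_seeds[k]
      s <- simulate_trajectory(cfg, sprintf("abn_%02d", i))
      s$group <- "imaging_abnormality"
      s$pathology <- "imaging_abnormality"
      cases[[s$case_id]] <- s
    }
    cases
  })
}

# rasterized ellipsoid on a voxel grid; semi_axes = c(in-plane x, in-plane y,
# through-plane z) in voxels
.rasterize_ellipsoid <- function(semi_axes, grid_shape, center) {
  if (any(center - semi_axes < 1) || any(center + semi_axes > grid_shape))
    stop("ellipsoid exceeds the grid", call. = FALSE)
  gx <- ((seq_len(grid_shape[1L]) - center[1L]) / semi_axes[1L])^2
  gy <- ((seq_len(grid_shape[2L]) - center[2L]) / semi_axes[2L])^2
  gz <- ((seq_len(grid_shape[3L]) - center[3L]) / semi_axes[3L])^2
  arr <- outer(outer(gx, gy, "+"), gz, "+") <= 1
  arr
}

#' Simulate an ellipsoid tumor phantom over time
#'
#' Rasterizes one ellipsoid per time point on a shared voxel grid and wraps
#' each as a [mask_series()]. Anisotropic growth (the through-plane axis
#' growing faster than the in-plane axes, which evades single-slice 2D
#' surveillance) is expressed by the axes themselves.
#'
#' @param axes List of length-3 numeric vectors, the ellipsoid semi-axes
#'   (in-plane x, in-plane y, through-plane z) in voxels at each time point.
#' @param grid_shape Voxel grid dimensions (default `c(64, 64, 64)`).
#' @param slice_distance Distance between axial images (default 1).
#' @param center Ellipsoid center (default grid midpoint).
#' @return List of [mask_series()], one per time point.
#' @export
#' @examples
#' ms <- simulate_mask_series(list(c(10, 10, 10)), grid_shape = c(32, 32, 32))
#' compute_volume(ms[[1]]) / (4 / 3 * pi * 10^3)  # close to 1
simulate_mask_series <- function(axes, grid_shape = c(64L, 64L, 64L),
                                 slice_distance = 1,
                                 center = (grid_shape + 1) / 2) {
  if (!is.list(axes) || length(axes) == 0L)
    stop("`axes` must be a nonempty list of length-3 vectors", call. = FALSE)
  lapply(axes, function(ax) {
    if (length(ax) != 3L || any(ax <= 0))
      stop("each axes entry must be 3 positive semi-axes", call. = FALSE)
    arr <- .rasterize_ellipsoid(ax, grid_shape, center)
    mask_series(arr, slice_distance = slice_distance)
  })
}
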