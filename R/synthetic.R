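#' Reference fiducial-arc geometry
#'
#' The nine-marker supporting-arc geometry used for co-registration:
#' sagittal (x) coordinates relative to fiducial 5, coronal (y)
#' coordinates relative to the back of the arc, axial (z) coordinates
#' relative to the arc base, all in mm. The layout is deliberately
#' asymmetric so that correspondence is unambiguous.
#'
#' @return A [point_set()] of the nine labelled fiducials.
#' @examples
#' fiducial_arc()
#' @export
fiducial_arc <- function() {
  point_set(rbind(
    c(-72,  99,  87),
    c(-60,  87, 104),
    c(-36, 111, 104),
    c(-24, 123,  77),
    c(  0, 135,  87),
    c( 24, 111, 104),
    c( 36, 123,  77),
    c( 60,  87,  87),
    c( 60,  75, 104)
  ), labels = as.character(1:9))
}

#' Simulation configuration
#'
#' Bundles the ground-truth scanner motion and the noise model for the
#' synthetic scan-pair generator. The motion is a similarity transform
#' given as Euler angles (see [compose_euler_rotation()] for the
#' convention), a translation and a scale; fiducial localization error is
#' modelled as i.i.d. zero-mean Gaussian noise added per axis to every
#' fiducial coordinate, the standard reduced model for the combined
#' scanner/partial-volume/search-routine error. `noise_sd` may be a single
#' sd (isotropic, the default model) or a length-3 per-axis sd (e.g.
#' larger along a coarser slice axis).
#'
#' @param alpha,beta,gamma true rotation angles (radians).
#' @param translation true translation (mm, length 3).
#' @param scale true scale factor (> 0).
#' @param noise_sd per-axis Gaussian localization noise sd (mm), length 1
#'   or 3, >= 0. Default 0.1 mm, a plausible magnitude for sub-voxel
#'   sphere localization on a half-millimetre grid.
#' @param seed integer seed making every simulation a pure function of
#'   (inputs, seed).
#' @param n_trials number of trials for ensemble simulations.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(alpha = 0, beta = 0, gamma = 0,
                              translation = c(0, 0, 0), scale = 1,
                              noise_sd = 0.1, seed = 1L, n_trials = 30L) {
  stopifnot(all(is.finite(c(alpha, beta, gamma, translation, scale))),
            scale > 0, all(noise_sd >= 0),
            length(noise_sd) %in% c(1L, 3L), n_trials >= 1L)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 translation = as.numeric(translation), scale = scale,
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed), n_trials = as.integer(n_trials)),
            class = "simulation_config")
}

config_transform <- function(cfg) {
  similarity_transform(
    compose_euler_rotation(cfg$alpha, cfg$beta, cfg$gamma),
    translation = cfg$translation, scale = cfg$scale)
}

# Run expr with a temporarily seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a pre/post-operative scan pair
#'
#' Generates the fiducial coordinate sets a pre- and a post-operative scan
#' would yield: `F1` is the arc perturbed by i.i.d. per-axis Gaussian
#' localization noise; `F2` is the arc moved by the ground-truth transform
#' and perturbed by independent noise of the same magnitude. The truth is
#' returned so recovery can be scored.
#'
#' @param arc a [point_set()], typically [fiducial_arc()].
#' @param cfg a [simulation_config()].
#' @return A list with `F1`, `F2` (point sets) and `truth`
#'   (the generating [similarity_transform()]).
#' @examples
#' pair <- simulate_scan_pair(fiducial_arc(), simulation_config(seed = 7))
#' horn_register(pair$F1, pair$F2)$residual_e
#' @export
simulate_scan_pair <- function(arc, cfg) {
  stopifnot(inherits(arc, "point_set"), inherits(cfg, "simulation_config"))
  truth <- config_transform(cfg)
  n <- n_points(arc)
  sd3 <- rep(cfg$noise_sd, length.out = 3L)
  with_seed(cfg$seed, {
    noise1 <- matrix(stats::rnorm(3L * n, sd = rep(sd3, each = n)), n, 3L)
    noise2 <- matrix(stats::rnorm(3L * n, sd = rep(sd3, each = n)), n, 3L)
    f1 <- arc
    f1$coords <- arc$coords + noise1
    f2 <- apply_transform(truth, arc)
    f2$coords <- f2$coords + noise2
    list(F1 = f1, F2 = f2, truth = truth)
  })
}

#' Simulate an ensemble of re-positioning trials
#'
#' Emulates the repeated reposition-and-rescan experiment used to
#' characterize fiducial re-positioning error: each trial generates an
#' independent scan pair (trial `k` uses seed `cfg$seed + k - 1`),
#' registers it with [horn_register()] and records the residual `e`. Both
#' the RMS and the arithmetic mean of the per-trial residuals are
#' reported, since either can serve as the ensemble summary.
#'
#' @inheritParams simulate_scan_pair
#' @param with_scale passed to [horn_register()].
#' @return A list with `residuals` (per-trial residual `e`, mm), `mean`
#'   (arithmetic mean), `rms` (root-mean-square) and `n_trials`.
#' @export
simulate_repositioning_trials <- function(arc, cfg, with_scale = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  res <- vapply(seq_len(cfg$n_trials), function(k) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k - 1L
    pair <- simulate_scan_pair(arc, cfg_k)
    horn_register(pair$F1, pair$F2, with_scale = with_scale)$residual_e
  }, numeric(1))
  list(residuals = res, mean = mean(res), rms = sqrt(mean(res^2)),
       n_trials = cfg$n_trials)
}

#' Rasterize spheres onto a voxel grid with partial-volume mixing
#'
#' Renders bright spheres (fiducial markers) into a 3-D intensity volume.
#' Each voxel's intensity is
#' `background + (foreground - background) * f`, where `f` is the fraction
#' of the voxel lying inside any sphere, estimated by a fixed 3 x 3 x 3
#' sub-voxel sampling of the voxel cell. On anisotropic grids this mixing
#' reproduces the slightly oval appearance of truly spherical markers.
#'
#' @param centres a [point_set()] of sphere centres (world mm).
#' @param radius sphere radius (mm); a 2.5 mm marker is typical.
#' @param spacing,origin grid geometry, see [voxel_grid()]. By default the
#'   origin places a `margin` of empty space around the spheres.
#' @param dims integer length-3 grid dimensions; computed from the centres
#'   and `margin` when omitted.
#' @param margin empty border (mm) used when auto-sizing the grid.
#' @param foreground,background intensities of sphere interior and
#'   surround.
#' @return A [voxel_grid()].
#' @examples
#' vol <- rasterize_spheres(fiducial_arc(), radius = 2.5)
#' dim(vol$intensities)
#' @export
rasterize_spheres <- function(centres, radius,
                              spacing = c(0.575, 0.575, 0.8),
                              origin = NULL, dims = NULL, margin = 5,
                              foreground = 100, background = 0) {
  stopifnot(inherits(centres, "point_set"), radius > 0)
  spacing <- as.numeric(spacing)
  cc <- centres$coords
  if (is.null(origin)) origin <- apply(cc, 2L, min) - radius - margin
  origin <- as.numeric(origin)
  if (is.null(dims)) {
    extent <- apply(cc, 2L, max) + radius + margin - origin
    dims <- as.integer(ceiling(extent / spacing)) + 1L
  }
  dims <- as.integer(dims)
  grid <- voxel_grid(array(background, dim = dims), spacing = spacing,
                     origin = origin)
  # 3x3x3 sub-voxel sample offsets at the centres of each third of a cell
  sub <- as.matrix(expand.grid(dx = (-1:1) / 3, dy = (-1:1) / 3,
                               dz = (-1:1) / 3))
  sub <- sweep(sub, 2L, spacing, "*")
  upper <- voxel_to_world(grid, matrix(dims - 1L, 1, 3))
  for (i in seq_len(nrow(cc))) {
    ctr <- cc[i, ]
    if (any(ctr - radius < origin - spacing / 2) ||
        any(ctr + radius > upper + spacing / 2)) {
      stop(sprintf("sphere '%s' extends outside the voxel grid",
                   centres$labels[i]), call. = FALSE)
    }
    lo <- pmax(floor((ctr - radius - origin) / spacing) - 1, 0)
    hi <- pmin(ceiling((ctr + radius - origin) / spacing) + 1, dims - 1)
    idx0 <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                  k = lo[3]:hi[3]))
    world <- voxel_to_world(grid, idx0)
    frac <- numeric(nrow(world))
    for (s in seq_len(nrow(sub))) {
      pt <- sweep(world, 2L, sub[s, ], "+")
      frac <- frac + (rowSums(sweep(pt, 2L, ctr)^2) <= radius^2)
    }
    frac <- frac / nrow(sub)
    lin <- idx0[, 1] + 1L + dims[1] * idx0[, 2] + dims[1] * dims[2] * idx0[, 3]
    # spheres may overlap a shared voxel: keep the larger filled fraction
    old <- (grid$intensities[lin] - background) / (foreground - background)
    grid$intensities[lin] <- background +
      (foreground - background) * pmax(old, frac)
  }
  grid
}

#' Simulate a measured cannula-tip position
#'
#' Displaces a planned target by i.i.d. per-axis Gaussian error — the
#' reduced model of the combined mechanical placement and tip-localization
#' error. With per-axis sd `sigma`, the Euclidean displacement follows a
#' chi distribution with 3 degrees of freedom (mean `sigma * sqrt(8/pi)`).
#'
#' @param planned length-3 planned target (mm).
#' @param displacement_sd per-axis sd (mm), >= 0.
#' @param seed integer seed.
#' @return Length-3 numeric simulated tip position.
#' @export
simulate_tip <- function(planned, displacement_sd, seed = 1L) {
  stopifnot(length(planned) == 3L, displacement_sd >= 0)
  with_seed(seed, as.numeric(planned) +
              stats::rnorm(3L, sd = displacement_sd))
}

#' Infusion regimes and delivered volume
#'
#' Convection-enhanced delivery uses a ramped infusion schedule — starting
#' slow to seat the infusate around the cannula tip, then stepping the
#' rate up. `infusion_regime()` builds a schedule from parallel rate and
#' duration vectors; `ced_ramp_regime()` returns the standard ramp
#' (0.5 ul/min for 5 min, 1 for 5, 2.5 for 5, then 5 ul/min for 20 min);
#' `total_infusion_volume()` integrates rate x duration.
#'
#' @param rates_ul_min infusion rates (ul/min), >= 0.
#' @param durations_min step durations (min), > 0.
#' @return `infusion_regime()`: a data frame with columns `rate_ul_min`,
#'   `duration_min`. `total_infusion_volume()`: total volume in ul.
#' @examples
#' total_infusion_volume(ced_ramp_regime())  # 120 ul
#' @export
infusion_regime <- function(rates_ul_min, durations_min) {
  stopifnot(length(rates_ul_min) == length(durations_min),
            all(rates_ul_min >= 0), all(durations_min > 0))
  data.frame(rate_ul_min = as.numeric(rates_ul_min),
             duration_min = as.numeric(durations_min))
}

#' @rdname infusion_regime
#' @export
ced_ramp_regime <- function() {
  infusion_regime(c(0.5, 1, 2.5, 5), c(5, 5, 5, 20))
}

#' @rdname infusion_regime
#' @param regime a data frame from [infusion_regime()] (an empty regime is
#'   allowed and delivers 0 ul).
#' @export
total_infusion_volume <- function(regime) {
  if (NROW(regime) == 0L) return(0)
  stopifnot(all(c("rate_ul_min", "duration_min") %in% names(regime)))
  sum(regime$rate_ul_min * regime$duration_min)
}
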