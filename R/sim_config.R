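#' Simulation configuration for the three-state Cel7A model
#'
#' Holds every parameter of the synthetic-data generator. Defaults are the
#' experimental conditions of the single-molecule study the package models:
#' 1 frame/s over 1000 frames, landings in the first 500 s, 1.5 nm
#' localization noise, a ~94/6 static/processive landing split, and the four
#' first-order rate constants of the three-state scheme (solution, static,
#' processive).
#'
#' Rates are in s^-1. The static state is left at total rate
#' `k_off_static + k_processive` (unbind vs. switch); the processive state at
#' `k_off_processive + k_static`. In `"duration"` mode the processive dwell is
#' exponential with that total exit rate and run length is emergent
#' (speed x dwell); in `"runlength"` mode the run length is exponential with
#' mean `segment_length_mean` (nm) and the dwell is length/speed.
#'
#' Per-segment speeds are drawn from a normal truncated below `speed_min`
#' whose post-truncation mean and SD equal `speed_mean`/`speed_sd`
#' (moment-matched; see [tnorm_params()]), so the generated speeds reproduce
#' the published mean +/- SD of measured segment velocities.
#'
#' Jumps (brief unbinding + rebinding within 100 nm) are a Poisson process at
#' `jump_rate` during bound time with radial displacement Exponential with
#' mean `jump_distance_scale`, capped at `jump_max_distance`. The published
#' data constrain only the jump frequency (~7.3% of molecules) and mean
#' distance (48.6 nm, 100 nm search cap), not the distribution shape; the
#' exponential is a stand-in.
#'
#' @param k_off_static static -> solution rate.
#' @param k_processive static -> processive rate.
#' @param k_off_processive processive -> solution rate.
#' @param k_static processive -> static rate.
#' @param p_land_static probability that a landing enters the static state.
#' @param speed_mean,speed_sd mean and SD (nm/s) of per-segment speeds.
#' @param speed_min lower truncation of the speed distribution (nm/s).
#' @param segment_length_mean mean (nm) of the latent exponential run length
#'   (run-length mode only).
#' @param motion_mode `"duration"` or `"runlength"`.
#' @param frame_interval seconds per frame.
#' @param n_frames movie length in frames.
#' @param landing_window landings are uniform on `[0, landing_window]` s.
#' @param localization_sd per-coordinate Gaussian localization noise SD (nm).
#' @param jump_rate Poisson rate of jumps during bound time (s^-1).
#' @param jump_distance_scale mean of the exponential jump distance (nm).
#' @param jump_max_distance cap on jump distance (nm), the re-association
#'   search radius.
#' @param drift optional n_frames x 2 matrix of per-frame stage drift
#'   (dx, dy) in nm, shared by all molecules; `NULL` for none.
#' @param arena_nm molecules land uniformly in a square of this side (nm);
#'   only matters when rendering movies.
#' @param n_molecules number of molecules to simulate.
#' @param rng_seed integer master seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(k_off_static = 0.0106,
                       k_processive = 0.00064,
                       k_off_processive = 0.0113,
                       k_static = 0.0379,
                       p_land_static = 0.944,
                       speed_mean = 3.24,
                       speed_sd = 2.68,
                       speed_min = 0.5,
                       segment_length_mean = 38.6,
                       motion_mode = c("duration", "runlength"),
                       frame_interval = 1,
                       n_frames = 1000,
                       landing_window = 500,
                       localization_sd = 1.5,
                       jump_rate = 0.00075,
                       jump_distance_scale = 48.6,
                       jump_max_distance = 100,
                       drift = NULL,
                       arena_nm = 3000,
                       n_molecules = 100,
                       rng_seed = 1L) {
  motion_mode <- match.arg(motion_mode)
  cfg <- list(k_off_static = k_off_static, k_processive = k_processive,
              k_off_processive = k_off_processive, k_static = k_static,
              p_land_static = p_land_static, speed_mean = speed_mean,
              speed_sd = speed_sd, speed_min = speed_min,
              segment_length_mean = segment_length_mean,
              motion_mode = motion_mode, frame_interval = frame_interval,
              n_frames = n_frames, landing_window = landing_window,
              localization_sd = localization_sd, jump_rate = jump_rate,
              jump_distance_scale = jump_distance_scale,
              jump_max_distance = jump_max_distance, drift = drift,
              arena_nm = arena_nm, n_molecules = n_molecules,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  rates <- c("k_off_static", "k_processive", "k_off_processive", "k_static",
             "jump_rate")
  for (r in rates)
    if (!is.numeric(cfg[[r]]) || cfg[[r]] < 0)
      stop("sim_config: '", r, "' must be a non-negative rate", call. = FALSE)
  if (cfg$p_land_static < 0 || cfg$p_land_static > 1)
    stop("sim_config: 'p_land_static' must be in [0, 1]", call. = FALSE)
  if (cfg$frame_interval <= 0)
    stop("sim_config: 'frame_interval' must be > 0", call. = FALSE)
  if (cfg$localization_sd < 0)
    stop("sim_config: 'localization_sd' must be >= 0", call. = FALSE)
  if (cfg$n_frames < 1 || cfg$n_molecules < 0)
    stop("sim_config: 'n_frames' >= 1 and 'n_molecules' >= 0 required",
         call. = FALSE)
  if (!is.null(cfg$drift)) {
    cfg$drift <- as.matrix(cfg$drift)
    if (ncol(cfg$drift) != 2 || nrow(cfg$drift) < cfg$n_frames)
      stop("sim_config: 'drift' must be an n_frames x 2 matrix", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> three-state Cel7A trajectory generator\n")
  cat(sprintf("  rates (s^-1): k_off_static=%.4g k_processive=%.4g k_off_processive=%.4g k_static=%.4g\n",
              x$k_off_static, x$k_processive, x$k_off_processive, x$k_static))
  cat(sprintf("  landing: P(static)=%.3f over [0, %g] s; %d molecules, %d frames @ %g s\n",
              x$p_land_static, x$landing_window, x$n_molecules, x$n_frames,
              x$frame_interval))
  cat(sprintf("  motion: %s mode, speed %.3g +/- %.3g nm/s (>= %.2g), noise %.2g nm\n",
              x$motion_mode, x$speed_mean, x$speed_sd, x$speed_min,
              x$localization_sd))
  invisible(x)
}

#' Movie rendering specification
#'
#' Geometry and photon budget for rendering trajectories into TIRF-like
#' image stacks. The default pixel size matches the instrument (66.0 nm);
#' the default photon budget is set so that single-frame localization
#' precision of a rendered emitter is around 1.5 nm, the tracking precision
#' the analysis assumes.
#'
#' @param field_size image side length in pixels.
#' @param pixel_size nm per pixel.
#' @param psf_sigma PSF Gaussian sigma in nm.
#' @param emitter_photons expected photons per emitter per frame.
#' @param background expected background photons per pixel per frame.
#' @param bead_positions matrix (n x 2) of fiducial bead positions in nm,
#'   or `NULL` to auto-place `n_beads` beads near the field corners.
#' @param bead_photons expected photons per bead per frame (beads are
#'   brighter than emitters, as Tetraspeck beads are brighter than Qdots).
#' @param n_beads number of auto-placed beads when `bead_positions` is NULL.
#' @return an object of class `movie_spec`.
#' @export
movie_spec <- function(field_size = 48,
                       pixel_size = 66.0,
                       psf_sigma = 130,
                       emitter_photons = 15000,
                       background = 50,
                       bead_positions = NULL,
                       bead_photons = 60000,
                       n_beads = 3) {
  if (pixel_size <= 0) stop("movie_spec: pixel_size must be > 0", call. = FALSE)
  if (psf_sigma <= 0) stop("movie_spec: psf_sigma must be > 0", call. = FALSE)
  if (is.null(bead_positions)) {
    side <- field_size * pixel_size
    m <- 0.15 * side
    corners <- rbind(c(m, m), c(side - m, m), c(m, side - m),
                     c(side - m, side - m))
    bead_positions <- corners[seq_len(min(n_beads, 4L)), , drop = FALSE]
  }
  bead_positions <- as.matrix(bead_positions)
  structure(list(field_size = as.integer(field_size), pixel_size = pixel_size,
                 psf_sigma = psf_sigma, emitter_photons = emitter_photons,
                 background = background, bead_positions = bead_positions,
                 bead_photons = bead_photons),
            class = "movie_spec")
}
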