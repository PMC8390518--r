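#' Sample one molecule's state path from the three-state model
#'
#' Draws the sequence of bound states for a single landing event. The
#' molecule lands in the static state with probability `p_land_static`,
#' otherwise in the processive state. Static dwells are exponential with the
#' total exit rate `k_off_static + k_processive`; the exit switches to the
#' processive state with probability `k_processive / (k_off_static +
#' k_processive)` and otherwise unbinds. Processive dwells are exponential
#' with rate `k_off_processive + k_static` in duration mode; in run-length
#' mode the run length is exponential with mean `segment_length_mean` and the
#' dwell is length/speed. Exit from the processive state switches to static
#' with probability `k_static / (k_off_processive + k_static)`.
#'
#' Speeds are drawn per processive segment from the moment-matched truncated
#' normal; the heading is a single uniform angle per bound event (motion is
#' 1D along a cellulose-strand proxy).
#'
#' @param config a [sim_config()].
#' @param speed_par optional precomputed [tnorm_params()] (avoids re-solving
#'   in tight loops).
#' @return list with `states` (data.frame: state, dwell, speed), `heading`
#'   (radians) and `total_dwell` (s). Uses the current RNG stream.
#' @export
sample_state_path <- function(config, speed_par = NULL) {
  if (is.null(speed_par))
    speed_par <- tnorm_params(config$speed_mean, config$speed_sd,
                              config$speed_min)
  exit_static <- config$k_off_static + config$k_processive
  exit_proc <- config$k_off_processive + config$k_static
  state <- if (stats::runif(1) < config$p_land_static) "static" else "processive"
  st <- character(0); dw <- numeric(0); sp <- numeric(0)
  repeat {
    if (state == "static") {
      if (exit_static <= 0)
        stop("non-terminating path: static state has zero total exit rate",
             call. = FALSE)
      dwell <- stats::rexp(1, exit_static)
      st <- c(st, "static"); dw <- c(dw, dwell); sp <- c(sp, NA_real_)
      if (stats::runif(1) < config$k_processive / exit_static) {
        state <- "processive"
      } else break
    } else {
      if (exit_proc <= 0)
        stop("non-terminating path: processive state has zero total exit rate",
             call. = FALSE)
      speed <- rtnorm(1, speed_par)
      if (config$motion_mode == "duration") {
        dwell <- stats::rexp(1, exit_proc)
      } else {
        len <- stats::rexp(1, 1 / config$segment_length_mean)
        dwell <- len / speed
      }
      st <- c(st, "processive"); dw <- c(dw, dwell); sp <- c(sp, speed)
      if (stats::runif(1) < config$k_static / exit_proc) {
        state <- "static"
      } else break
    }
  }
  list(states = data.frame(state = st, dwell = dw, speed = sp,
                           stringsAsFactors = FALSE),
       heading = stats::runif(1, 0, 2 * pi),
       total_dwell = sum(dw))
}

# true (x, y) at times tau (s, relative to landing) for a sampled path,
# before jumps; anchor at origin
true_path_positions <- function(path, tau) {
  sts <- path$states
  ends <- cumsum(sts$dwell)
  starts <- c(0, ends[-length(ends)])
  disp <- ifelse(sts$state == "processive", sts$speed * sts$dwell, 0)
  cumdisp <- c(0, cumsum(disp))
  seg <- findInterval(tau, starts, rightmost.closed = FALSE)
  seg[seg < 1] <- 1
  s <- cumdisp[seg] +
    ifelse(sts$state[seg] == "processive",
           sts$speed[seg] * (tau - starts[seg]), 0)
  cbind(x = s * cos(path$heading), y = s * sin(path$heading))
}

#' Render a sampled state path into an observed trajectory
#'
#' Samples the molecule's true position at the frame times between landing
#' and unbinding (truncated at movie end), inserts jump displacements, and
#' adds independent Gaussian localization noise per coordinate per frame.
#' Jumps are Poisson events during bound time; each instantaneously
#' displaces the molecule (and all later positions) by an exponential radial
#' distance capped at `jump_max_distance`, in a uniform direction, so the
#' observed relocation completes within one frame step.
#'
#' @param path output of [sample_state_path()].
#' @param config a [sim_config()].
#' @param landing_time landing time in seconds.
#' @param anchor length-2 numeric, landing position (nm).
#' @param molecule_id id stamped on the output rows.
#' @return list with `trajectory` (data.frame: molecule_id, frame, t_s,
#'   x_nm, y_nm, intensity) and `jumps` (data.frame: time_s, distance_nm).
#'   Uses the current RNG stream.
#' @export
render_positions <- function(path, config, landing_time = 0,
                             anchor = c(0, 0), molecule_id = 1L) {
  dt <- config$frame_interval
  t_all <- (seq_len(config$n_frames) - 1) * dt
  vis <- t_all >= landing_time & t_all < landing_time + path$total_dwell
  frames <- which(vis) - 1L
  jumps <- data.frame(time_s = numeric(0), distance_nm = numeric(0))
  if (!length(frames)) {
    return(list(trajectory = data.frame(molecule_id = integer(0),
                                        frame = integer(0), t_s = numeric(0),
                                        x_nm = numeric(0), y_nm = numeric(0),
                                        intensity = numeric(0)),
                jumps = jumps))
  }
  tau <- t_all[vis] - landing_time
  pos <- true_path_positions(path, tau)
  # jumps: Poisson over the bound interval
  n_j <- stats::rpois(1, config$jump_rate * path$total_dwell)
  if (n_j > 0) {
    jt <- sort(stats::runif(n_j, 0, path$total_dwell))
    # exponential truncated at the re-association search radius (inverse
    # CDF; clipping instead would pile mass exactly on the cap)
    u <- stats::runif(n_j)
    jd <- -config$jump_distance_scale *
      log(1 - u * (1 - exp(-config$jump_max_distance /
                             config$jump_distance_scale)))
    ja <- stats::runif(n_j, 0, 2 * pi)
    for (k in seq_len(n_j)) {
      after <- tau >= jt[k]
      pos[after, 1] <- pos[after, 1] + jd[k] * cos(ja[k])
      pos[after, 2] <- pos[after, 2] + jd[k] * sin(ja[k])
    }
    jumps <- data.frame(time_s = landing_time + jt, distance_nm = jd)
  }
  x <- anchor[1] + pos[, 1]
  y <- anchor[2] + pos[, 2]
  if (!is.null(config$drift)) {
    x <- x + config$drift[frames + 1L, 1]
    y <- y + config$drift[frames + 1L, 2]
  }
  if (config$localization_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, config$localization_sd)
    y <- y + stats::rnorm(length(y), 0, config$localization_sd)
  }
  list(trajectory = data.frame(molecule_id = molecule_id, frame = frames,
                               t_s = t_all[vis], x_nm = x, y_nm = y,
                               intensity = stats::rnorm(length(x), 1000, 50)),
       jumps = jumps)
}

#' Simulate a full single-molecule experiment
#'
#' Samples `n_molecules` landing events with landing times uniform on
#' `[0, landing_window]`, renders each into an observed trajectory, and
#' returns trajectories alongside the ground truth. Fully reproducible from
#' `config$rng_seed`.
#'
#' @param config a [sim_config()].
#' @return list with `trajectories` (one data.frame, schema molecule_id,
#'   frame, t_s, x_nm, y_nm, intensity) and `ground_truth` (list per
#'   molecule: landing_time, states, heading, total_dwell, anchor, jumps).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  speed_par <- tnorm_params(config$speed_mean, config$speed_sd,
                            config$speed_min)
  trajs <- vector("list", config$n_molecules)
  gt <- vector("list", config$n_molecules)
  for (i in seq_len(config$n_molecules)) {
    landing <- stats::runif(1, 0, config$landing_window)
    anchor <- stats::runif(2, 0.1 * config$arena_nm, 0.9 * config$arena_nm)
    path <- sample_state_path(config, speed_par)
    rp <- render_positions(path, config, landing_time = landing,
                           anchor = anchor, molecule_id = i)
    trajs[[i]] <- rp$trajectory
    gt[[i]] <- list(molecule_id = i, landing_time = landing,
                    states = path$states, heading = path$heading,
                    total_dwell = path$total_dwell, anchor = anchor,
                    jumps = rp$jumps)
  }
  trajectories <- do.call(rbind, trajs)
  if (is.null(trajectories))
    trajectories <- data.frame(molecule_id = integer(0), frame = integer(0),
                               t_s = numeric(0), x_nm = numeric(0),
                               y_nm = numeric(0), intensity = numeric(0))
  list(trajectories = trajectories, ground_truth = gt)
}

#' Calibrate the latent run-length scale to a detected-segment mean
#'
#' In run-length mode the generator draws latent exponential run lengths,
#' but the analysis only counts segments with net displacement at or above
#' the detection radius (10 nm) and duration at or above the minimum
#' processive duration (5 s). Published run-length means describe detected
#' segments, so emulating them requires inverting the detection model:
#' given a target detected mean, this solves for the latent exponential
#' scale by numerical integration of the detection probability and the
#' detected-length expectation over the speed distribution. For a segment at
#' speed v the detection threshold is `max(min_displacement,
#' min_duration * v)` and, by memorylessness, the detected mean at that
#' speed is threshold + scale.
#'
#' @param target_detected_mean target mean (nm) of detected run lengths.
#' @param config a [sim_config()] supplying the speed distribution.
#' @param min_displacement detection radius (nm), default 10.
#' @param min_duration minimum processive duration (s), default 5.
#' @return latent exponential mean (nm) to use as `segment_length_mean`.
#' @export
calibrate_run_length_scale <- function(target_detected_mean, config,
                                       min_displacement = 10,
                                       min_duration = 5) {
  par <- tnorm_params(config$speed_mean, config$speed_sd, config$speed_min)
  p0 <- stats::pnorm((par$lower - par$mu) / par$sigma)
  detected_mean <- function(scale) {
    f_num <- function(v) {
      thr <- pmax(min_displacement, min_duration * v)
      w <- exp(-thr / scale) * (thr + scale)
      w * stats::dnorm(v, par$mu, par$sigma) / (1 - p0)
    }
    f_den <- function(v) {
      thr <- pmax(min_displacement, min_duration * v)
      exp(-thr / scale) * stats::dnorm(v, par$mu, par$sigma) / (1 - p0)
    }
    lo <- par$lower; hi <- par$mu + 8 * par$sigma
    stats::integrate(f_num, lo, hi)$value /
      stats::integrate(f_den, lo, hi)$value
  }
  stats::uniroot(function(s) detected_mean(s) - target_detected_mean,
                 interval = c(1, 10 * target_detected_mean),
                 tol = 1e-8)$root
}
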