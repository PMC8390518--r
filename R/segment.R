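#' Segmentation parameters (operational motion-state definitions)
#'
#' Thresholds and filters for classifying trajectories into static and
#' processive segments and jump events. Defaults are the study's operational
#' definitions: static = within 10 nm of the anchor; processive = net
#' displacement of at least 10 nm sustained for at least 5 s; jump = more
#' than 10 nm within two frames with re-association within 100 nm; tracks
#' shorter than 10 s, landing after 500 s, or longer than 510 s are
#' excluded; dwell fits of static segments use the 5-310 s window.
#'
#' @param static_radius nm, static anchor radius.
#' @param min_processive_duration s, minimum processive segment duration.
#' @param min_static_segment s, static segments shorter than this are merged
#'   into neighbours.
#' @param min_total_duration s, minimum total bound duration for inclusion.
#' @param jump_threshold nm, minimum jump displacement.
#' @param jump_max_frames frames a jump may span.
#' @param jump_search_radius nm, maximum jump displacement (re-association
#'   search radius).
#' @param boxcar_window frames, odd, for position smoothing.
#' @param landing_cutoff s, latest admissible landing time.
#' @param max_total_duration s, tracks bound longer are excluded as outliers.
#' @param static_fit_min,static_fit_max s, dwell-fit window for static
#'   segments of processive molecules.
#' @param static_mode `"max_deviation"` (default: every smoothed position
#'   within `static_radius` of the anchor) or `"sd"` (positional SD below
#'   the radius) for the static criterion.
#' @param stop_hysteresis fraction of `static_radius` the trailing window
#'   displacement must fall below to close a processive segment; below 1 it
#'   keeps localization noise from prematurely stopping slow segments (a
#'   genuine arrival shows only noise-level displacement).
#' @param velocity_mode `"net"` (net displacement / duration, default) or
#'   `"fit"` (slope of distance-from-start vs time).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(static_radius = 10,
                                min_processive_duration = 5,
                                min_static_segment = 5,
                                min_total_duration = 10,
                                jump_threshold = 10,
                                jump_max_frames = 2,
                                jump_search_radius = 100,
                                boxcar_window = 5,
                                landing_cutoff = 500,
                                max_total_duration = 510,
                                static_fit_min = 5,
                                static_fit_max = 310,
                                static_mode = c("max_deviation", "sd"),
                                velocity_mode = c("net", "fit"),
                                stop_hysteresis = 0.7) {
  p <- list(static_radius = static_radius,
            min_processive_duration = min_processive_duration,
            min_static_segment = min_static_segment,
            min_total_duration = min_total_duration,
            jump_threshold = jump_threshold,
            jump_max_frames = as.integer(jump_max_frames),
            jump_search_radius = jump_search_radius,
            boxcar_window = as.integer(boxcar_window),
            landing_cutoff = landing_cutoff,
            max_total_duration = max_total_duration,
            static_fit_min = static_fit_min,
            static_fit_max = static_fit_max,
            static_mode = match.arg(static_mode),
            velocity_mode = match.arg(velocity_mode),
            stop_hysteresis = stop_hysteresis)
  num <- p[!(names(p) %in% c("static_mode", "velocity_mode"))]
  if (any(!vapply(num, is.numeric, logical(1))) || any(unlist(num) <= 0))
    stop("segmentation_params: all thresholds must be positive numbers",
         call. = FALSE)
  if (p$static_fit_min >= p$static_fit_max)
    stop("segmentation_params: static_fit_min must be < static_fit_max",
         call. = FALSE)
  if (p$jump_max_frames < 1)
    stop("segmentation_params: jump_max_frames must be >= 1", call. = FALSE)
  structure(p, class = "segmentation_params")
}

#' Centered boxcar smoothing with shrinking edge windows
#'
#' @param v numeric vector.
#' @param window odd window length in frames.
#' @return smoothed vector of the same length; at the edges the window
#'   shrinks to what fits inside the series.
#' @export
boxcar <- function(v, window = 5) {
  n <- length(v)
  if (n < 1) stop("cannot smooth an empty series", call. = FALSE)
  if (window %% 2 != 1) stop("boxcar window must be odd", call. = FALSE)
  h <- (window - 1) %/% 2
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smooth the x/y positions of a trajectory
#'
#' @param traj data.frame with x_nm, y_nm (one molecule, frame-ordered).
#' @param window odd boxcar window in frames.
#' @return `traj` with positions replaced by their boxcar averages.
#' @export
smooth_positions <- function(traj, window = 5) {
  traj$x_nm <- boxcar(traj$x_nm, window)
  traj$y_nm <- boxcar(traj$y_nm, window)
  traj
}

dist2d <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

#' Detect jump events on raw positions
#'
#' A jump is a displacement exceeding `jump_threshold` completed within
#' `jump_max_frames`, with re-association within `jump_search_radius` of the
#' pre-jump position. To distinguish jumps from sustained fast processive
#' motion (and from single-frame localization outliers), the candidate span
#' must be isolated: the flanking windows of `2 * jump_max_frames` frames on
#' either side (truncated at the track ends; an empty window passes, so
#' landing jumps are kept) must each have net displacement below the
#' threshold — a relocation has quasi-static flanks, which sustained motion
#' cannot fake over windows longer than the span — and a multi-frame span
#' must contain one dominant single-frame step (at least 70% of the
#' threshold), since a real relocation is instantaneous and at most
#' straddles one frame boundary. Spans overlapping an already-accepted
#' shorter jump are skipped.
#'
#' @param traj one molecule's trajectory (frame-ordered; raw positions).
#' @param params a [segmentation_params()].
#' @return list with `jumps` (data.frame: frame_start, frame_end,
#'   distance_nm, at_landing) and `blocks` (list of row-index ranges
#'   `c(first, last)` of the jump-free pieces).
#' @export
detect_jumps <- function(traj, params) {
  n <- nrow(traj)
  x <- traj$x_nm; y <- traj$y_nm
  acc <- list()
  covered <- rep(FALSE, n)   # TRUE where a jump interval (i, i+s] starts
  for (s in seq_len(params$jump_max_frames)) {
    if (n <= s) break
    for (i in seq_len(n - s)) {
      if (any(covered[i:(i + s - 1)])) next
      d <- dist2d(x[i], y[i], x[i + s], y[i + s])
      if (d <= params$jump_threshold || d > params$jump_search_radius) next
      if (s > 1) {
        steps <- dist2d(x[i:(i + s - 1)], y[i:(i + s - 1)],
                        x[(i + 1):(i + s)], y[(i + 1):(i + s)])
        if (max(steps) < 0.7 * params$jump_threshold) next
      }
      L <- 2L * params$jump_max_frames
      ip <- max(1L, i - L)
      pre_ok <- ip == i ||
        dist2d(x[ip], y[ip], x[i], y[i]) <= params$jump_threshold
      iq <- min(n, i + s + L)
      post_ok <- iq == i + s ||
        dist2d(x[i + s], y[i + s], x[iq], y[iq]) <= params$jump_threshold
      if (pre_ok && post_ok) {
        acc[[length(acc) + 1L]] <-
          data.frame(frame_start = traj$frame[i],
                     frame_end = traj$frame[i + s],
                     idx_start = i, idx_end = i + s, distance_nm = d,
                     at_landing = i <= params$jump_max_frames)
        covered[i:(i + s - 1)] <- TRUE
      }
    }
  }
  if (length(acc)) {
    jumps <- do.call(rbind, acc)
    jumps <- jumps[order(jumps$idx_start), ]
    rownames(jumps) <- NULL
  } else {
    jumps <- data.frame(frame_start = integer(0), frame_end = integer(0),
                        idx_start = integer(0), idx_end = integer(0),
                        distance_nm = numeric(0), at_landing = logical(0))
  }
  starts <- c(1L, jumps$idx_end)
  ends <- c(jumps$idx_start, n)
  blocks <- Map(c, starts, ends)
  blocks <- blocks[vapply(blocks, function(b) b[2] >= b[1], logical(1))]
  list(jumps = jumps, blocks = blocks)
}

# anchor-based changepoint scan of one smoothed jump-free block; returns a
# data.frame of index-based segments (kind, i_start, i_end)
segment_block_scan <- function(t, xs, ys, params, dt) {
  n <- length(t)
  R <- params$static_radius
  W <- max(1L, round(params$min_processive_duration / dt))
  segs <- list()
  push <- function(kind, a, b)
    segs[[length(segs) + 1L]] <<- data.frame(kind = kind, i_start = a,
                                             i_end = b)
  i <- 1L
  while (i <= n) {
    d <- dist2d(xs[i], ys[i], xs[i:n], ys[i:n])
    exceeds <- if (params$static_mode == "sd") {
      # running positional SD about the anchor; exceeds when 2D RMS > R
      cum_r2 <- cumsum(d^2) / seq_along(d)
      which(sqrt(cum_r2) > R)[1]
    } else which(d > R)[1]
    if (is.na(exceeds)) {
      push("static", i, n)
      break
    }
    j <- i + exceeds - 1L
    # excursion start: walk back to the local distance minimum
    e <- j
    while (e > i && d[e - i] < d[e - i + 1L]) e <- e - 1L
    # motion stop: first frame whose trailing window moved less than the
    # hysteresis fraction of R. The window is adaptive: at least W frames,
    # but scaled to the time this excursion needed to cover R, so
    # slow-but-real motion (advancing less than R per W frames) is not cut
    # short the moment it opens.
    Wseg <- max(W, min(60L, as.integer(ceiling(1.3 * (j - e)))))
    k0 <- max(j, e + Wseg)
    stopk <- NA_integer_
    if (k0 <= n) {
      k <- k0
      while (k <= n) {
        if (dist2d(xs[k - Wseg], ys[k - Wseg], xs[k], ys[k]) <
            params$stop_hysteresis * R) {
          stopk <- k
          break
        }
        k <- k + 1L
      }
    }
    if (is.na(stopk)) {
      # no quiet trailing window before the block ends: the end of motion
      # is the farthest point reached (equals the block end if the motion
      # runs through it, otherwise the arrival point of a short tail)
      win <- j:n
    } else {
      win <- (stopk - Wseg):stopk
    }
    de <- dist2d(xs[e], ys[e], xs[win], ys[win])
    endk <- win[which.max(de)]
    dur <- t[endk] - t[e]
    net <- dist2d(xs[e], ys[e], xs[endk], ys[endk])
    if (dur >= params$min_processive_duration && net >= R) {
      if (e > i) push("static", i, e)
      push("processive", e, endk)
      if (endk >= n) break
      i <- endk
    } else {
      # unsustained excursion: close the static stretch and re-anchor
      push("static", i, j)
      if (j >= n) break
      i <- j
    }
  }
  do.call(rbind, segs)
}

# merge adjacent same-kind segments, then absorb static segments shorter
# than min_static_segment into their neighbours
merge_segments <- function(segs, t, params) {
  repeat {
    changed <- FALSE
    k <- 1L
    while (k < nrow(segs)) {
      if (segs$kind[k] == segs$kind[k + 1]) {
        segs$i_end[k] <- segs$i_end[k + 1]
        segs <- segs[-(k + 1), ]
        changed <- TRUE
      } else k <- k + 1L
    }
    durs <- t[segs$i_end] - t[segs$i_start]
    short <- which(segs$kind == "static" &
                   durs < params$min_static_segment)
    short <- short[rep(nrow(segs) > 1, length(short))]
    if (length(short)) {
      k <- short[1]
      if (k == 1L) {
        segs$i_start[2] <- segs$i_start[1]
      } else if (k == nrow(segs)) {
        segs$i_end[k - 1] <- segs$i_end[k]
      } else {
        # interior short static between two processives: absorb backwards
        segs$i_end[k - 1] <- segs$i_end[k]
      }
      segs <- segs[-k, ]
      changed <- TRUE
    }
    if (!changed) break
  }
  rownames(segs) <- NULL
  segs
}

#' Segment one trajectory into static and processive segments
#'
#' Jumps are detected on the raw positions and split the track into
#' jump-free blocks; each block is boxcar-smoothed and scanned with an
#' anchor-based changepoint rule: a static segment holds while the smoothed
#' positions stay within `static_radius` of the segment anchor; an excursion
#' that sustains a net displacement of at least `static_radius` for at least
#' `min_processive_duration` opens a processive segment at the excursion
#' start, which closes when the trailing `min_processive_duration` window
#' moves less than `static_radius` (the new static anchor is the current
#' smoothed position). Static segments shorter than `min_static_segment`
#' are merged into neighbours. The last segment of the track is `unbind`
#' (or `censored` if the track reaches the movie end); segments cut short
#' by a jump are `censored` (the jump interrupts the dwell without
#' revealing the exit route); all others are `switch`.
#'
#' @param traj one molecule's trajectory (data.frame: molecule_id, frame,
#'   t_s, x_nm, y_nm).
#' @param params a [segmentation_params()].
#' @param movie_end_frame last frame index of the movie (0-based), used to
#'   flag censoring; `NULL` disables censoring.
#' @return object of class `segmented_trajectory`: list with `molecule_id`,
#'   `segments` (kind, t_start, t_end, duration, net_displacement, velocity,
#'   terminal_fate), `jumps`, `molecule_class` (`"static_only"` or
#'   `"processive"`), `landing_time`, `total_bound_duration`.
#' @export
segment_trajectory <- function(traj, params = segmentation_params(),
                               movie_end_frame = NULL) {
  traj <- traj[order(traj$frame), ]
  n <- nrow(traj)
  if (n < 1) stop("cannot segment an empty trajectory", call. = FALSE)
  dt <- if (n > 1) stats::median(diff(traj$t_s)) else 1
  jd <- detect_jumps(traj, params)
  out_segs <- list()
  n_blocks <- length(jd$blocks)
  for (b in seq_len(n_blocks)) {
    rng <- jd$blocks[[b]]
    idx <- rng[1]:rng[2]
    tb <- traj$t_s[idx]
    xs <- boxcar(traj$x_nm[idx], params$boxcar_window)
    ys <- boxcar(traj$y_nm[idx], params$boxcar_window)
    if (length(idx) < 2) {
      segs <- data.frame(kind = "static", i_start = 1L,
                         i_end = length(idx))
    } else {
      segs <- segment_block_scan(tb, xs, ys, params, dt)
      segs <- merge_segments(segs, tb, params)
    }
    segs$t_start <- tb[segs$i_start]
    segs$t_end <- tb[segs$i_end]
    # the boxcar delays/advances apparent motion onsets by its half-width:
    # shared static<->processive boundaries are shifted into the processive
    # side to compensate, which de-smears both segment durations
    hshift <- (params$boxcar_window - 1L) %/% 2L * dt
    nseg0 <- nrow(segs)
    if (nseg0 > 1) {
      for (k in seq_len(nseg0 - 1L)) {
        if (segs$kind[k] == "static" && segs$kind[k + 1] == "processive") {
          b <- min(segs$t_end[k] + hshift, segs$t_end[k + 1] - dt)
          segs$t_end[k] <- b; segs$t_start[k + 1] <- b
        } else if (segs$kind[k] == "processive" &&
                   segs$kind[k + 1] == "static") {
          b <- max(segs$t_end[k] - hshift, segs$t_start[k] + dt)
          segs$t_end[k] <- b; segs$t_start[k + 1] <- b
        }
      }
    }
    segs$duration <- segs$t_end - segs$t_start
    # processive run lengths are measured anchor-to-anchor: endpoints are
    # pushed by the boxcar half-width into the flanking static segments,
    # otherwise the smoothing window mixes moving and anchored frames and
    # clips every run by about one window. At block edges (landing, unbind
    # or jump boundaries, where no flanking anchor exists) the raw edge
    # position is used instead of the edge-shrunk boxcar (which is pulled
    # into the segment by about one frame of motion), and half a frame of
    # motion is added for the unobserved sampling phase.
    h <- (params$boxcar_window - 1L) %/% 2L
    ns <- max(segs$i_end)
    nseg <- nrow(segs)
    pk <- segs$kind == "processive"
    a_start <- ifelse(pk, pmax(1L, segs$i_start - h), segs$i_start)
    a_end <- ifelse(pk, pmin(ns, segs$i_end + h), segs$i_end)
    px_s <- xs[a_start]; py_s <- ys[a_start]
    px_e <- xs[a_end]; py_e <- ys[a_end]
    rx <- traj$x_nm[idx]; ry <- traj$y_nm[idx]
    edge_s <- pk & segs$i_start == 1L
    edge_e <- pk & segs$i_end == ns
    px_s[edge_s] <- rx[1]; py_s[edge_s] <- ry[1]
    px_e[edge_e] <- rx[ns]; py_e[edge_e] <- ry[ns]
    net0 <- dist2d(px_s, py_s, px_e, py_e)
    # smear-corrected duration: each static-flanked boundary inflates the
    # measured duration by the boxcar half-width; floored at the minimum
    # processive duration (a detected segment moved at least that long)
    flanks <- (c("", segs$kind[-nseg]) == "static") +
              (c(segs$kind[-1], "") == "static")
    # durations are already de-smeared by the boundary shift above; floor
    # at the minimum processive duration a detected segment must have moved
    d_corr <- pmax(segs$duration, params$min_processive_duration)
    # second-order ratio-bias (Jensen) correction: the measured duration
    # carries boundary-placement noise of about the boxcar half-width per
    # smoothed flank, which would otherwise inflate E[net / duration]
    v0 <- net0 * d_corr / (d_corr^2 + (h * dt)^2 * flanks)
    segs$net_displacement <- net0 +
      ifelse(pk, v0 * dt / 2 * (edge_s + edge_e), 0)
    segs$velocity <- NA_real_
    if (any(pk)) {
      if (params$velocity_mode == "fit") {
        for (k in which(pk)) {
          ii <- segs$i_start[k]:segs$i_end[k]
          dd <- dist2d(xs[segs$i_start[k]], ys[segs$i_start[k]],
                       xs[ii], ys[ii])
          segs$velocity[k] <- stats::coef(stats::lm(dd ~ tb[ii]))[2]
        }
      } else {
        # v0, not the phase-corrected net over d_corr: the extra half-frame
        # of run length corresponds to unobserved time outside d_corr
        segs$velocity[pk] <- v0[pk]
      }
    }
    segs$terminal_fate <- "switch"
    if (b < n_blocks) {
      segs$terminal_fate[nrow(segs)] <- "censored"   # cut short by a jump
    } else {
      last_fate <- if (!is.null(movie_end_frame) &&
                       traj$frame[n] >= movie_end_frame) "censored"
                   else "unbind"
      segs$terminal_fate[nrow(segs)] <- last_fate
    }
    segs$i_start <- NULL; segs$i_end <- NULL
    out_segs[[b]] <- segs
  }
  segments <- do.call(rbind, out_segs)
  rownames(segments) <- NULL
  jumps <- jd$jumps
  jumps$idx_start <- NULL; jumps$idx_end <- NULL
  structure(list(
    molecule_id = traj$molecule_id[1],
    segments = segments,
    jumps = jumps,
    molecule_class = if (any(segments$kind == "processive")) "processive"
                     else "static_only",
    landing_time = traj$t_s[1],
    total_bound_duration = traj$t_s[n] - traj$t_s[1] + dt,
    censored = !is.null(movie_end_frame) && traj$frame[n] >= movie_end_frame
  ), class = "segmented_trajectory")
}

#' Segment every molecule in a trajectory table
#'
#' @param trajectories data.frame with molecule_id, frame, t_s, x_nm, y_nm.
#' @param params a [segmentation_params()].
#' @param movie_end_frame last movie frame (0-based) for censoring flags.
#' @return list of [segment_trajectory()] results, one per molecule.
#' @export
segment_cohort <- function(trajectories, params = segmentation_params(),
                           movie_end_frame = NULL) {
  ids <- unique(trajectories$molecule_id)
  lapply(ids, function(id)
    segment_trajectory(trajectories[trajectories$molecule_id == id, ],
                       params, movie_end_frame))
}

#' Apply the study's inclusion filters to a segmented cohort
#'
#' Drops molecules with total bound duration below `min_total_duration`,
#' above `max_total_duration`, or landing after `landing_cutoff`.
#'
#' @param segmented list of `segmented_trajectory` objects.
#' @param params a [segmentation_params()].
#' @return list with `retained` (filtered list) and `report` (data.frame of
#'   counts: n_input, n_short, n_long, n_late, n_retained).
#' @export
apply_filters <- function(segmented, params = segmentation_params()) {
  dur <- vapply(segmented, function(s) s$total_bound_duration, numeric(1))
  land <- vapply(segmented, function(s) s$landing_time, numeric(1))
  short <- dur < params$min_total_duration
  long <- !short & dur > params$max_total_duration
  late <- !short & !long & land > params$landing_cutoff
  keep <- !(short | long | late)
  list(retained = segmented[keep],
       report = data.frame(n_input = length(segmented),
                           n_short = sum(short), n_long = sum(long),
                           n_late = sum(late), n_retained = sum(keep)))
}

#' Per-segment statistics
#'
#' Run length is the net displacement between the segment endpoints on
#' smoothed positions (jump displacement never contributes because jumps
#' split tracks before segmentation); velocity is run length over duration.
#'
#' @param seg one row of a `segments` data.frame.
#' @return list with `velocity` (nm/s, NA for static), `run_length` (nm) and
#'   `duration` (s).
#' @export
segment_stats <- function(seg) {
  if (seg$duration <= 0) stop("segment has zero duration", call. = FALSE)
  list(velocity = if (seg$kind == "processive")
         seg$net_displacement / seg$duration else NA_real_,
       run_length = seg$net_displacement,
       duration = seg$duration)
}

#' Flatten a segmented cohort into one segments table
#'
#' @param segmented list of `segmented_trajectory` objects.
#' @return data.frame of all segments with molecule_id and molecule_class.
#' @export
segment_table <- function(segmented) {
  do.call(rbind, lapply(segmented, function(s) {
    cbind(molecule_id = s$molecule_id, s$segments,
          molecule_class = s$molecule_class)
  }))
}
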