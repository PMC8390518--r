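#' Detect candidate spots in one frame
#'
#' Local maxima above an intensity threshold, with non-maximum suppression:
#' when two maxima lie within `min_separation` pixels, the brighter one is
#' kept.
#'
#' @param img numeric matrix (one frame; rows = y, cols = x).
#' @param intensity_threshold absolute counts a maximum must exceed.
#' @param min_separation minimum separation in pixels.
#' @return data.frame with columns `row`, `col`, `value` (may be empty).
#' @export
detect_spots <- function(img, intensity_threshold, min_separation = 3) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(data.frame(row = integer(0), col = integer(0),
                                          value = numeric(0)))
  core <- img[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > intensity_threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (core >= img[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(row = integer(0), col = integer(0),
                                    value = numeric(0)))
  cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                     value = img[cbind(idx[, 1] + 1L, idx[, 2] + 1L)])
  cand <- cand[order(-cand$value), ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand$row[j] - cand$row[i])^2 + (cand$col[j] - cand$col[i])^2
      keep[j[d2 < min_separation^2]] <- FALSE
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

#' Fit a symmetric 2D Gaussian to one spot
#'
#' Levenberg-Marquardt least squares of
#' `offset + amplitude * exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))`
#' over a square window, via [minpack.lm::nlsLM]. The sub-pixel center is
#' converted to nm with the pixel size; pixel centers sit at
#' `(index - 0.5) * pixel_size` so coordinates share the image-corner origin
#' used by the renderer.
#'
#' @param img numeric matrix (one frame).
#' @param center length-2 integer-ish `(row, col)` initial guess.
#' @param window half-width in pixels; the fitted square has side
#'   `2 * window + 1` and must lie inside the image.
#' @param pixel_size nm per pixel.
#' @return list of class `spot_fit`: `x`, `y`, `sigma` (nm), `amplitude`,
#'   `offset` (counts), `rss`, `ok` (logical), `reason` (when rejected).
#' @export
fit_spot <- function(img, center, window = 4, pixel_size = 66.0) {
  r0 <- round(center[1]); c0 <- round(center[2])
  if (r0 - window < 1 || r0 + window > nrow(img) ||
      c0 - window < 1 || c0 + window > ncol(img))
    stop("fit window extends outside the image", call. = FALSE)
  rows <- (r0 - window):(r0 + window)
  cols <- (c0 - window):(c0 + window)
  z <- img[rows, cols]
  d <- data.frame(z = as.vector(z),
                  ry = rep(rows, times = length(cols)),
                  cx = rep(cols, each = length(rows)))
  amp0 <- max(z) - min(z)
  start <- list(A = max(amp0, 1), x0 = c0, y0 = r0, s = 1.5, b = min(z))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((cx - x0)^2 + (ry - y0)^2) / (2 * s^2)),
      data = d, start = start,
      lower = c(A = 0, x0 = min(cols) - 1, y0 = min(rows) - 1, s = 0.3,
                b = -Inf),
      upper = c(A = Inf, x0 = max(cols) + 1, y0 = max(rows) + 1,
                s = 3 * window, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(ok = FALSE, reason = conditionMessage(fit)),
                     class = "spot_fit"))
  p <- as.list(stats::coef(fit))
  if (p$A <= 0)
    return(structure(list(ok = FALSE, reason = "non-positive amplitude"),
                     class = "spot_fit"))
  structure(list(x = (p$x0 - 0.5) * pixel_size,
                 y = (p$y0 - 0.5) * pixel_size,
                 sigma = p$s * pixel_size, amplitude = p$A, offset = p$b,
                 rss = sum(stats::resid(fit)^2), ok = TRUE, reason = NA),
            class = "spot_fit")
}

#' Localize every spot in every frame of a stack
#'
#' Runs [detect_spots()] then [fit_spot()] per frame; rejected fits and
#' candidates whose window would leave the image are dropped.
#'
#' @param stack 3D array `[row, col, frame]`.
#' @param intensity_threshold detection threshold in counts; by default
#'   `median(frame) + 6 * mad(frame)` per frame.
#' @param min_separation pixels, see [detect_spots()].
#' @param window fit half-width in pixels.
#' @param pixel_size nm per pixel.
#' @return data.frame: frame (0-based), x_nm, y_nm, sigma_nm, amplitude,
#'   offset, rss.
#' @export
localize_stack <- function(stack, intensity_threshold = NULL,
                           min_separation = 3, window = 4,
                           pixel_size = 66.0) {
  out <- list()
  for (f in seq_len(dim(stack)[3])) {
    img <- stack[, , f]
    thr <- if (is.null(intensity_threshold))
      stats::median(img) + 6 * stats::mad(img) else intensity_threshold
    cand <- detect_spots(img, thr, min_separation)
    for (i in seq_len(nrow(cand))) {
      if (cand$row[i] - window < 1 || cand$row[i] + window > nrow(img) ||
          cand$col[i] - window < 1 || cand$col[i] + window > ncol(img))
        next
      sf <- fit_spot(img, c(cand$row[i], cand$col[i]), window, pixel_size)
      if (isTRUE(sf$ok))
        out[[length(out) + 1L]] <-
          data.frame(frame = f - 1L, x_nm = sf$x, y_nm = sf$y,
                     sigma_nm = sf$sigma, amplitude = sf$amplitude,
                     offset = sf$offset, rss = sf$rss)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), sigma_nm = numeric(0),
                      amplitude = numeric(0), offset = numeric(0),
                      rss = numeric(0)))
  do.call(rbind, out)
}

#' Link per-frame localizations into tracks
#'
#' Greedy nearest-neighbour linking: active tracks are visited in order of
#' track id; each claims its nearest unclaimed spot in the next frame within
#' `max_step` (ties broken by lowest spot index). Unclaimed spots start new
#' tracks; tracks are closed after `max_gap` missed frames. Tracks present
#' in at least `fiducial_presence` of all frames are flagged as fiducial
#' candidates.
#'
#' @param spots data.frame from [localize_stack()].
#' @param max_step maximum frame-to-frame step in nm.
#' @param max_gap allowed missed frames.
#' @param n_frames total frames in the movie.
#' @param fiducial_presence fraction of frames a fiducial must span
#'   (default 0.99).
#' @return data.frame of `spots` plus `track_id` and `is_fiducial`.
#' @export
link_spots <- function(spots, max_step = 200, max_gap = 1, n_frames = NULL,
                       fiducial_presence = 0.99) {
  if (!nrow(spots))
    return(cbind(spots, track_id = integer(0), is_fiducial = logical(0)))
  spots <- spots[order(spots$frame), ]
  rownames(spots) <- NULL
  if (is.null(n_frames)) n_frames <- max(spots$frame) + 1L
  track_id <- rep(NA_integer_, nrow(spots))
  # active tracks: id -> (x, y, last_frame)
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- integer(0); next_id <- 1L
  for (f in sort(unique(spots$frame))) {
    idx <- which(spots$frame == f)
    open <- act_f >= f - 1L - max_gap
    act_id <- act_id[open]; act_x <- act_x[open]; act_y <- act_y[open]
    act_f <- act_f[open]
    claimed <- rep(FALSE, length(idx))
    for (a in seq_along(act_id)) {
      if (!length(idx)) break
      d <- sqrt((spots$x_nm[idx] - act_x[a])^2 +
                (spots$y_nm[idx] - act_y[a])^2)
      d[claimed] <- Inf
      j <- which(d <= max_step)
      if (length(j)) {
        pick <- j[which.min(d[j])]   # which.min returns the first minimum:
        claimed[pick] <- TRUE        # deterministic lowest-index tie-break
        track_id[idx[pick]] <- act_id[a]
        act_x[a] <- spots$x_nm[idx[pick]]
        act_y[a] <- spots$y_nm[idx[pick]]
        act_f[a] <- f
      }
    }
    for (k in which(!claimed)) {
      track_id[idx[k]] <- next_id
      act_id <- c(act_id, next_id); act_x <- c(act_x, spots$x_nm[idx[k]])
      act_y <- c(act_y, spots$y_nm[idx[k]]); act_f <- c(act_f, f)
      next_id <- next_id + 1L
    }
  }
  spots$track_id <- track_id
  span <- tapply(spots$frame, spots$track_id, function(fr) length(unique(fr)))
  fid <- as.integer(names(span))[span >= fiducial_presence * n_frames]
  spots$is_fiducial <- spots$track_id %in% fid
  spots
}

#' Subtract fiducial-derived stage drift from tracks
#'
#' Per-frame drift is the mean displacement of the fiducial tracks from
#' their frame-0 positions; it is subtracted from every track. Frames where
#' a fiducial is missing are linearly interpolated from its neighbours.
#'
#' @param tracks data.frame with frame, x_nm, y_nm, track_id (non-fiducial
#'   tracks).
#' @param fiducials data.frame with the same columns for fiducial tracks;
#'   at least one must be present.
#' @param n_frames total frames.
#' @return list with `tracks` (drift-subtracted copy of `tracks`) and
#'   `drift` (data.frame frame, dx_nm, dy_nm).
#' @export
correct_drift <- function(tracks, fiducials, n_frames = NULL) {
  if (is.null(fiducials) || !nrow(fiducials))
    stop("drift correction requires at least one fiducial track",
         call. = FALSE)
  if (is.null(n_frames))
    n_frames <- max(c(tracks$frame, fiducials$frame)) + 1L
  frames <- 0:(n_frames - 1L)
  ids <- unique(fiducials$track_id)
  dx <- matrix(NA_real_, length(ids), n_frames)
  dy <- matrix(NA_real_, length(ids), n_frames)
  for (i in seq_along(ids)) {
    fi <- fiducials[fiducials$track_id == ids[i], ]
    fi <- fi[order(fi$frame), ]
    x <- stats::approx(fi$frame, fi$x_nm, xout = frames, rule = 2)$y
    y <- stats::approx(fi$frame, fi$y_nm, xout = frames, rule = 2)$y
    dx[i, ] <- x - x[1]
    dy[i, ] <- y - y[1]
  }
  drift <- data.frame(frame = frames, dx_nm = colMeans(dx),
                      dy_nm = colMeans(dy))
  out <- tracks
  m <- match(out$frame, drift$frame)
  out$x_nm <- out$x_nm - drift$dx_nm[m]
  out$y_nm <- out$y_nm - drift$dy_nm[m]
  list(tracks = out, drift = drift)
}
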