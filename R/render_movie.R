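#' Render trajectories into a TIRF-like image stack
#'
#' Each frame is a constant background plus one symmetric 2D Gaussian spot
#' per visible emitter and per fiducial bead, with Poisson counting noise.
#' Spot photons are integrated over pixel areas (difference of normal CDFs),
#' not sampled at pixel centers. Beads are present in every frame. An
#' optional per-frame drift is applied to all objects (emitters and beads
#' share the stage).
#'
#' Emitters falling outside the field in a frame are dropped from that frame
#' with a warning.
#'
#' @param trajectories data.frame with columns molecule_id, frame, x_nm,
#'   y_nm (positions BEFORE drift; pass ground-truth or noiseless positions
#'   for physically meaningful rendering).
#' @param spec a [movie_spec()].
#' @param n_frames number of frames to render.
#' @param drift optional n_frames x 2 drift matrix (nm), applied to all
#'   objects.
#' @param noise logical; add Poisson noise (default TRUE).
#' @param seed optional integer seed for the noise.
#' @return 3D array `[row, col, frame]` of photon counts. Coordinates:
#'   x right (columns), y down (rows), origin at the image corner, 0-based
#'   frames in the input.
#' @export
render_movie <- function(trajectories, spec, n_frames, drift = NULL,
                         noise = TRUE, seed = NULL) {
  stopifnot(inherits(spec, "movie_spec"))
  if (!is.null(seed)) set.seed(seed)
  px <- spec$pixel_size
  n <- spec$field_size
  side <- n * px
  stack <- array(spec$background, dim = c(n, n, n_frames))
  edges <- (0:n) * px
  add_spot <- function(frame_mat, x, y, photons) {
    # photon mass integrated per pixel: columns are x, rows are y
    cx <- diff(stats::pnorm(edges, x, spec$psf_sigma))
    cy <- diff(stats::pnorm(edges, y, spec$psf_sigma))
    frame_mat + photons * (cy %o% cx)
  }
  dropped <- 0L
  for (f in seq_len(n_frames)) {
    dx <- if (is.null(drift)) 0 else drift[f, 1]
    dy <- if (is.null(drift)) 0 else drift[f, 2]
    fr <- stack[, , f]
    rows <- trajectories$frame == (f - 1L)
    if (any(rows)) {
      xs <- trajectories$x_nm[rows] + dx
      ys <- trajectories$y_nm[rows] + dy
      for (k in seq_along(xs)) {
        if (xs[k] < 0 || xs[k] > side || ys[k] < 0 || ys[k] > side) {
          dropped <- dropped + 1L
          next
        }
        fr <- add_spot(fr, xs[k], ys[k], spec$emitter_photons)
      }
    }
    for (b in seq_len(nrow(spec$bead_positions))) {
      fr <- add_spot(fr, spec$bead_positions[b, 1] + dx,
                     spec$bead_positions[b, 2] + dy, spec$bead_photons)
    }
    stack[, , f] <- fr
  }
  if (dropped > 0)
    warning(dropped, " emitter-frame(s) fell outside the field and were omitted")
  if (noise) {
    stack[] <- stats::rpois(length(stack), stack)
  }
  stack
}

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' Counts are clipped to 65535 and stored as 16-bit unsigned grey values.
#'
#' @param stack 3D array `[row, col, frame]` of counts.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- stack[, , f]
    m[m > 65535] <- 65535
    m[m < 0] <- 0
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack()] back into counts
#'
#' @param path TIFF file path.
#' @return 3D array `[row, col, frame]` of counts.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) out[, , f] <- round(pages[[f]] * 65535)
  out
}
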