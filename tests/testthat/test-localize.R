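# rendering + localization round trips; pixel size 66 nm throughout

test_that("spot detection finds isolated maxima and nothing in blank frames", {
  spec <- movie_spec(field_size = 32)
  blank <- matrix(50, 32, 32)
  expect_equal(nrow(detect_spots(blank, 60)), 0)

  tr <- data.frame(molecule_id = 1, frame = 0, x_nm = 1000, y_nm = 800)
  spec1 <- movie_spec(field_size = 32, bead_positions = matrix(numeric(0), 0, 2))
  img <- render_movie(tr, spec1, 1, noise = FALSE)[, , 1]
  cand <- detect_spots(img, 60)
  expect_equal(nrow(cand), 1)
  # within 1 pixel of the truth (row = y, col = x)
  expect_lt(abs((cand$col - 0.5) * 66 - 1000), 66)
  expect_lt(abs((cand$row - 0.5) * 66 - 800), 66)

  tr2 <- data.frame(molecule_id = 1:2, frame = 0,
                    x_nm = c(500, 500 + 10 * 66), y_nm = 800)
  img2 <- render_movie(tr2, spec1, 1, noise = FALSE)[, , 1]
  expect_equal(nrow(detect_spots(img2, 60)), 2)
})

test_that("noiseless Gaussian fit recovers the center to < 0.01 pixel", {
  spec <- movie_spec(field_size = 32, bead_positions = matrix(numeric(0), 0, 2))
  truth <- c(x = 1017.3, y = 803.9)
  tr <- data.frame(molecule_id = 1, frame = 0, x_nm = truth["x"],
                   y_nm = truth["y"])
  img <- render_movie(tr, spec, 1, noise = FALSE)[, , 1]
  cand <- detect_spots(img, 60)
  fit <- fit_spot(img, c(cand$row[1], cand$col[1]), window = 4)
  expect_true(fit$ok)
  expect_lt(abs(fit$x - truth["x"]), 0.01 * 66)
  expect_lt(abs(fit$y - truth["y"]), 0.01 * 66)
  expect_error(fit_spot(img, c(2, 2), window = 4), "outside the image")
})

test_that("photon-limited localization precision matches the instrument scale", {
  # the default photon budget is calibrated so single-frame precision is
  # about 1.5 nm per coordinate
  spec <- movie_spec(field_size = 24, bead_positions = matrix(numeric(0), 0, 2))
  truth <- c(760, 790)
  tr <- data.frame(molecule_id = 1, frame = 0, x_nm = truth[1], y_nm = truth[2])
  set.seed(21)
  xs <- numeric(100); ys <- numeric(100)
  for (i in 1:100) {
    img <- render_movie(tr, spec, 1, noise = TRUE)[, , 1]
    s <- localize_stack(img[, , drop = FALSE] |>
                          array(dim = c(24, 24, 1)), window = 4)
    j <- which.min((s$x_nm - truth[1])^2 + (s$y_nm - truth[2])^2)
    xs[i] <- s$x_nm[j]; ys[i] <- s$y_nm[j]
  }
  expect_gt(sd(xs), 0.9); expect_lt(sd(xs), 2.2)
  expect_gt(sd(ys), 0.9); expect_lt(sd(ys), 2.2)
})

test_that("stage-step experiment: plateau means reproduce programmed steps", {
  # immobilized emitter, stage stepped +33 nm in x every 10 frames
  spec <- movie_spec(field_size = 24, bead_positions = matrix(numeric(0), 0, 2))
  steps <- rep(c(0, 33, 66), each = 10)
  tr <- data.frame(molecule_id = 1, frame = 0:29, x_nm = 700 + steps,
                   y_nm = 700)
  set.seed(22)
  stack <- render_movie(tr, spec, 30, noise = TRUE)
  spots <- localize_stack(stack, window = 4)
  expect_equal(nrow(spots), 30)
  plateau <- tapply(spots$x_nm, rep(1:3, each = 10), mean)
  d1 <- plateau[2] - plateau[1]; d2 <- plateau[3] - plateau[2]
  se <- 1.5 / sqrt(10) * sqrt(2)   # difference of two 10-frame means
  expect_lt(abs(d1 - 33), 3 * se)
  expect_lt(abs(d2 - 33), 3 * se)
})

test_that("greedy linking builds continuous tracks and bridges single gaps", {
  sp <- function(frame, x, y) data.frame(frame = frame, x_nm = x, y_nm = y,
                                         sigma_nm = 130, amplitude = 100,
                                         offset = 0, rss = 0)
  # one molecule, 10 frames
  a <- sp(0:9, 100 + 3 * (0:9), 200)
  la <- link_spots(a, max_step = 50, n_frames = 10)
  expect_equal(length(unique(la$track_id)), 1)
  # two well-separated molecules: two tracks, no identity switches
  b <- rbind(sp(0:9, 100 + 3 * (0:9), 200), sp(0:9, 1500, 1400 - 3 * (0:9)))
  lb <- link_spots(b, max_step = 50, n_frames = 10)
  expect_equal(length(unique(lb$track_id)), 2)
  expect_equal(length(unique(lb$track_id[lb$y_nm == 200])), 1)
  # one frame missing with max_gap = 1: still one track
  cc <- sp(c(0:4, 6:9), 100, 200)
  lc <- link_spots(cc, max_step = 50, max_gap = 1, n_frames = 10)
  expect_equal(length(unique(lc$track_id)), 1)
})

test_that("drift correction cancels shared drift exactly for noiseless fiducials", {
  n <- 40
  drift <- cbind(cumsum(runif(n, -2, 2)), cumsum(runif(n, -2, 2)))
  drift <- sweep(drift, 2, drift[1, ])   # reference frame 0
  mk <- function(id, x, y, frames = 0:(n - 1)) {
    data.frame(frame = frames, x_nm = x + drift[frames + 1, 1],
               y_nm = y + drift[frames + 1, 2], track_id = id)
  }
  set.seed(23)
  fid <- rbind(mk(1, 100, 100), mk(2, 2000, 150), mk(3, 150, 2000))
  mol <- mk(10, 800, 900)
  out <- correct_drift(mol, fid, n_frames = n)
  expect_equal(out$tracks$x_nm, rep(800, n), tolerance = 1e-12)
  expect_equal(out$tracks$y_nm, rep(900, n), tolerance = 1e-12)
  # zero drift: identity
  mol0 <- data.frame(frame = 0:(n - 1), x_nm = 800, y_nm = 900, track_id = 10)
  fid0 <- data.frame(frame = 0:(n - 1), x_nm = 100, y_nm = 100, track_id = 1)
  out0 <- correct_drift(mol0, fid0, n_frames = n)
  expect_identical(out0$tracks$x_nm, mol0$x_nm)
  # fiducial gaps are interpolated
  fidg <- fid[!(fid$track_id == 1 & fid$frame %in% 17:19), ]
  outg <- correct_drift(mol, fidg, n_frames = n)
  expect_lt(max(abs(outg$tracks$x_nm - 800)), 2.5)
  expect_error(correct_drift(mol, fid[0, ], n_frames = n), "fiducial")
})

test_that("averaging noisy fiducials suppresses residual drift", {
  n <- 60
  set.seed(24)
  drift <- cbind(cumsum(rep(0.8, n)), cumsum(rep(-0.5, n)))
  fid <- do.call(rbind, lapply(1:3, function(id) {
    data.frame(frame = 0:(n - 1),
               x_nm = 100 * id + drift[, 1] + rnorm(n, 0, 1.5),
               y_nm = 120 * id + drift[, 2] + rnorm(n, 0, 1.5),
               track_id = id)
  }))
  mol <- data.frame(frame = 0:(n - 1), x_nm = 800 + drift[, 1],
                    y_nm = 900 + drift[, 2], track_id = 10)
  out <- correct_drift(mol, fid, n_frames = n)
  resid <- sqrt((out$tracks$x_nm - 800)^2 + (out$tracks$y_nm - 900)^2)
  # residual per-frame drift ~ sqrt(2) * localization_sd / sqrt(3) beads
  expect_lt(sqrt(mean(resid^2)), 2.5 * 1.5 * sqrt(2) / sqrt(3))
})

test_that("render-localize round trip recovers ground-truth positions", {
  # two static molecules + corner beads, shared drift, photon noise
  spec <- movie_spec(field_size = 40)
  n <- 30
  drift <- cbind(cumsum(rep(1.1, n)), cumsum(rep(-0.7, n)))
  # placed well away from the corner fiducials so no fit window overlaps
  # a bead's Gaussian shoulder
  truth <- rbind(c(900, 1300), c(1800, 1500))
  tr <- do.call(rbind, lapply(1:2, function(i)
    data.frame(molecule_id = i, frame = 2:(n - 3), x_nm = truth[i, 1],
               y_nm = truth[i, 2])))
  set.seed(25)
  stack <- render_movie(tr, spec, n, drift = drift, seed = 26)
  tmp <- tempfile(fileext = ".tif")
  write_stack(stack, tmp)
  back <- read_stack(tmp)
  expect_equal(dim(back), c(40, 40, n))
  expect_lt(max(abs(back - pmin(stack, 65535))), 1)

  spots <- localize_stack(back, window = 4)
  linked <- link_spots(spots, max_step = 100, n_frames = n)
  fid <- linked[linked$is_fiducial, ]
  mol <- linked[!linked$is_fiducial, ]
  expect_equal(length(unique(fid$track_id)), 3)
  expect_equal(length(unique(mol$track_id)), 2)
  cd <- correct_drift(mol, fid, n_frames = n)
  # drift at the molecules' first frame (frame 2) is the reference offset:
  # corrected tracks sit at truth + drift[frame0]; compare per-track RMS
  # about the truth after removing the frame-0 fiducial reference
  for (i in 1:2) {
    ti <- cd$tracks[abs(cd$tracks$x_nm - truth[i, 1]) < 100, ]
    err <- sqrt((ti$x_nm - mean(ti$x_nm))^2 + (ti$y_nm - mean(ti$y_nm))^2)
    expect_lt(sqrt(mean(err^2)), 3)
    expect_lt(abs(mean(ti$x_nm) - truth[i, 1]), 5)
    expect_lt(abs(mean(ti$y_nm) - truth[i, 2]), 5)
  }
  unlink(tmp)
})
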