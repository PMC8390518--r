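test_that("boxcar smoothing is exact on constants, ramps, and lone outliers", {
  expect_equal(boxcar(rep(7, 20), 5), rep(7, 20))
  # linear ramp unchanged away from the edges
  r <- boxcar(1:30, 5)
  expect_equal(r[3:28], 3:28)
  # +delta outlier attenuated to delta/5 at its own frame
  v <- rep(0, 21); v[11] <- 10
  s <- boxcar(v, 5)
  expect_equal(s[11], 10 / 5)
  expect_error(boxcar(1:10, 4), "odd")
  expect_error(boxcar(numeric(0), 5), "empty")
})

test_that("a single-frame offset is a jump; sub-threshold steps are not", {
  p <- segmentation_params()
  # static track with one 48.6 nm relocation (the study's mean jump size)
  tr <- make_piecewise_track(static1 = 40, move = 0, static2 = 0)
  tr2 <- make_piecewise_track(static1 = 40, move = 0, static2 = 0)
  tr2$x_nm <- tr2$x_nm + 48.6
  tr2$frame <- tr2$frame + 40L; tr2$t_s <- tr2$t_s + 40
  track <- rbind(tr, tr2)
  jd <- detect_jumps(track, p)
  expect_equal(nrow(jd$jumps), 1)
  expect_equal(jd$jumps$distance_nm, 48.6, tolerance = 1e-6)
  expect_length(jd$blocks, 2)
  seg <- segment_trajectory(track, p)
  expect_equal(seg$molecule_class, "static_only")
  expect_equal(nrow(seg$segments), 2)
  expect_equal(nrow(seg$jumps), 1)

  # 9 nm in one frame: below threshold, no jump
  tr9 <- track; tr9$x_nm <- c(rep(100, 40), rep(109, 40))
  expect_equal(nrow(detect_jumps(tr9, p)$jumps), 0)
})

test_that("jump detection: >=95% recall at >=15 nm, none invented on static tracks", {
  # noiseless static-only molecules with frequent jumps, so every detected
  # event must be a genuine ground-truth relocation
  cfg <- paper_config(n_molecules = 400, rng_seed = 31, k_processive = 0,
                      p_land_static = 1, jump_rate = 0.004,
                      localization_sd = 0)
  sim <- simulate_experiment(cfg)
  p <- segmentation_params()
  n_gt15 <- 0; n_found15 <- 0; n_fp <- 0
  for (g in sim$ground_truth) {
    tr <- sim$trajectories[sim$trajectories$molecule_id == g$molecule_id, ]
    if (nrow(tr) < 3) next
    jd <- detect_jumps(tr, p)
    t_obs <- range(tr$t_s)
    gtj <- g$jumps[g$jumps$time_s > t_obs[1] + 1 &
                   g$jumps$time_s < t_obs[2] - 1, ]
    for (k in seq_len(nrow(gtj))) {
      if (gtj$distance_nm[k] < 15) next
      n_gt15 <- n_gt15 + 1
      hit <- nrow(jd$jumps) > 0 &&
        any(gtj$time_s[k] > jd$jumps$frame_start - 1 &
            gtj$time_s[k] <= jd$jumps$frame_end + 1)
      n_found15 <- n_found15 + hit
    }
    if (nrow(jd$jumps)) for (k in seq_len(nrow(jd$jumps))) {
      matched <- nrow(g$jumps) > 0 &&
        any(g$jumps$time_s > jd$jumps$frame_start[k] - 1.5 &
            g$jumps$time_s <= jd$jumps$frame_end[k] + 1.5)
      n_fp <- n_fp + !matched
    }
  }
  expect_gt(n_gt15, 50)
  expect_gte(n_found15 / n_gt15, 0.95)
  expect_equal(n_fp, 0)
})

test_that("piecewise tracks segment into static/processive/static", {
  p <- segmentation_params()
  # noiseless 100 s stationary track: one static segment ending in unbind
  tr0 <- make_piecewise_track(static1 = 100, move = 0, static2 = 0)
  s0 <- segment_trajectory(tr0, p, movie_end_frame = 999)
  expect_equal(nrow(s0$segments), 1)
  expect_equal(s0$segments$kind, "static")
  expect_equal(s0$segments$terminal_fate, "unbind")

  # 60 s static / 20 s at 3.24 nm/s / 80 s static
  tr <- make_piecewise_track(static1 = 60, move = 20, static2 = 80)
  s <- segment_trajectory(tr, p, movie_end_frame = 999)
  expect_equal(s$segments$kind, c("static", "processive", "static"))
  expect_equal(s$molecule_class, "processive")
  pseg <- s$segments[s$segments$kind == "processive", ]
  expect_lt(abs(pseg$t_start - 60), 2.5)
  expect_lt(abs(pseg$t_end - 80), 2.5)
  expect_equal(pseg$net_displacement, 64.8, tolerance = 0.05)
  expect_equal(pseg$velocity, 3.24, tolerance = 0.15)
  expect_equal(s$segments$terminal_fate, c("switch", "switch", "unbind"))

  # 8 nm total excursion over 300 s: below the 10 nm radius, stays static
  slow <- make_piecewise_track(static1 = 10, move = 280, static2 = 10,
                               speed = 8 / 280)
  sl <- segment_trajectory(slow, p)
  expect_equal(unique(sl$segments$kind), "static")
})

test_that("inclusion filters drop short, long and late tracks", {
  p <- segmentation_params()
  mk <- function(dur, id, start = 0) {
    n <- dur   # 1 fps: duration = n frames * 1 s (t_last - t_first + dt)
    data.frame(molecule_id = id, frame = start + 0:(n - 1),
               t_s = start + 0:(n - 1), x_nm = 50, y_nm = 60,
               intensity = 1000)
  }
  durs <- c(5, 9, 10, 200, 509, 511)
  segd <- lapply(seq_along(durs), function(i)
    segment_trajectory(mk(durs[i], i), p))
  out <- apply_filters(segd, p)
  expect_equal(out$report$n_retained, 3)
  expect_equal(out$report$n_short, 2)
  expect_equal(out$report$n_long, 1)
  expect_equal(out$report$n_late, 0)
  kept <- vapply(out$retained, function(s) s$molecule_id, numeric(1))
  expect_equal(kept, c(3, 4, 5))

  # a track landing after the 500 s cutoff is dropped
  late <- segment_trajectory(mk(50, 9, start = 501), p)
  out2 <- apply_filters(c(segd[3], list(late)), p)
  expect_equal(out2$report$n_late, 1)
  expect_equal(out2$report$n_retained, 1)
})

test_that("segment statistics are simple ratios with guarded degenerate input", {
  seg <- data.frame(kind = "processive", duration = 20,
                    net_displacement = 64.8, velocity = 3.24)
  st <- segment_stats(seg)
  expect_equal(st$velocity, 3.24)
  expect_equal(st$run_length, 64.8)
  seg0 <- data.frame(kind = "static", duration = 30, net_displacement = 0,
                     velocity = NA)
  expect_equal(segment_stats(seg0)$run_length, 0)
  segbad <- data.frame(kind = "processive", duration = 0,
                       net_displacement = 5, velocity = NA)
  expect_error(segment_stats(segbad), "zero duration")
})

test_that("molecule classification matches detectable ground truth", {
  p <- segmentation_params()
  # noiseless: >=99% correct class and segment counts
  cfg0 <- paper_config(n_molecules = 700, rng_seed = 33, localization_sd = 0,
                       jump_rate = 0)
  sim0 <- simulate_experiment(cfg0)
  seg0 <- segment_cohort(sim0$trajectories, p, movie_end_frame = 999)
  fl0 <- apply_filters(seg0, p)
  ids0 <- vapply(fl0$retained, function(s) s$molecule_id, numeric(1))
  gt_cls <- vapply(sim0$ground_truth[ids0], gt_detectable_class, character(1))
  cls <- vapply(fl0$retained, function(s) s$molecule_class, character(1))
  expect_gte(mean(gt_cls == cls), 0.99)
  gt_n <- vapply(sim0$ground_truth[ids0], gt_detectable_count, numeric(1))
  n_det <- vapply(fl0$retained, function(s)
    sum(s$segments$kind == "processive"), numeric(1))
  expect_gte(mean(gt_n == n_det), 0.99)

  # with 1.5 nm localization noise: >=97%
  cfg1 <- paper_config(n_molecules = 700, rng_seed = 34)
  sim1 <- simulate_experiment(cfg1)
  seg1 <- segment_cohort(sim1$trajectories, p, movie_end_frame = 999)
  fl1 <- apply_filters(seg1, p)
  ids1 <- vapply(fl1$retained, function(s) s$molecule_id, numeric(1))
  gt_cls1 <- vapply(sim1$ground_truth[ids1], gt_detectable_class, character(1))
  cls1 <- vapply(fl1$retained, function(s) s$molecule_class, character(1))
  expect_gte(mean(gt_cls1 == cls1), 0.97)
})

test_that("raising the static radius never increases processive molecules", {
  cfg <- paper_config(n_molecules = 250, rng_seed = 35)
  sim <- simulate_experiment(cfg)
  n_proc <- vapply(c(10, 15, 20, 30), function(r) {
    p <- segmentation_params(static_radius = r)
    seg <- segment_cohort(sim$trajectories, p, movie_end_frame = 999)
    sum(vapply(seg, function(s) s$molecule_class, character(1)) ==
          "processive")
  }, numeric(1))
  expect_true(all(diff(n_proc) <= 0))
})

test_that("an inserted jump does not change total run length", {
  p <- segmentation_params()
  base <- make_piecewise_track(static1 = 40, move = 25, static2 = 60,
                               noise_sd = 0)
  s_base <- segment_trajectory(base, p)
  rl_base <- sum(s_base$segments$net_displacement[
    s_base$segments$kind == "processive"])
  # inject a 50 nm relocation in the middle of the trailing static phase
  jumped <- base
  shift <- jumped$frame >= 95
  jumped$y_nm[shift] <- jumped$y_nm[shift] + 50
  s_j <- segment_trajectory(jumped, p)
  expect_equal(nrow(s_j$jumps), 1)
  rl_j <- sum(s_j$segments$net_displacement[
    s_j$segments$kind == "processive"])
  expect_equal(rl_j, rl_base, tolerance = 1e-6)
})

test_that("segments and jumps tile the bound interval without gaps", {
  cfg <- paper_config(n_molecules = 120, rng_seed = 36, jump_rate = 0.003)
  sim <- simulate_experiment(cfg)
  p <- segmentation_params()
  seg <- segment_cohort(sim$trajectories, p, movie_end_frame = 999)
  for (s in seg) {
    segs <- s$segments[order(s$segments$t_start), ]
    bounds <- sort(c(segs$t_start, segs$t_end))
    covered <- sum(segs$t_end - segs$t_start) +
      (if (nrow(s$jumps)) sum(s$jumps$frame_end - s$jumps$frame_start)
       else 0)
    span <- max(segs$t_end) - min(segs$t_start)
    expect_equal(covered, span, tolerance = 1e-9)
    if (nrow(segs) > 1) {
      internal_ok <- all(diff(segs$t_start) > 0)
      expect_true(internal_ok)
    }
  }
})
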