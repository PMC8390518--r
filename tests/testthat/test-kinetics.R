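test_that("truncated-exponential MLE closed forms and windowing", {
  f <- fit_exponential_mle(c(10, 20, 30), t_min = 0, boot_iterations = 50,
                           seed = 1)
  expect_equal(f$tau, 20)
  expect_equal(f$n, 3)
  expect_true(f$ci95[1] <= f$tau && f$tau <= f$ci95[2])
  expect_error(fit_exponential_mle(c(1, 2), t_min = 5, label = "x"),
               "fewer than 2")

  # left-truncated recovery: draws above 10 s shifted back
  set.seed(41)
  d <- rexp(1e4, 1 / 89)
  f2 <- fit_exponential_mle(d[d >= 10], t_min = 10, boot_iterations = 100,
                            seed = 2)
  expect_equal(f2$tau, 89, tolerance = 3 * (89 / sqrt(f2$n)) / 89)

  # doubly-windowed MLE stays unbiased where the naive shift is ~10% low
  set.seed(42)
  d3 <- rexp(4e4, 1 / 89)
  f3 <- fit_exponential_mle(d3, t_min = 5, t_max = 310,
                            boot_iterations = 100, seed = 3)
  naive <- mean(d3[d3 >= 5 & d3 <= 310]) - 5
  expect_lt(naive, 82)                      # the shift estimator is biased
  expect_equal(f3$tau, 89, tolerance = 0.02)
})

test_that("bootstrap CI half-width matches the asymptotic standard error", {
  set.seed(43)
  d <- rexp(4136, 1 / 89)
  f <- fit_exponential_mle(d, t_min = 0, boot_iterations = 1000, seed = 4)
  half <- diff(f$ci95) / 2
  # 1.96 * 89 / sqrt(4136) = 2.71 s
  expect_gt(half, 2.1)
  expect_lt(half, 3.4)
})

test_that("windowed MLE bias stays below 2% across the study's time constants", {
  taus <- c(20.3, 65.9, 84.1, 89.0)
  set.seed(44)
  for (tau in taus) {
    est <- replicate(200, {
      d <- rexp(1000, 1 / tau)
      fit_exponential_mle(d, t_min = 5, t_max = 310, boot_iterations = 2,
                          seed = sample.int(1e6, 1))$tau
    })
    expect_lt(abs(mean(est) - tau) / tau, 0.02)
  }
})

test_that("bootstrap 95% CIs cover the true tau at nominal rate", {
  set.seed(45)
  cover <- replicate(500, {
    d <- rexp(500, 1 / 89)
    d <- d[d >= 10]
    f <- fit_exponential_mle(d, t_min = 10, boot_iterations = 1000,
                             seed = sample.int(1e6, 1))
    f$ci95[1] <= 89 && 89 <= f$ci95[2]
  })
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("rate decomposition identities hold to machine precision", {
  fits <- list(
    processive = structure(list(tau = 20.3, n = 1058), class = "exp_fit"),
    static_molecule = structure(list(tau = 89.0, n = 4136),
                                class = "exp_fit"),
    static_all = structure(list(tau = 85.9, n = 1820), class = "exp_fit"))
  cnt <- branching_counts(0.23, 0.63, frac_static_only = 0.899,
                          frac_processive_start_static = 0.44)
  for (pool in c("weighted", "molecules_only", "segments_only")) {
    r <- derive_rates(fits, cnt, static_pooling = pool)
    expect_equal(r$k_off_processive + r$k_static, r$k_exit_processive,
                 tolerance = 1e-12)
    expect_equal(r$k_off_static + r$k_processive, r$k_exit_static,
                 tolerance = 1e-12)
    expect_equal(r$p_land_static + r$p_land_processive, 1,
                 tolerance = 1e-12)
  }
  expect_error(derive_rates(fits["processive"], cnt), "static_molecule")
})

test_that("count-weighted static pooling reproduces the combined exit rate", {
  fits <- list(
    processive = structure(list(tau = 20.3, n = 1058), class = "exp_fit"),
    static_molecule = structure(list(tau = 89.0, n = 4136),
                                class = "exp_fit"),
    static_all = structure(list(tau = 85.9, n = 1820), class = "exp_fit"))
  cnt <- branching_counts(0.23, 0.63)
  r <- derive_rates(fits, cnt)
  expect_equal(r$tau_static_pooled,
               (4136 * 89.0 + 1820 * 85.9) / (4136 + 1820),
               tolerance = 1e-12)             # 88.05 s
  expect_equal(r$k_exit_static, 0.01136, tolerance = 0.001)
})

test_that("chain observables: closed forms against Monte-Carlo paths", {
  rates <- list(k_exit_static = 0.0106 + 0.00064,
                k_exit_processive = 0.0113 + 0.0379,
                k_off_static = 0.0106, k_processive = 0.00064,
                k_off_processive = 0.0113, k_static = 0.0379,
                p_land_static = 0.944, p_land_processive = 0.056)
  po <- predict_observables(rates)
  expect_equal(po$p_enter_processive, 0.110, tolerance = 0.01)

  # absorbing static chain never enters the processive state
  r0 <- within(rates, {k_processive <- 0; p_land_static <- 1
                       p_land_processive <- 0
                       k_exit_static <- k_off_static})
  expect_equal(predict_observables(r0)$p_enter_processive, 0)
  expect_error(predict_observables(within(rates, k_exit_static <- 0)),
               "positive")

  cfg <- paper_config(n_frames = 1)
  sp <- tnorm_params(cfg$speed_mean, cfg$speed_sd, cfg$speed_min)
  set.seed(46)
  n <- 3e4
  nproc <- numeric(n); nstat <- numeric(n); bt <- numeric(n)
  for (i in seq_len(n)) {
    s <- sample_state_path(cfg, sp)$states
    nproc[i] <- sum(s$state == "processive")
    nstat[i] <- sum(s$state == "static")
    bt[i] <- sum(s$dwell)
  }
  expect_lt(abs(mean(nproc > 0) - po$p_enter_processive),
            3 * sd(nproc > 0) / sqrt(n))
  expect_lt(abs(mean(nproc) - po$expected_processive_visits),
            3 * sd(nproc) / sqrt(n))
  expect_lt(abs(mean(nstat) - po$expected_static_visits),
            3 * sd(nstat) / sqrt(n))
  expect_lt(abs(mean(bt) - po$expected_bound_time), 3 * sd(bt) / sqrt(n))
})

test_that("landing arithmetic composes molecule-class fractions", {
  expect_equal(p_land_static_overall(1, 0, 0), 1)
  expect_equal(p_land_static_overall(0.899, 0.101, 0.44), 0.9434,
               tolerance = 1e-4)
})

test_that("full cohort pipeline recovers the generator's rate constants", {
  # cohort size chosen for estimation power: route fractions carry binomial
  # noise of several percent per hundred events, so resolving all four
  # rates to 15% needs on the order of 800 detected processive segments
  p <- segmentation_params()
  cfg <- paper_config(n_molecules = 10000, rng_seed = 1)
  sim <- simulate_experiment(cfg)
  seg <- segment_cohort(sim$trajectories, p,
                        movie_end_frame = cfg$n_frames - 1)
  fl <- apply_filters(seg, p)
  smp <- dwell_samples(fl$retained)
  cnt <- branching_fractions(fl$retained, p)
  fits <- fit_all_dwells(smp, p, boot_iterations = 200,
                         seed = derive_seed(1, "bootstrap"))
  rts <- derive_rates(fits, cnt)
  expect_equal(rts$k_off_static, 0.0106, tolerance = 0.15)
  expect_equal(rts$k_processive, 0.00064, tolerance = 0.15)
  expect_equal(rts$k_off_processive, 0.0113, tolerance = 0.15)
  expect_equal(rts$k_static, 0.0379, tolerance = 0.15)
  # landing split recovered alongside
  expect_equal(rts$p_land_static, 0.944, tolerance = 0.02)
})

test_that("the report table carries every measured-parameter row", {
  p <- segmentation_params()
  cfg <- paper_config(n_molecules = 400, rng_seed = 48)
  sim <- simulate_experiment(cfg)
  seg <- segment_cohort(sim$trajectories, p,
                        movie_end_frame = cfg$n_frames - 1)
  fl <- apply_filters(seg, p)
  smp <- dwell_samples(fl$retained)
  cnt <- branching_fractions(fl$retained, p)
  fits <- fit_all_dwells(smp, p, boot_iterations = 100, seed = 5)
  rts <- derive_rates(fits, cnt)
  rep <- build_report(fl$retained, fits, cnt, rts)
  need <- c("total_molecules", "percent_entirely_static",
            "percent_with_processive_segments",
            "binding_duration_static_molecules", "velocity_mean",
            "velocity_sd", "run_length_mean", "run_length_sd",
            "duration_processive_segments",
            "percent_processive_end_unbinding",
            "percent_static_segments_end_unbinding",
            "percent_molecules_with_jumps", "jump_distance_mean",
            "percent_landing_static", "k_off_processive", "k_static",
            "k_off_static", "k_processive")
  expect_true(all(need %in% rep$parameter))
  g <- function(x) rep$value[rep$parameter == x]
  expect_equal(g("percent_entirely_static") +
                 g("percent_with_processive_segments"), 100)
  expect_equal(g("percent_processive_end_unbinding") +
                 g("percent_processive_end_static"), 100)
  # velocity row is the mean of per-segment velocities
  st <- segment_table(fl$retained)
  expect_equal(g("velocity_mean"),
               mean(st$velocity[st$kind == "processive"]))
  tsv <- tempfile(fileext = ".tsv"); md <- tempfile(fileext = ".md")
  write_report(rep, tsv, md)
  expect_true(file.exists(tsv) && file.exists(md))
  expect_gt(length(readLines(md)), 20)
  unlink(c(tsv, md))
})
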