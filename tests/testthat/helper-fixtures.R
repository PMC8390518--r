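# shared fixture builders; everything is generated in code at test time

# scratch space for cohorts reused across test blocks in one file
shared <- new.env(parent = emptyenv())

# three-state rates as used throughout the study conditions
paper_rates <- list(k_off_static = 0.0106, k_processive = 0.00064,
                    k_off_processive = 0.0113, k_static = 0.0379,
                    p_land_static = 0.944)

paper_config <- function(n_molecules = 500, rng_seed = 1L, ...) {
  args <- list(...)
  base <- c(paper_rates, list(n_molecules = n_molecules,
                              rng_seed = rng_seed))
  base <- base[!(names(base) %in% names(args))]
  do.call(sim_config, c(base, args))
}

# a hand-built noiseless trajectory: static at (x0, y0), then motion at
# `speed` nm/s along +x, then static again; durations in seconds at 1 fps
make_piecewise_track <- function(static1 = 60, move = 20, static2 = 80,
                                 speed = 3.24, x0 = 100, y0 = 100,
                                 noise_sd = 0, id = 1L, seed = 1L) {
  set.seed(seed)
  n1 <- static1; n2 <- move; n3 <- static2
  x <- c(rep(x0, n1), x0 + speed * seq_len(n2), rep(x0 + speed * n2, n3))
  y <- rep(y0, n1 + n2 + n3)
  n <- length(x)
  data.frame(molecule_id = id, frame = 0:(n - 1), t_s = 0:(n - 1),
             x_nm = x + rnorm(n, 0, noise_sd),
             y_nm = y + rnorm(n, 0, noise_sd),
             intensity = 1000)
}

# ground-truth molecule class under the operational detection limits:
# a processive visit counts only if it lasts >= min_dur and covers >= radius
gt_detectable_class <- function(gt, min_dur = 5, radius = 10) {
  s <- gt$states
  det <- s$state == "processive" & s$dwell >= min_dur &
    s$dwell * s$speed >= radius
  if (any(det)) "processive" else "static_only"
}

gt_detectable_count <- function(gt, min_dur = 5, radius = 10) {
  s <- gt$states
  sum(s$state == "processive" & s$dwell >= min_dur &
        s$dwell * s$speed >= radius)
}
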