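#' Truncated-exponential dwell-time MLE with bootstrap CI
#'
#' Observations outside `(t_min, t_max)` are windowed out (values below
#' `t_min` reflect the detection limit; values above `t_max` are excluded as
#' outliers, mirroring the study's fitting window). The fit maximizes the
#' exponential likelihood conditioned on the observation window. With no
#' upper window (`t_max = Inf`) this reduces to the memoryless-shift closed
#' form `tau = mean(durations) - t_min`; with a finite window the MLE
#' solves `mean(d - t_min) = tau - W * exp(-W/tau) / (1 - exp(-W/tau))`,
#' `W = t_max - t_min` (the naive shift would be biased low by about 10%
#' when the window is only a few time constants wide). The 95% CI is a
#' seeded percentile bootstrap over the windowed observations.
#'
#' When the detection limit differs per observation — processive segments
#' at speed v only become detectable once they have lasted
#' `max(t_min, R / v)`, the time needed to cover the detection radius R —
#' a vector of per-observation truncation times can be supplied via
#' `t_trunc`; the exact MLE is then `mean(durations - t_trunc)` and the
#' bootstrap resamples (duration, truncation) pairs.
#'
#' @param durations numeric vector of dwell times (s).
#' @param t_min left truncation (s).
#' @param t_max right window (s); values above are discarded.
#' @param boot_iterations bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param label optional sample label carried in the result.
#' @param t_trunc optional per-observation left-truncation times (same
#'   length as `durations`, each `>= t_min`); overrides the scalar shift.
#' @return object of class `exp_fit`: `tau`, `ci95` (lo, hi), `n`,
#'   `boot_iterations`, `t_min`, `t_max`, `label`.
#' @export
fit_exponential_mle <- function(durations, t_min = 0, t_max = Inf,
                                boot_iterations = 1000, seed = 1L,
                                label = NA_character_, t_trunc = NULL) {
  keep <- durations >= t_min & durations <= t_max
  d <- durations[keep]
  if (length(d) < 2)
    stop("fewer than 2 observations remain after windowing [", t_min, ", ",
         t_max, "] for sample '", label, "'", call. = FALSE)
  shift <- if (is.null(t_trunc)) rep(t_min, length(d))
           else pmax(t_min, t_trunc[keep])
  excess <- pmax(d - shift, 0)
  W <- t_max - shift
  # windowed-exponential MLE: E[excess] = tau - W e^{-W/tau}/(1 - e^{-W/tau})
  solve_tau <- function(m, W) {
    if (m <= 0) return(0)
    if (all(!is.finite(W))) return(m)
    g <- function(tau) {
      r <- W / tau
      corr <- ifelse(is.finite(W), W * exp(-r) / (1 - exp(-r)), 0)
      tau - mean(corr) - m
    }
    hi <- m * 2
    while (g(hi) < 0 && hi < m * 1e4) hi <- hi * 2
    if (g(hi) < 0) return(m)   # window too narrow to resolve tau
    stats::uniroot(g, c(m * 0.5, hi), tol = 1e-9)$root
  }
  tau <- solve_tau(mean(excess), W)
  set.seed(seed)
  n <- length(d)
  idx <- matrix(sample.int(n, n * boot_iterations, replace = TRUE),
                nrow = boot_iterations)
  Wconst <- length(unique(W)) == 1L
  taus <- if (Wconst) {
    m_b <- rowMeans(matrix(excess[idx], nrow = boot_iterations))
    vapply(m_b, solve_tau, numeric(1), W = W[1])
  } else {
    apply(idx, 1, function(ii) solve_tau(mean(excess[ii]), W[ii]))
  }
  ci <- unname(stats::quantile(taus, c(0.025, 0.975), type = 7))
  structure(list(tau = tau, ci95 = ci, n = n,
                 boot_iterations = boot_iterations, t_min = t_min,
                 t_max = t_max, label = label),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %s: tau = %.3g s (95%% CI %.3g-%.3g), n = %d\n",
              ifelse(is.na(x$label), "dwell sample", x$label),
              x$tau, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Extract the labelled dwell samples from a segmented cohort
#'
#' Produces the dwell samples used by the three-state fit, with the fates
#' determining the labels. Censored segments/molecules are excluded.
#'
#' @param segmented filtered list of `segmented_trajectory` objects.
#' @return named list of numeric vectors:
#'   `static_molecule` (total bound durations of static-only molecules),
#'   `processive_molecule` (total bound durations of processive molecules),
#'   `jump_molecule` (total bound durations of molecules with jumps),
#'   `processive` (processive segment durations, non-censored),
#'   `processive_velocity` (their velocities, for detection-aware
#'   truncation),
#'   `static_all` (static segment durations of processive molecules),
#'   `static_pre` (those ending in a switch to processive),
#'   `static_post` (those ending in unbinding).
#' @export
dwell_samples <- function(segmented) {
  cls <- vapply(segmented, function(s) s$molecule_class, character(1))
  dur <- vapply(segmented, function(s) s$total_bound_duration, numeric(1))
  cens <- vapply(segmented, function(s) isTRUE(s$censored), logical(1))
  has_jump <- vapply(segmented, function(s) nrow(s$jumps) > 0, logical(1))
  st <- segment_table(segmented)
  # count the static neighbours of each processive segment (position
  # smoothing smears each static-flanked boundary outward, which the
  # dwell fit compensates for via the truncation time)
  st$static_flanks <- 0L
  for (id in unique(st$molecule_id)) {
    ii <- which(st$molecule_id == id)
    ii <- ii[order(st$t_start[ii])]
    k <- st$kind[ii]
    fl <- integer(length(ii))
    if (length(ii) > 1) {
      fl <- (c("", head(k, -1)) == "static") +
            (c(k[-1], "") == "static")
    }
    st$static_flanks[ii] <- fl
  }
  proc_segs <- st[st$kind == "processive" & st$terminal_fate != "censored", ]
  stat_of_proc <- st[st$kind == "static" & st$molecule_class == "processive" &
                     st$terminal_fate != "censored", ]
  list(static_molecule = dur[cls == "static_only" & !cens],
       processive_molecule = dur[cls == "processive" & !cens],
       jump_molecule = dur[has_jump & !cens],
       processive = proc_segs$duration,
       processive_velocity = proc_segs$velocity,
       processive_net = proc_segs$net_displacement,
       processive_flanks = proc_segs$static_flanks,
       static_all = stat_of_proc$duration,
       static_pre = stat_of_proc$duration[stat_of_proc$terminal_fate == "switch"],
       static_post = stat_of_proc$duration[stat_of_proc$terminal_fate == "unbind"])
}

#' Fit all dwell samples of a cohort
#'
#' Applies [fit_exponential_mle()] to each labelled sample with the
#' appropriate window: molecule-level binding durations use the inclusion
#' window (`min_total_duration` to `max_total_duration`); segment-level
#' dwells use the `static_fit_min`-`static_fit_max` window.
#'
#' For processive segments the truncation time is per-observation:
#' `R / v`, the time the segment needed to become detectable (cover the
#' static radius R at its speed); the scalar window minimum still applies
#' through `t_min`.
#'
#' @param samples output of [dwell_samples()].
#' @param params a [segmentation_params()] supplying the windows.
#' @param boot_iterations bootstrap resamples per fit.
#' @param seed master seed; each label gets a derived seed.
#' @param frame_interval seconds per frame (reserved for time-unit
#'   conversions of frame-based thresholds).
#' @return named list of `exp_fit` objects (labels with fewer than two
#'   windowed observations are dropped).
#' @export
fit_all_dwells <- function(samples, params = segmentation_params(),
                           boot_iterations = 1000, seed = 1L,
                           frame_interval = 1) {
  windows <- list(
    static_molecule = c(params$min_total_duration, params$max_total_duration),
    processive_molecule = c(params$min_total_duration,
                            params$max_total_duration),
    jump_molecule = c(params$min_total_duration, params$max_total_duration),
    processive = c(params$static_fit_min, params$static_fit_max),
    static_all = c(params$static_fit_min, params$static_fit_max),
    static_pre = c(params$static_fit_min, params$static_fit_max),
    static_post = c(params$static_fit_min, params$static_fit_max))
  fits <- list()
  for (lab in names(windows)) {
    d <- samples[[lab]]
    w <- windows[[lab]]
    # processive segments at speed v are only detectable once they have
    # covered the static radius, so their truncation time is speed-dependent
    tt <- NULL
    if (lab == "processive" && !is.null(samples$processive_velocity))
      tt <- params$static_radius / samples$processive_velocity
    if (length(d[d >= w[1] & d <= w[2]]) >= 2)
      fits[[lab]] <- fit_exponential_mle(d, w[1], w[2], boot_iterations,
                                         seed = derive_seed(seed, lab),
                                         label = lab, t_trunc = tt)
  }
  fits
}

#' Overall static-landing probability from the observed fractions
#'
#' `P(land static) = f_static_only + f_processive * f_start_static`, where
#' `f_start_static` is the fraction of processive molecules whose first
#' segment is static.
#'
#' @param frac_static_only fraction of molecules that are entirely static.
#' @param frac_processive fraction with at least one processive segment.
#' @param frac_processive_start_static fraction of processive molecules
#'   starting with a static segment.
#' @return probability in `[0, 1]`.
#' @export
p_land_static_overall <- function(frac_static_only, frac_processive,
                                  frac_processive_start_static) {
  frac_static_only + frac_processive * frac_processive_start_static
}

#' Exit-route counts and branching fractions of a segmented cohort
#'
#' Counts how segments of each state terminate (unbinding vs switching),
#' treating each static-only molecule as one static segment ending in
#' unbinding, and derives the landing-state split from the first segment of
#' each molecule. Censored segments are excluded from route counts.
#'
#' @param segmented filtered list of `segmented_trajectory` objects.
#' @param params a [segmentation_params()]; used to record each detected
#'   processive segment's detection threshold (needed by the
#'   detection-probability correction in [derive_rates()]).
#' @return object of class `branching_counts`: the counts named in the
#'   fields plus `frac_processive_to_unbind`, `frac_static_to_unbind`,
#'   `frac_molecules_processive`, `frac_processive_start_static`,
#'   `p_land_static_obs`, `p_land_processive_obs`, and
#'   `detection_thresholds` (per detected processive segment,
#'   `max(min_processive_duration, static_radius / velocity)`).
#' @export
branching_fractions <- function(segmented, params = segmentation_params()) {
  st <- segment_table(segmented)
  cls <- vapply(segmented, function(s) s$molecule_class, character(1))
  n_static_only <- sum(cls == "static_only")
  n_proc_mol <- sum(cls == "processive")
  proc <- st[st$kind == "processive" & st$terminal_fate != "censored", ]
  stat_p <- st[st$kind == "static" & st$molecule_class == "processive" &
               st$terminal_fate != "censored", ]
  # static-only molecules: one static dwell ending in unbinding each
  static_only_unbind <-
    sum(cls == "static_only" &
        !vapply(segmented, function(s) isTRUE(s$censored), logical(1)))
  n_p2u <- sum(proc$terminal_fate == "unbind")
  n_p2s <- sum(proc$terminal_fate == "switch")
  n_s2u <- sum(stat_p$terminal_fate == "unbind") + static_only_unbind
  n_s2p <- sum(stat_p$terminal_fate == "switch")
  first_kind <- vapply(segmented, function(s) s$segments$kind[1], character(1))
  frac_proc_mol <- n_proc_mol / max(1, length(segmented))
  frac_start_static <- if (n_proc_mol > 0)
    sum(first_kind == "static" & cls == "processive") / n_proc_mol else 0
  p_ls <- p_land_static_overall(n_static_only / max(1, length(segmented)),
                                frac_proc_mol, frac_start_static)
  structure(list(
    n_processive_to_unbind = n_p2u, n_processive_to_static = n_p2s,
    n_static_to_unbind = n_s2u, n_static_to_processive = n_s2p,
    n_static_only_molecules = n_static_only,
    n_static_segments_of_processive = nrow(stat_p),
    frac_processive_to_unbind = n_p2u / max(1, n_p2u + n_p2s),
    frac_static_to_unbind = n_s2u / max(1, n_s2u + n_s2p),
    frac_molecules_processive = frac_proc_mol,
    frac_processive_start_static = frac_start_static,
    p_land_static_obs = p_ls,
    p_land_processive_obs = 1 - p_ls,
    detection_thresholds = pmax(params$min_processive_duration,
                                params$static_radius / proc$velocity),
    min_static_segment = params$min_static_segment),
    class = "branching_counts")
}

#' Construct branching counts from known fractions
#'
#' Builds a `branching_counts` object directly from route fractions and
#' landing fractions (e.g. published values), for use with
#' [derive_rates()] without a segmented cohort. Counts are filled in from
#' the fractions at the stated totals.
#'
#' @param frac_processive_to_unbind fraction of processive segments ending
#'   in unbinding.
#' @param frac_static_to_unbind fraction of static dwells ending in
#'   unbinding.
#' @param frac_static_only fraction of molecules that are entirely static.
#' @param frac_processive_start_static fraction of processive molecules
#'   whose first segment is static.
#' @param n_processive,n_static totals used to materialize the counts.
#' @return a `branching_counts` object (without detection thresholds, so
#'   [derive_rates()] applies no detection correction).
#' @export
branching_counts <- function(frac_processive_to_unbind,
                             frac_static_to_unbind,
                             frac_static_only = NA_real_,
                             frac_processive_start_static = NA_real_,
                             n_processive = 1000L, n_static = 1000L) {
  p_ls <- if (!is.na(frac_static_only) &&
              !is.na(frac_processive_start_static))
    p_land_static_overall(frac_static_only, 1 - frac_static_only,
                          frac_processive_start_static)
  else NA_real_
  structure(list(
    n_processive_to_unbind = round(frac_processive_to_unbind * n_processive),
    n_processive_to_static = round((1 - frac_processive_to_unbind) *
                                   n_processive),
    n_static_to_unbind = round(frac_static_to_unbind * n_static),
    n_static_to_processive = round((1 - frac_static_to_unbind) * n_static),
    n_static_only_molecules = NA_integer_,
    n_static_segments_of_processive = NA_integer_,
    frac_processive_to_unbind = frac_processive_to_unbind,
    frac_static_to_unbind = frac_static_to_unbind,
    frac_molecules_processive = 1 - frac_static_only,
    frac_processive_start_static = frac_processive_start_static,
    p_land_static_obs = p_ls,
    p_land_processive_obs = 1 - p_ls,
    detection_thresholds = numeric(0)), class = "branching_counts")
}

#' Derive the three-state rate constants from fits and branching
#'
#' The total exit rate of each bound state is the inverse of its fitted
#' dwell time constant; route rates are branching fraction times exit rate.
#' The static exit rate uses, by default, the count-weighted average of the
#' static-molecule and static-segment time constants (`"weighted"`); the
#' alternatives use one of the two alone.
#'
#' Processive visits shorter than the detection limit (below
#' `min_processive_duration`, or too slow to cover `static_radius` within
#' their dwell) are invisible to segmentation, so observed
#' static-to-processive switch counts and processive-landing fractions
#' undercount the true branching. With `detection_correction = TRUE`
#' (default) these are rescaled by the estimated mean detection probability
#' `P(dwell >= threshold) = exp(-threshold / tau_processive)`, averaged over
#' the speed distribution by inverse-probability weighting of the detected
#' segments. Symmetrically, a processive-to-static switch whose following
#' static dwell is shorter than `min_static_segment` is misread as
#' processive-to-unbind (the short static is unresolvable); the switch
#' counts are rescaled by `1 / (1 - q)` with
#' `q = 1 - exp(-min_static_segment / tau_static)` and the unbind counts
#' reduced accordingly. The corrections require the count metadata stored
#' by [branching_fractions()]; when absent (e.g. counts built from
#' published fractions alone) they are skipped.
#'
#' The rate-decomposition identities
#' `k_off_processive + k_static = k_exit_processive` and
#' `k_off_static + k_processive = k_exit_static` hold exactly by
#' construction.
#'
#' @param fits named list of `exp_fit` objects; requires `processive` and,
#'   depending on pooling, `static_molecule` and/or `static_all`.
#' @param counts a `branching_counts` object.
#' @param static_pooling `"weighted"`, `"molecules_only"` or
#'   `"segments_only"`.
#' @param detection_correction correct switch counts and landing fractions
#'   for undetectable processive visits (see Details).
#' @return object of class `three_state_rates` with `k_exit_processive`,
#'   `k_exit_static`, `k_off_processive`, `k_static`, `k_off_static`,
#'   `k_processive`, `p_land_static`, `p_land_processive`,
#'   `tau_static_pooled`, and `detection_prob` (the estimated mean
#'   detection probability, `NA` when no correction was applied).
#' @export
derive_rates <- function(fits, counts,
                         static_pooling = c("weighted", "molecules_only",
                                            "segments_only"),
                         detection_correction = TRUE) {
  static_pooling <- match.arg(static_pooling)
  need <- c("processive",
            switch(static_pooling,
                   weighted = c("static_molecule", "static_all"),
                   molecules_only = "static_molecule",
                   segments_only = "static_all"))
  for (lab in need)
    if (is.null(fits[[lab]]))
      stop("derive_rates: missing dwell fit for label '", lab, "'",
           call. = FALSE)
  tau_p <- fits$processive$tau
  tau_s <- switch(static_pooling,
    weighted = {
      n1 <- fits$static_molecule$n; n2 <- fits$static_all$n
      (n1 * fits$static_molecule$tau + n2 * fits$static_all$tau) / (n1 + n2)
    },
    molecules_only = fits$static_molecule$tau,
    segments_only = fits$static_all$tau)
  k_exit_p <- 1 / tau_p
  k_exit_s <- 1 / tau_s
  f_pu <- counts$frac_processive_to_unbind
  f_su <- counts$frac_static_to_unbind
  p_ls <- counts$p_land_static_obs
  p_det <- NA_real_
  thr <- counts$detection_thresholds
  if (detection_correction && length(thr)) {
    # IPW mean detection probability over the (detection-biased) observed
    # speeds: p_det = n / sum(1 / P(detect | v_i))
    p_i <- exp(-thr / tau_p)
    p_det <- length(p_i) / sum(1 / p_i)
    s2p_c <- counts$n_static_to_processive / p_det
    f_su <- counts$n_static_to_unbind /
      (counts$n_static_to_unbind + s2p_c)
    p_lp_c <- min(1, counts$p_land_processive_obs / p_det)
    p_ls <- 1 - p_lp_c
    if (!is.null(counts$min_static_segment)) {
      # switches followed by an unresolvably short static read as unbinding
      q <- 1 - exp(-counts$min_static_segment / tau_s)
      p2s_c <- counts$n_processive_to_static / (1 - q)
      p2u_c <- max(0, counts$n_processive_to_unbind -
                      counts$n_processive_to_static * q / (1 - q))
      f_pu <- p2u_c / (p2u_c + p2s_c)
    }
  }
  structure(list(
    k_exit_processive = k_exit_p,
    k_exit_static = k_exit_s,
    k_off_processive = f_pu * k_exit_p,
    k_static = (1 - f_pu) * k_exit_p,
    k_off_static = f_su * k_exit_s,
    k_processive = (1 - f_su) * k_exit_s,
    p_land_static = p_ls,
    p_land_processive = 1 - p_ls,
    tau_static_pooled = tau_s,
    static_pooling = static_pooling,
    detection_prob = p_det), class = "three_state_rates")
}

#' @export
print.three_state_rates <- function(x, ...) {
  cat("<three_state_rates> (s^-1)\n")
  cat(sprintf("  processive exit %.4g = k_off_processive %.4g + k_static %.4g\n",
              x$k_exit_processive, x$k_off_processive, x$k_static))
  cat(sprintf("  static exit     %.4g = k_off_static     %.4g + k_processive %.4g\n",
              x$k_exit_static, x$k_off_static, x$k_processive))
  cat(sprintf("  landing split: static %.3f / processive %.3f\n",
              x$p_land_static, x$p_land_processive))
  invisible(x)
}

#' Closed-form observables of the embedded three-state Markov chain
#'
#' Analytic predictions from the discrete chain embedded in the rate model:
#' the probability of ever entering the processive state, the expected
#' number of processive and static visits per landing, the mean dwell per
#' visit, and the expected total bound time. Used as the oracle against
#' Monte-Carlo simulation.
#'
#' @param rates a `three_state_rates` object (or any list with the six
#'   rates and the landing probabilities).
#' @return list with `p_enter_processive`, `expected_processive_visits`,
#'   `expected_static_visits`, `mean_static_dwell`, `mean_processive_dwell`,
#'   `expected_bound_time`.
#' @export
predict_observables <- function(rates) {
  ks <- rates$k_exit_static
  kp <- rates$k_exit_processive
  if (ks <= 0 || kp <= 0)
    stop("predict_observables: exit rates must be positive", call. = FALSE)
  a <- rates$k_processive / ks      # P(static -> processive)
  b <- rates$k_static / kp          # P(processive -> static)
  pls <- rates$p_land_static
  plp <- rates$p_land_processive
  p_enter <- plp + pls * a
  r <- a * b
  e_proc <- p_enter / (1 - r)
  e_stat <- (pls + plp * b) / (1 - r)
  list(p_enter_processive = p_enter,
       expected_processive_visits = e_proc,
       expected_static_visits = e_stat,
       mean_static_dwell = 1 / ks,
       mean_processive_dwell = 1 / kp,
       expected_bound_time = e_stat / ks + e_proc / kp)
}

#' Assemble the full measured-parameter report
#'
#' Collects every cohort-level statistic the pipeline measures (counts and
#' percentages of molecule classes, dwell time constants with CIs, velocity
#' and run-length moments, branching percentages, jump statistics) together
#' with the derived three-state rates, as a machine-readable table.
#'
#' @param segmented filtered list of `segmented_trajectory` objects.
#' @param fits output of [fit_all_dwells()].
#' @param counts output of [branching_fractions()].
#' @param rates output of [derive_rates()].
#' @return data.frame with columns `parameter`, `value`, `ci_lo`, `ci_hi`,
#'   `n`, `units`.
#' @export
build_report <- function(segmented, fits, counts, rates) {
  st <- segment_table(segmented)
  proc <- st[st$kind == "processive", ]
  n_mol <- length(segmented)
  has_jump <- vapply(segmented, function(s) nrow(s$jumps) > 0, logical(1))
  jump_d <- unlist(lapply(segmented, function(s) s$jumps$distance_nm))
  row <- function(parameter, value, ci_lo = NA, ci_hi = NA, n = NA,
                  units = "") {
    data.frame(parameter = parameter, value = value, ci_lo = ci_lo,
               ci_hi = ci_hi, n = n, units = units)
  }
  fit_row <- function(parameter, lab) {
    f <- fits[[lab]]
    if (is.null(f)) return(NULL)
    row(parameter, f$tau, f$ci95[1], f$ci95[2], f$n, "s")
  }
  pct_static <- 100 * counts$n_static_only_molecules / max(1, n_mol)
  out <- rbind(
    row("total_molecules", n_mol, n = n_mol, units = "count"),
    row("percent_entirely_static", pct_static, units = "%"),
    row("percent_with_processive_segments", 100 - pct_static, units = "%"),
    fit_row("binding_duration_static_molecules", "static_molecule"),
    fit_row("binding_duration_processive_molecules", "processive_molecule"),
    row("percent_bound_into_processive_state",
        100 * (1 - counts$frac_processive_start_static), units = "%"),
    row("percent_bound_into_static_state",
        100 * counts$frac_processive_start_static, units = "%"),
    row("n_processive_segments",
        counts$n_processive_to_unbind + counts$n_processive_to_static,
        units = "count"),
    fit_row("duration_processive_segments", "processive"),
    row("velocity_mean", mean(proc$velocity), n = nrow(proc), units = "nm/s"),
    row("velocity_sd", stats::sd(proc$velocity), units = "nm/s"),
    row("run_length_mean", mean(proc$net_displacement), n = nrow(proc),
        units = "nm"),
    row("run_length_sd", stats::sd(proc$net_displacement), units = "nm"),
    row("percent_processive_end_unbinding",
        100 * counts$frac_processive_to_unbind, units = "%"),
    row("percent_processive_end_static",
        100 * (1 - counts$frac_processive_to_unbind), units = "%"),
    row("n_static_segments_of_processive",
        counts$n_static_segments_of_processive, units = "count"),
    fit_row("dwell_static_segments_of_processive", "static_all"),
    fit_row("dwell_static_segments_end_unbinding", "static_post"),
    fit_row("dwell_static_segments_end_processive", "static_pre"),
    row("percent_static_segments_end_unbinding",
        100 * counts$frac_static_to_unbind, units = "%"),
    row("percent_static_segments_end_processive",
        100 * (1 - counts$frac_static_to_unbind), units = "%"),
    row("percent_molecules_with_jumps", 100 * mean(has_jump), units = "%"),
    row("jump_distance_mean",
        if (length(jump_d)) mean(jump_d) else NA, n = length(jump_d),
        units = "nm"),
    fit_row("binding_duration_jump_molecules", "jump_molecule"),
    row("percent_landing_static", 100 * counts$p_land_static_obs,
        units = "%"),
    row("k_exit_processive", rates$k_exit_processive, units = "s^-1"),
    row("k_exit_static", rates$k_exit_static, units = "s^-1"),
    row("k_off_processive", rates$k_off_processive, units = "s^-1"),
    row("k_static", rates$k_static, units = "s^-1"),
    row("k_off_static", rates$k_off_static, units = "s^-1"),
    row("k_processive", rates$k_processive, units = "s^-1"))
  rownames(out) <- NULL
  out
}

#' Write a report table as TSV and Markdown
#'
#' @param report data.frame from [build_report()].
#' @param path_tsv,path_md output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path_tsv = NULL, path_md = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(report, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(path_md)) {
    fmt <- function(v) ifelse(is.na(v), "", signif(v, 4))
    lines <- c("| parameter | value | 95% CI | n | units |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s |", report$parameter,
                       fmt(report$value),
                       ifelse(is.na(report$ci_lo), "",
                              paste0(fmt(report$ci_lo), "-",
                                     fmt(report$ci_hi))),
                       ifelse(is.na(report$n), "", report$n), report$units))
    writeLines(lines, path_md)
  }
  invisible(report)
}
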