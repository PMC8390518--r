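#' Validate a pipeline configuration (file or list)
#'
#' Reads a YAML or JSON configuration, checks it against the known schema,
#' and fills defaults: the default thresholds are the study's operational
#' values (10 nm radius, 5 s minimum segment, 10 s inclusion, 500 s landing
#' cutoff, 510 s maximum, 1000 bootstrap iterations, 66.0 nm pixels,
#' 1 frame/s). An empty file yields the full default configuration.
#'
#' Recognized top-level blocks: `stages` (logical toggles: simulate, render,
#' localize, segment, fit, report), `sim` ([sim_config()] fields),
#' `movie` ([movie_spec()] fields), `segmentation`
#' ([segmentation_params()] fields), `kinetics` (boot_iterations,
#' static_pooling), and `seed`.
#'
#' @param config path to a YAML/JSON file, or a list, or `NULL` for
#'   defaults.
#' @return object of class `pipeline_config`; on invalid input an error
#'   listing every offending field.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a file path or a list",
                             call. = FALSE)
  errs <- character(0)
  known <- c("stages", "sim", "movie", "segmentation", "kinetics", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(unknown, collapse = ", ")))
  check_block <- function(block, fn, fn_name) {
    args <- config[[block]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      errs <<- c(errs, paste0("unknown ", block, " field(s): ",
                              paste(bad, collapse = ", ")))
    out <- tryCatch(do.call(fn, args[setdiff(names(args), bad)]),
                    error = function(e)
                      errs <<- c(errs, conditionMessage(e)))
    out
  }
  sim <- check_block("sim", sim_config, "sim_config")
  movie <- check_block("movie", movie_spec, "movie_spec")
  seg <- check_block("segmentation", segmentation_params,
                     "segmentation_params")
  kin <- config$kinetics
  if (is.null(kin)) kin <- list()
  bad_kin <- setdiff(names(kin), c("boot_iterations", "static_pooling"))
  if (length(bad_kin))
    errs <- c(errs, paste0("unknown kinetics field(s): ",
                           paste(bad_kin, collapse = ", ")))
  kin$boot_iterations <- if (is.null(kin$boot_iterations)) 1000L
                         else as.integer(kin$boot_iterations)
  if (!is.na(kin$boot_iterations) && kin$boot_iterations < 1)
    errs <- c(errs, "kinetics: boot_iterations must be >= 1")
  kin$static_pooling <- if (is.null(kin$static_pooling)) "weighted"
                        else kin$static_pooling
  if (!kin$static_pooling %in% c("weighted", "molecules_only",
                                 "segments_only"))
    errs <- c(errs, "kinetics: static_pooling must be one of weighted, molecules_only, segments_only")
  stages <- config$stages
  all_stages <- c("simulate", "render", "localize", "segment", "fit",
                  "report")
  if (is.null(stages))
    stages <- list(simulate = TRUE, render = FALSE, localize = FALSE,
                   segment = TRUE, fit = TRUE, report = TRUE)
  bad_st <- setdiff(names(stages), all_stages)
  if (length(bad_st))
    errs <- c(errs, paste0("unknown stage(s): ",
                           paste(bad_st, collapse = ", ")))
  for (s in all_stages) if (is.null(stages[[s]])) stages[[s]] <- FALSE
  seed <- config$seed
  if (is.null(seed)) seed <- if (!is.null(sim$rng_seed)) sim$rng_seed else 1L
  if (length(errs))
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  # one master seed drives every stage
  sim$rng_seed <- as.integer(seed)
  structure(list(stages = stages[all_stages], sim = sim, movie = movie,
                 segmentation = seg, kinetics = kin,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, render, localize,
#' segment, fit, report), writing each stage's artifact to `outdir`:
#' `trajectories.csv`, `ground_truth.json`, `movie.tif` + `beads.json`,
#' `localizations.csv`, `segments.csv`, `jumps.csv`, `molecules.csv`,
#' `filter_report.csv`, `fits.json`, `rates.json`, `report.tsv`,
#' `report.md`, and a `manifest.json` recording the seed, config hash and
#' row counts. When `localize` is enabled the segmentation consumes the
#' drift-corrected localized tracks instead of the simulated trajectories.
#'
#' @param config a [validate_config()] result, or anything it accepts.
#' @param outdir output directory (created if needed).
#' @param quiet suppress stage-boundary messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[cel7track] ", ...)
  manifest <- list(seed = cfg$seed, config_hash = config_hash(unclass(cfg)),
                   stages = cfg$stages, counts = list(), failed_at = NULL)
  finish <- function() {
    m <- manifest
    m[vapply(m, is.null, logical(1))] <- NULL
    jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(manifest)
  }
  run_stage <- function(name, expr) {
    say("stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      manifest$failed_at <<- name
      finish()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  trajectories <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    sim <- run_stage("simulate", simulate_experiment(cfg$sim))
    trajectories <- sim$trajectories
    utils::write.csv(trajectories, file.path(outdir, "trajectories.csv"),
                     row.names = FALSE)
    gt <- lapply(sim$ground_truth, function(g)
      list(molecule_id = g$molecule_id, landing_time = g$landing_time,
           heading = g$heading, total_dwell = g$total_dwell,
           anchor = g$anchor, states = g$states, jumps = g$jumps))
    jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest$counts$trajectory_rows <- nrow(trajectories)
    manifest$counts$molecules <- length(sim$ground_truth)
  } else {
    tr_path <- file.path(outdir, "trajectories.csv")
    if (file.exists(tr_path)) trajectories <- utils::read.csv(tr_path)
  }
  if (isTRUE(cfg$stages$render)) {
    run_stage("render", {
      stack <- render_movie(trajectories, cfg$movie, cfg$sim$n_frames,
                            drift = cfg$sim$drift,
                            seed = derive_seed(cfg$seed, "render"))
      write_stack(stack, file.path(outdir, "movie.tif"))
      jsonlite::write_json(
        list(bead_positions = cfg$movie$bead_positions,
             pixel_size = cfg$movie$pixel_size),
        file.path(outdir, "beads.json"), digits = NA, force = TRUE)
    })
  }
  if (isTRUE(cfg$stages$localize)) {
    trajectories <- run_stage("localize", {
      stack <- read_stack(file.path(outdir, "movie.tif"))
      spots <- localize_stack(stack, pixel_size = cfg$movie$pixel_size)
      linked <- link_spots(spots, n_frames = dim(stack)[3])
      fid <- linked[linked$is_fiducial, ]
      mol <- linked[!linked$is_fiducial, ]
      cd <- correct_drift(mol, fid, n_frames = dim(stack)[3])
      out <- cd$tracks
      out$molecule_id <- out$track_id
      out$t_s <- out$frame * cfg$sim$frame_interval
      out$intensity <- out$amplitude
      utils::write.csv(out, file.path(outdir, "localizations.csv"),
                       row.names = FALSE)
      out
    })
    manifest$counts$localized_rows <- nrow(trajectories)
  }
  segmented <- NULL
  if (isTRUE(cfg$stages$segment)) {
    res <- run_stage("segment", {
      if (is.null(trajectories)) stop("no trajectories available")
      seg_all <- segment_cohort(trajectories, cfg$segmentation,
                                movie_end_frame = cfg$sim$n_frames - 1L)
      apply_filters(seg_all, cfg$segmentation)
    })
    segmented <- res$retained
    utils::write.csv(segment_table(segmented),
                     file.path(outdir, "segments.csv"), row.names = FALSE)
    jumps <- do.call(rbind, lapply(segmented, function(s)
      if (nrow(s$jumps)) cbind(molecule_id = s$molecule_id, s$jumps)))
    if (is.null(jumps))
      jumps <- data.frame(molecule_id = integer(0), frame_start = integer(0),
                          frame_end = integer(0), distance_nm = numeric(0),
                          at_landing = logical(0))
    utils::write.csv(jumps, file.path(outdir, "jumps.csv"),
                     row.names = FALSE)
    mols <- data.frame(
      molecule_id = vapply(segmented, `[[`, numeric(1), "molecule_id"),
      molecule_class = vapply(segmented, `[[`, character(1),
                              "molecule_class"),
      landing_time = vapply(segmented, `[[`, numeric(1), "landing_time"),
      total_bound_duration = vapply(segmented, `[[`, numeric(1),
                                    "total_bound_duration"))
    utils::write.csv(mols, file.path(outdir, "molecules.csv"),
                     row.names = FALSE)
    utils::write.csv(res$report, file.path(outdir, "filter_report.csv"),
                     row.names = FALSE)
    manifest$counts$molecules_retained <- length(segmented)
  }
  fits <- NULL; counts <- NULL; rates <- NULL
  if (isTRUE(cfg$stages$fit)) {
    fitres <- run_stage("fit", {
      if (is.null(segmented)) stop("no segmented cohort available")
      samples <- dwell_samples(segmented)
      f <- fit_all_dwells(samples, cfg$segmentation,
                          cfg$kinetics$boot_iterations,
                          seed = derive_seed(cfg$seed, "bootstrap"),
                          frame_interval = cfg$sim$frame_interval)
      cn <- branching_fractions(segmented, cfg$segmentation)
      r <- derive_rates(f, cn, cfg$kinetics$static_pooling)
      jsonlite::write_json(
        lapply(f, unclass), file.path(outdir, "fits.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
      jsonlite::write_json(unclass(r), file.path(outdir, "rates.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      list(fits = f, counts = cn, rates = r)
    })
    fits <- fitres$fits; counts <- fitres$counts; rates <- fitres$rates
  }
  if (isTRUE(cfg$stages$report)) {
    run_stage("report", {
      if (is.null(rates)) stop("fit stage outputs required for the report")
      rep <- build_report(segmented, fits, counts, rates)
      write_report(rep, file.path(outdir, "report.tsv"),
                   file.path(outdir, "report.md"))
    })
  }
  say("done")
  finish()
}
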