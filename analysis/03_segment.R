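#!/usr/bin/env Rscript
# Classify the simulated cohort into static and processive segments and
# jump events with the operational definitions (10 nm static radius,
# >=10 nm over >=5 s for processive, >10 nm within two frames for jumps),
# apply the inclusion filters (>=10 s bound, landed by 500 s, <=510 s),
# and write the segment, jump and per-molecule tables.

library(cel7track)

trajectories <- read.csv("results/trajectories.csv")
params <- segmentation_params()
message("segmenting ", length(unique(trajectories$molecule_id)),
        " trajectories ...")
seg_all <- segment_cohort(trajectories, params, movie_end_frame = 999)
fl <- apply_filters(seg_all, params)
message(sprintf("filters: %d in, %d short, %d long, %d late -> %d retained",
                fl$report$n_input, fl$report$n_short, fl$report$n_long,
                fl$report$n_late, fl$report$n_retained))

st <- segment_table(fl$retained)
write.csv(st, "results/segments.csv", row.names = FALSE)
jumps <- do.call(rbind, lapply(fl$retained, function(s)
  if (nrow(s$jumps)) cbind(molecule_id = s$molecule_id, s$jumps)))
if (is.null(jumps)) jumps <- data.frame()
write.csv(jumps, "results/jumps.csv", row.names = FALSE)
mols <- data.frame(
  molecule_id = vapply(fl$retained, `[[`, numeric(1), "molecule_id"),
  molecule_class = vapply(fl$retained, `[[`, character(1), "molecule_class"),
  landing_time = vapply(fl$retained, `[[`, numeric(1), "landing_time"),
  total_bound_duration = vapply(fl$retained, `[[`, numeric(1),
                                "total_bound_duration"))
write.csv(mols, "results/molecules.csv", row.names = FALSE)
write.csv(fl$report, "results/filter_report.csv", row.names = FALSE)

pr <- st[st$kind == "processive", ]
message(sprintf("%.1f%% of molecules show processive segments (n = %d segments)",
                100 * mean(mols$molecule_class == "processive"), nrow(pr)))
message(sprintf("mean velocity %.2f nm/s, mean run length %.1f nm, %.1f%% of molecules jump",
                mean(pr$velocity), mean(pr$net_displacement),
                100 * mean(vapply(fl$retained, function(s)
                  nrow(s$jumps) > 0, logical(1)))))
message("wrote results/segments.csv, jumps.csv, molecules.csv")
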