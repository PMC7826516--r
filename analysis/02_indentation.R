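#!/usr/bin/env Rscript
# Quasi-static indentation of the single-supercell composite by the capped
# (16,0) tip: 0.5 A displacement steps with conjugate-gradient relaxation
# (RMS-gradient tolerance 0.1 kcal/(mol A)) at every step, forward stroke to
# tip coordinate +4.4 A and full retraction to -4.1 A.
#
# Writes: per-step records (coordinate, total energy, adhesion energy,
# per-layer maximum local stress), detected key points, relaxed frames, and
# the trajectory object reused by the downstream analysis scripts.

library(nanoindent)
dir.create("results", showWarnings = FALSE)

sup <- assemble_supercell(seed = 1)
tip <- build_capped_cnt(tip_spec(n = 16, target_length = 12))
scene <- place_tip(sup, tip, gap = 4.1)

traj <- run_indentation(
  scene,
  protocol_config(max_tip_coord = 4.4, retract_to = -4.1),
  default_ffparams(),
  mconfig = minimizer_config(max_iterations = 250),
  mconfig_initial = minimizer_config(max_iterations = 2000),
  verbose = TRUE)

write_trajectory_csv(traj, "results/trajectory.csv")
write_xyz(traj$frames, "results/trajectory_frames.xyz")
saveRDS(traj, "results/trajectory.rds")   # consumed by 03/04

kp <- detect_key_points(traj)
write.csv(kp, "results/key_points.csv", row.names = FALSE)

rec <- traj$records
cat(sprintf("\n%d records (%d forward, %d reverse)\n", nrow(rec),
            sum(rec$stroke == "forward"), sum(rec$stroke == "reverse")))
cat(sprintf("adhesion energy: %.2f kcal/mol before indentation, %.2f at the end of the reverse stroke\n",
            rec$e_adh[1], rec$e_adh[nrow(rec)]))
cat(sprintf("peak MLS %.2f GPa at tip coordinate %+.1f A; final MLS %.3f GPa\n",
            max(pmax(rec$mls_upper, rec$mls_lower)),
            rec$tip_edge_coord[which.max(pmax(rec$mls_upper, rec$mls_lower))],
            pmax(rec$mls_upper, rec$mls_lower)[nrow(rec)]))
cat("\nKey points:\n")
print(kp, row.names = FALSE)
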