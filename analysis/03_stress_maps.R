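#!/usr/bin/env Rscript
# Per-atom local-stress maps at the key points of the indentation:
# sigma_i = |E_i - E0_i| / V_i with V = 4 pi (1.7 A)^3 / 3, converted to GPa.
# Reads the trajectory produced by 02_indentation.R.

library(nanoindent)
traj <- readRDS("results/trajectory.rds")

rec <- traj$records
sp <- traj$stress_params
mls <- pmax(rec$mls_upper, rec$mls_lower)

# map the initial state, the vdW-contact minimum, the deepest point, and the
# final retracted state
fwd <- rec$stroke == "forward"
approach <- which(fwd & rec$tip_edge_coord < 0)
picks <- unique(c(1L,
                  approach[which.min(rec$e_total[approach])],
                  which.max(rec$tip_edge_coord),
                  nrow(rec)))
for (k in picks) {
  sm <- local_stress_map(traj$per_atom[[k]], traj$reference, sp,
                         layers = traj$composite$groups)
  path <- sprintf("results/stress_map_step%02d.csv", rec$step[k])
  write_stress_csv(sm, traj$composite, path)
  cat(sprintf("step %2d (%s, tip %+5.1f A): MLS upper %7.3f GPa, lower %6.3f GPa -> %s\n",
              rec$step[k], rec$stroke[k], rec$tip_edge_coord[k],
              max_layer_stress(sm, "upper_graphene")$value,
              max_layer_stress(sm, "lower_graphene")$value, path))
}

# MLS against indentation step, both strokes
write.csv(data.frame(step = rec$step, stroke = rec$stroke,
                     tip_edge_coord = rec$tip_edge_coord,
                     mls_upper = rec$mls_upper, mls_lower = rec$mls_lower),
          "results/mls_vs_step.csv", row.names = FALSE)
cat(sprintf("\nMLS rose from %.3f to %.3f GPa during loading and fell to %.3f GPa after retraction.\n",
            mls[1], max(mls), mls[length(mls)]))
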