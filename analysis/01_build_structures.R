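#!/usr/bin/env Rscript
# Build every structure of the study and record their composition.
#
# Generates: the DPPC molecule (C40H80NO8P, 130 atoms), the composite
# supercell (two 25.5 x 35.51 A graphene flakes, 618 C total, with two lipids
# 6.23 A from each sheet; 878 atoms), the 3x3 film fragment (7902 atoms), and
# the capped (16,0) nanotube tip (radius ~6.26 A) placed 4.1 A above the
# upper sheet.

library(nanoindent)
dir.create("results", showWarnings = FALSE)

dppc <- build_dppc(seed = 1)
sup <- assemble_supercell(seed = 1)
frag <- tile_fragment(sup, 3, 3)
tip_full <- build_capped_cnt(tip_spec(n = 16, target_length = 50.62))
tip_short <- build_capped_cnt(tip_spec(n = 16, target_length = 12))
scene <- place_tip(sup, tip_short, gap = 4.1)

write_xyz(dppc, "results/dppc.xyz")
write_xyz(sup, "results/supercell.xyz")
write_xyz(frag, "results/fragment.xyz")
write_xyz(scene$structure, "results/scene.xyz")
write_pdb(sup, "results/supercell.pdb")
write_bonds(sup, "results/supercell.bonds")

cyl <- tip_full$positions[tip_full$positions[, 2] > 1, ]
summary <- data.frame(
  quantity = c("dppc_atoms", "supercell_atoms", "supercell_graphene_atoms",
               "fragment_atoms", "cnt_radius_A", "cnt_length_A",
               "lipid_sheet_distance_A", "sheet_separation_A",
               "tip_gap_A", "tip_edge_coordinate_A"),
  value = c(n_atoms(dppc), n_atoms(sup),
            sum(sup$groups %in% c("upper_graphene", "lower_graphene")),
            n_atoms(frag),
            round(mean(sqrt(cyl[, 1]^2 + cyl[, 3]^2)), 4),
            round(diff(range(tip_full$positions[, 2])), 3),
            round(mean(sup$positions[sup$groups == "upper_graphene", 2]) -
                  mean(sup$positions[sup$groups == "lipid_1", 2]), 4),
            round(mean(sup$positions[sup$groups == "upper_graphene", 2]) -
                  mean(sup$positions[sup$groups == "lower_graphene", 2]), 4),
            4.1, scene$tip_edge_coord))
write.csv(summary, "results/structures_summary.csv", row.names = FALSE)
print(summary, row.names = FALSE)
cat("\nStructures written under results/.\n")
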