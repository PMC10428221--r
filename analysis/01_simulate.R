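#!/usr/bin/env Rscript
# Generate the synthetic study systems: a weakly-coupled ("unbound") and a
# strongly-coupled ("bound") toy channel trajectory sharing one planted
# allosteric chain, plus docking pose ensembles with planted modes.
suppressPackageStartupMessages(library(allopath))

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
seed <- 1L

spec <- toy_channel_spec()            # C4 tetramer, 10 residues/subunit
ref <- generate_toy_channel(spec, ligand = TRUE)
message("reference structure: ", nrow(ref$atom), " atoms, ",
        length(unique(paste(ref$atom$chain, ref$atom$resno))) - 1,
        " residues + 1 ligand")

# the same chain of residues 2..9 on subunit A carries the planted
# correlation; the "bound" system couples it more strongly
for (state in c("unbound", "bound")) {
  rho <- if (state == "bound") 0.9 else 0.5
  cov <- planted_covariance(path_nodes = 2:9, rho_path = rho)
  sys <- generate_trajectory(ref, cov, n_frames = 500L, seed = seed)
  files <- write_trajectory(sys, file.path("results/sim", state))
  message(sprintf("%s state: rho_path = %.1f, 500 frames -> %s",
                  state, rho, paste(basename(files), collapse = ", ")))
}

# docking pose ensembles: a dominant low-energy mode and a sparse rival,
# for two retained ligand states
states <- enumerate_ligand_states()$retained$state_id[1:2]
tabs <- lapply(seq_along(states), function(i) {
  pm <- planted_pose_model(modes = list(
    list(center = matrix(0, 5, 3), energy = -9.5, n_poses = 70,
         spread_sd = 0.3),
    list(center = matrix(c(9, 0, 0), 5, 3, byrow = TRUE), energy = -8.0,
         n_poses = 30, spread_sd = 0.3)),
    receptor_cluster = 1L, ligand_state = states[i])
  generate_pose_ensemble(pm, seed = seed + i)
})
poses <- do.call(rbind, tabs)
poses$pose_id <- seq_len(nrow(poses))
write_pose_table(poses, "results/sim/poses.tsv")
message("pose table: ", nrow(poses), " poses over ",
        length(states), " ligand states -> results/sim/poses.tsv")
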