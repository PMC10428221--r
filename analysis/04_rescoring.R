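#!/usr/bin/env Rscript
# Cluster the docking poses (2 A leader algorithm) and rank them under the
# bare energy, MaxP and MaxP' criteria.
suppressPackageStartupMessages(library(allopath))

dir.create("results/rescoring", showWarnings = FALSE, recursive = TRUE)
poses <- read_pose_table("results/sim/poses.tsv")
pj <- unlist(jsonlite::read_json("results/cluster/populations.json"))
pj <- pj / sum(pj)

ranked <- rescore_pose_table(poses, rmsd_threshold = 2,
                             receptor_populations = NULL, kT = 0.593)
message("pose clusters found: ", nrow(ranked))
top <- ranked[1, ]
message(sprintf(
  "MaxP top rank: %s cluster %d (P_I = %.2f, E_I = %.2f kcal/mol)",
  top$ligand_state, top$cluster, top$population, top$energy))
if (any(ranked$rank_maxp != ranked$rank_energy))
  message("note: MaxP and the bare energy ranking disagree on ",
          sum(ranked$rank_maxp != ranked$rank_energy), " clusters")

# MaxP': the poses were docked against receptor cluster 1; weighting by its
# ensemble population P_J penalizes it relative to a hypothetical dominant
# conformation
sets <- attr(ranked, "cluster_sets")
rp <- maxp_prime_score(sets, pj, kT = 0.593)
topp <- rp[1, ]
message(sprintf(
  "MaxP' top rank: %s cluster %d (P_J = %.3f, score = %.3g)",
  topp$ligand_state, topp$cluster, topp$p_receptor, topp$score_maxp_prime))
write.csv(ranked, "results/rescoring/maxp_ranking.csv", row.names = FALSE)
write.csv(rp, "results/rescoring/maxp_prime_ranking.csv", row.names = FALSE)
message("rankings written to results/rescoring/")
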