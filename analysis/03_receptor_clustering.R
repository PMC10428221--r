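#!/usr/bin/env Rscript
# Symmetry-aware k-means clustering of the unbound channel conformations;
# populations P_J feed the MaxP' rescoring.
suppressPackageStartupMessages(library(allopath))

dir.create("results/cluster", showWarnings = FALSE, recursive = TRUE)
sys <- load_system("results/sim/unbound.pdb", "results/sim/unbound.dcd",
                   system_label = "unbound")
aug <- symmetry_expand(sys)
message("symmetry expansion: ", nrow(sys$xyz), " frames -> ",
        nrow(aug$xyz), " items (x", length(unique(sys$pdb$atom$chain)) - 1,
        " cyclic relabelings)")

rcs <- kmeans_rmsd(aug, cluster_selection(), k = 4L, seed = 1L)
message("populations P_J: ",
        paste(sprintf("%.3f", rcs$populations), collapse = ", "))
write.csv(rcs$assignments, "results/cluster/assignments.csv",
          row.names = FALSE)
jsonlite::write_json(as.list(rcs$populations),
                     "results/cluster/populations.json",
                     auto_unbox = TRUE, digits = NA)
reps <- write_representatives(rcs, aug, "results/cluster")
message("medoid representatives written to results/cluster/")
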