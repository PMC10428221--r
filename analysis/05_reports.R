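#!/usr/bin/env Rscript
# Structural sanity reports: ligand-residue contact fractions and the
# pore-integrity distance check on the bound system.
suppressPackageStartupMessages(library(allopath))

dir.create("results/reports", showWarnings = FALSE, recursive = TRUE)
sys <- load_system("results/sim/bound.pdb", "results/sim/bound.dcd",
                   system_label = "bound")

cf <- contact_fractions(sys, cutoff = 4.5)
persistent <- cf[cf$fraction >= 0.5, ]
message("residues in persistent ligand contact (fraction >= 0.5): ",
        if (nrow(persistent)) paste(persistent$node_id, collapse = ", ")
        else "none")
write.csv(cf, "results/reports/contact_fractions.csv", row.names = FALSE)

pint <- pore_integrity(sys, marker_resno = 5)
message(sprintf("pore integrity (res 5 CA diagonals): %s",
                paste(sprintf("%s %.2f +/- %.2f A", pint$pairs, pint$mean,
                              pint$sd), collapse = "; ")))
write.csv(data.frame(frame = seq_len(nrow(pint$distances)),
                     pint$distances),
          "results/reports/pore_integrity.csv", row.names = FALSE)
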