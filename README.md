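# allopath

Allosteric pathway analysis for multi-subunit ion channels: weighted
residue-interaction networks built from molecular-dynamics trajectories,
plus the ensemble-docking post-processing needed to place a ligand into the
picture. The package targets the question "how does a bound activator
rewire the communication between the voltage-sensor and pore domains of a
channel?", but every component is generic: any topology + trajectory pair
with per-residue C&alpha; atoms works.

## The model

The protein (and optionally a ligand split into rigid fragments) becomes an
undirected graph. An edge between nodes *i* and *j* carries

&nbsp;&nbsp;&nbsp;&nbsp;*w<sub>ij</sub>* = −ln(*C<sub>ij</sub>* · *M̂<sub>ij</sub>*)

where *C<sub>ij</sub>* is a semi-binary contact map — the frame average of
a truncated Gaussian kernel of the C&alpha;–C&alpha; distance (1 within
7 Å, Gaussian tail of width σ = 0.6252 Å, hard zero at 10 Å) — and
*M̂<sub>ij</sub>* ∈ [0, 1] is the mutual information of the two side-chain
centre-of-mass displacement series normalized by their joint Shannon
entropy. Strong, persistent coupling gives cheap edges; the minimal
source-to-sink Dijkstra path length *d*<sub>min</sub> then measures
allosteric coupling (exp(−*d*<sub>min</sub>) is the end-to-end coupling
efficiency: 9 units of *d*<sub>min</sub> ≈ 4 orders of magnitude), and
Brandes betweenness ranks the residues carrying the communication.

Around the network core the package provides:

* **Ensemble-docking rescoring** — AutoDock-style energy-ordered leader
  clustering of poses at 2 Å RMSD, cluster energies *E<sub>I</sub>* and
  populations *P<sub>I</sub>*, and the population-weighted rankings
  MaxP = *P<sub>I</sub>* e<sup>−E<sub>I</sub>/kT</sup> and
  MaxP′ = *P<sub>J</sub>* *P<sub>I</sub>* e<sup>−E<sub>I</sub>/kT</sup>
  (receptor-conformation population *P<sub>J</sub>*), plus the discrete
  enumeration of ligand protonation/ring states (8 states, 4 retained).
* **Symmetry-aware receptor clustering** — k-means over superposed
  coordinates with explicit cyclic expansion of the homotetramer's subunit
  labels, medoid representatives, populations *P<sub>J</sub>*.
* **Structural reports** — ligand–residue contact fractions at 4.5 Å and
  diagonal pore-integrity distances.
* **A synthetic test bed** — C4-symmetric toy channels, trajectories with
  a planted correlated residue chain, and pose ensembles with planted
  modes, so every estimator is validated against known ground truth.

See `vignettes/allosteric-network-methods.Rmd` for the full methods
account, including why the kernel width and the MI estimator defaults are
what they are.

## Worked example

The `analysis/` scripts run the whole study at desk scale; the core of it
fits in a screenful:

```r
library(allopath)

ref <- generate_toy_channel(toy_channel_spec(), ligand = TRUE)
cov <- planted_covariance(path_nodes = 2:9, rho_path = 0.9)
sys <- generate_trajectory(ref, cov, n_frames = 500, seed = 1)

ns  <- extract_node_series(sys, ligand_map = list(
  frag1 = paste0("C", 1:3), frag2 = paste0("C", 4:6),
  frag3 = paste0("C", 7:9)))
net <- build_network(contact_map(ns), mi_matrix(ns)$M_hat,
                     nodes = ns$nodes)
src <- detect_region(ns, "A:2", radius = 7, occupancy = 0.7)
snk <- setdiff(detect_region(ns, "A:9", radius = 7, occupancy = 0.7), src)
min_path(net, src, snk)
#> path_result: d_min = 7.8471 via A:3 -> A:4 -> A:5 -> A:6 -> A:7 -> A:8
#> (1 co-minimal)
```

Running the numbered scripts in order (`Rscript analysis/01_simulate.R`
… `05_reports.R`) compares a weakly coupled "unbound" system
(ρ = 0.5 along the planted chain) with the strongly coupled "bound" one
(ρ = 0.9) and prints, among other things:

```
unbound:  d_min = 15.42 via A:3 -> A:4 -> A:5 -> A:6 -> A:7 -> A:8
bound:    d_min =  7.85 via A:3 -> A:4 -> A:5 -> A:6 -> A:7 -> A:8
coupling gain on binding: delta d_min = 7.58 (~3.3 orders of magnitude)
populations P_J: 0.237, 0.251, 0.261, 0.251
MaxP  top rank: Z(eae) cluster 1 (P_I = 0.70, E_I = -9.77 kcal/mol)
residues in persistent ligand contact (fraction >= 0.5): A:4, A:5, A:6
```

i.e. the planted chain is recovered as the minimal path in both states, its
cost drops by ~7.6 natural-log units (≈ 3.3 orders of magnitude in coupling
efficiency) when the coupling strengthens, the four symmetry-expanded
receptor clusters are uniformly populated as planted, and the dominant
planted pose mode wins the MaxP ranking. Tables land under `results/`.

`run_pipeline()` drives the same stages from a single YAML config and
writes a manifest with checksums for reproducibility audits.

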