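---
title: "Methods: mutual-information residue networks, ensemble-docking rescoring, and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutual-information residue networks and ensemble-docking rescoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

`allopath` analyses how perturbations — typically a bound small molecule —
rewire the allosteric communication between the voltage-sensor and pore
domains of a multi-subunit ion channel, using equilibrium MD trajectories as
input. This vignette is the package's account of the underlying models, the
tunable parameters, the numerical choices, and what the synthetic test bed
does and does not demonstrate.

## The residue network model

The channel (plus, optionally, a ligand split into a few rigid fragments) is
represented as a weighted undirected graph. Nodes are amino acids and ligand
fragments; an edge between nodes $i$ and $j$ carries the weight

$$ w_{ij} = -\ln\!\left(C_{ij}\,\hat M_{ij}\right), $$

so that a path's total length adds the logarithms of a contact-weighted
coupling efficiency along the chain, and $\exp(-d_{\min})$ can be read as the
end-to-end coupling efficiency of the best path. The natural logarithm is a
deliberate convention: with it, a difference of nine units in $d_{\min}$
corresponds to $9\log_{10}e \approx 3.9$, i.e. about four orders of
magnitude in coupling efficiency; a base-10 weight would make the same
difference nine orders.

**Contact term.** $C_{ij}$ is a semi-binary contact map: the frame average
of a truncated Gaussian kernel of the anchor distance $d_{ij}(t)$
(C$\alpha$ for residues, heavy-atom centre of mass for ligand fragments),

$$ K(d) = \begin{cases}
1 & d \le c \\
\exp\!\left(-\frac{(d-c)^2}{2\sigma^2}\right) & c < d < d_{\mathrm{cut}} \\
0 & d \ge d_{\mathrm{cut}},
\end{cases} $$

with defaults $c = 7$ Å and $d_{\mathrm{cut}} = 10$ Å. The width defaults to
the value solved from the calibration condition
$K(d_{\mathrm{cut}}) = 10^{-5}$,

$$ \sigma = \frac{d_{\mathrm{cut}} - c}{\sqrt{-2\ln 10^{-5}}} = 0.6252
\ \text{Å}, $$

which `sigma_from_constraint()` computes. The literature also reports a
broader width of $\sigma = 1.48$ Å for nominally the same calibration; that
value is not reproducible from the stated condition under this (or, in our
enumeration, any) parameterization of the shifted tail, so `kernel_params()`
accepts an explicit `sigma` for users who want to match it, while the
constraint-derived value is the package default. An unshifted Gaussian
centred at $c$ evaluated at 10 Å would need $\sigma = 2.08$; one whose $10^{-5}$
point is measured from zero gives $1.46$ — the ambiguity is documented rather
than resolved.

**Coupling term.** $\hat M_{ij} = M_{ij} / H_{ij} \in [0,1]$ is the mutual
information between the side-chain centre-of-mass displacement vectors
$\mathbf d_i(t)$ and $\mathbf d_j(t)$ (each node's displacement is its
side-chain COM minus the time average, so it is centred by construction),
normalized by the joint Shannon entropy. Normalizing by $H_{ij}$ requires
non-negative entropies, which discrete estimators guarantee; the default is
therefore a histogram estimator.

### Estimator choices

The histogram estimator discretizes each coordinate dimension into
$B = 16$ equal-width bins spanning $\pm 3$ standard deviations of that
dimension (samples beyond the range are clamped into the edge bins), applies
the Miller–Madow bias correction to every entropy, and sums the
per-dimension quantities $M$, $H_i$, $H_j$, $H_{ij}$ over x, y, z. Summing
per-dimension 2-D joint histograms, rather than binning the full 3-D vectors
(available as `dims = "joint"`), is a statistical necessity at trajectory
scale: a joint histogram over two 3-D variables has $B^6$ cells, and with
the $10^2$–$10^4$ frames typical of the estimator's inputs nearly every
occupied cell holds one sample, driving the naive estimate towards
$\ln n$ regardless of the data. The per-dimension sum is exact when the
coordinate dimensions are independent — which the synthetic generator
guarantees and roughly holds for isotropic side-chain rattling — and is the
well-sampled regime ($B^2 = 256$ cells) at 500 frames. The defaults were
chosen on the closed-form Gaussian benchmark: with them, the per-dimension
MI of a bivariate Gaussian is recovered within roughly 10% of
$-\tfrac12\ln(1-\rho^2)$ at 5000 frames for both $\rho = 0.5$ and
$\rho = 0.9$, with a residual positive bias of order $10^{-1}$ nats at 500
frames for independent series — small enough that background edges stay
expensive ($w \gtrsim 3.5$) relative to strongly coupled ones
($w \approx 1.5$ at $\rho = 0.9$).

A parametric Gaussian estimator (`method = "gaussian"`) is provided for
closed-form testing; its entropies are differential and can be negative, so
its normalized $\hat M$ is only meaningful for sufficiently broad
displacements.

Degenerate inputs: a node with zero displacement variance in all dimensions
has $\hat M = 0$ by definition (with a warning) — no information, no edge.
Zero-variance single dimensions are skipped in the per-dimension sum.

### Sources, sinks, paths, centrality

Source and sink regions are detected by a moving sphere: every node whose
anchor lies within 7 Å of the centre node's anchor in at least 70% of the
frames belongs to the region. $d_{\min}$ is the minimum Dijkstra distance
over all (source, sink) pairs; all co-minimal paths are retained and the
lexicographically smallest node sequence is designated `best_path`, so
reruns are deterministic even under ties. Per-node importance uses Brandes
betweenness on the weighted graph (igraph's undirected convention: each
unordered pair counted once, endpoints excluded). The test suite holds both
algorithms to exhaustive path enumeration on every small graph it
constructs.

Edges between sequence-adjacent residues are kept by default — backbone
neighbours genuinely do carry coupling — but `build_network()` exposes an
adjacency mask (`exclude_adjacent`) for users who want pathways forced
through tertiary contacts.

## Ensemble-docking rescoring

Docking against an ensemble of receptor conformations (the relaxed complex
scheme) produces, per receptor cluster $J$ and ligand state, a pile of
scored poses. The post-processing is:

1. **Ligand state enumeration.** The activator's discrete state space is
   protonation (zwitterionic/neutral) × ring pseudorotation × nitrogen
   pyramidalization = 8 states, named `Z(eea)`-style by the
   equatorial/axial attributes of the substituents at ring positions 1, 3,
   4; the positions-3/4 substituents are syn and always opposite. States
   with the position-1 substituent axial are dropped, retaining 4.
2. **Pose clustering.** An energy-ordered leader algorithm with a 2 Å
   heavy-atom RMSD threshold (no refitting — poses share the receptor
   frame): the best-energy unassigned pose founds each cluster, and poses
   join the first-founded cluster whose seed is within threshold. Cluster
   energy $E_I$ is the lowest member energy; population $P_I$ is the member
   fraction of the state's pose total.
3. **Rescoring.** $\mathrm{MaxP}_I = P_I\, e^{-E_I/kT}$ and
   $\mathrm{MaxP}'_{I,J} = P_J\, P_I\, e^{-E_I/kT}$, with $P_J$ the
   receptor-cluster population referred to the whole conformational
   ensemble, and $kT = 0.593$ kcal/mol (298 K). Only rankings are
   meaningful — the published algebra of these scores is not fully
   specified, and the Boltzmann-weighted population form was adopted as the
   natural reading of "maximum probability"; the additive equivalent
   $E_I - kT\ln P_I$ (identical ranking) is reported alongside for
   energy-unit intuition. Ties break by lower $E_I$, then cluster id.

Pose-cluster populations are normalized within their (receptor cluster,
ligand state) group, and groups are pooled into one ranked table;
cross-state RMSD comparisons are never attempted because the states have
different atom sets.

## Receptor clustering with cyclic symmetry

Channel conformations are clustered by k-means over superposed coordinates
of a residue selection (in the real system, the S5/S6 binding-site helices).
Because a homotetramer has four equivalent binding sites, each frame is
first expanded into four copies under cyclic relabeling of the subunits;
clustering the augmented set pools symmetry-equivalent conformations, and
populations are computed over the augmented items (normalization is
unaffected). Frames are superposed onto their mean structure in two passes,
and k-means runs in the flattened coordinate space, where Euclidean distance
is RMSD after alignment times $\sqrt{m}$. Initialization is seeded
farthest-point (first centre drawn from the seed, rest maximally spread);
the seed is recorded in the result. Representatives are medoids — the
member minimizing mean RMSD to its cluster mates, computed exactly up to 500
members and by the mean-squared-distance minimizer above that. Degenerate
input (fewer distinct conformations than $k$) reduces $k$ with a warning
rather than fabricating empty clusters.

The alternative of a symmetry-corrected RMSD inside the distance kernel
(minimizing over rotations per pair) was considered and rejected: expansion
is exactly equivalent for population purposes, simpler to audit, and keeps
`stats::kmeans` usable.

## Structural reports

Ligand–residue contact fractions count, per residue, the fraction of frames
in which any ligand heavy atom is within 4.5 Å of any side-chain heavy atom
(C$\alpha$ stands in for glycine, consistently with the node definition);
a fraction of 1 means the contact persists through the whole trajectory.
Pore integrity is monitored as the per-frame C$\alpha$–C$\alpha$ distances
between a marker residue (the selectivity-filter glycine in the real
channel) of diagonally opposite subunits — two pairs in a tetramer.
Pore-radius profiling is deliberately out of scope; the diagonal distance
check is the package's integrity surface.

## The synthetic test bed

Because the quantities above are only as trustworthy as their estimators,
the package ships a generator of desk-scale surrogate inputs with known
statistical structure:

* **Geometry.** `generate_toy_channel()` builds an exactly C$_n$-symmetric
  bundle of gently twisted rods (default: 4 subunits × 10 residues, each
  residue N/CA/C plus two side-chain atoms pointing outward). Spacings are
  chosen so that consecutive residues are in permanent contact
  (≈ 5.6 Å), residues two apart sit beyond the 10 Å truncation, and
  neighbouring subunits only touch through the kernel tail. This makes
  planted correlation structure identifiable: in a compact helix, i/i+2
  contact shortcuts combined with the transitivity of the planted
  correlations would let Dijkstra legitimately skip chain nodes, and
  "recover the planted chain" would be unachievable *by construction* — a
  property of the geometry, not of the estimators under test.
* **Displacements.** `generate_trajectory()` draws i.i.d. per-frame
  Gaussian displacements per coordinate dimension with a planted node
  correlation matrix, applied rigidly to each residue's atoms. Along the
  designated path the correlation is a first-order chain
  ($\rho^{|a-b|}$ between path positions — positive semi-definite by
  construction, with exactly $\rho$ between consecutive nodes); off-path
  nodes share a background correlation (default 0). Jointly infeasible
  requests are repaired by clipping negative eigenvalues at zero, with a
  warning and a flag; repairs beyond a relative tolerance of 0.5 are
  errors.
* **Poses.** `generate_pose_ensemble()` scatters poses around planted
  spatial modes with planted energies and populations, recording
  ground-truth memberships out-of-band.

Study conditions used throughout the tests and the acceptance script: 500
frames, displacement SD 0.8 Å per coordinate, planted chain of 8 residues at
$\rho = 0.9$ on one subunit, 20 replicate seeds; MI benchmark at 5000
frames; pose ensembles of 100–200 poses with modes 8–9 Å apart and spreads
0.2–0.3 Å. These sizes keep every check seconds-scale while leaving all
estimators in their intended sampling regime.

**What passing these tests does *not* show.** Frames are i.i.d., so nothing
here validates behaviour under the autocorrelation of real MD (where the
effective sample count is far below the frame count); displacements are
isotropic Gaussians, so the estimator's binning is never stressed by the
multimodal or anisotropic side-chain rotamer dynamics of real proteins; the
trajectory has no global drift, so the optional pre-superposition
(`align = TRUE` in `extract_node_series()`, logged when used) is untested
against genuinely diffusing inputs; and the toy geometry's clean contact
separation is kinder than a real fold's dense contact graph, where co-minimal
and near-minimal paths proliferate. Conclusions about a real channel should
rest on convergence checks across replicas, not on this test bed.

## Other numerical conventions

* Displacement centring is per trajectory; concatenate replicas before
  loading if pooled centring is wanted.
* Side-chain COM is mass-weighted over heavy atoms (masses from a small
  element table keyed on PDB atom names); hydrogens are excluded
  everywhere.
* The DCD writer emits a single dialect (no unit cell, 32-bit floats,
  native byte order) and is validated by round-trip against the
  \pkg{bio3d} reader; coordinates survive to $10^{-4}$ Å (float32).
* All generators and the clustering are pure functions of their inputs and
  an explicit integer seed; `run_pipeline()` writes a manifest with
  checksums so deterministic stages can be audited byte-for-byte.
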