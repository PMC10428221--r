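#' Specify a toy pseudo-channel
#'
#' Defines the geometry of a synthetic multi-subunit "channel": `n_subunits`
#' straight, gently twisted rods of residues arranged with exact cyclic
#' (C\eqn{n}) symmetry around the pore (z) axis. Each residue carries a
#' backbone (N, CA, C) and, unless listed in `glycine_at`, two side-chain
#' heavy atoms (CB, CG) pointing radially outward so that the side-chain
#' centre of mass is distinct from the CA anchor.
#'
#' The default spacing places consecutive residues within a subunit in
#' permanent contact (about 5.6 A between CA atoms) while residues two apart
#' sit beyond 10 A, and neighbouring subunits approach no closer than about
#' 9 A. The contact graph of the reference structure is therefore a sparse
#' bundle of chains with only weak inter-subunit kernel tails, which makes
#' planted correlation structure cleanly identifiable downstream.
#'
#' @param n_subunits Number of subunits (>= 1); default 4 (homotetramer).
#' @param residues_per_subunit Residues per subunit (>= 2).
#' @param bundle_radius Distance (A) from the pore axis to each subunit rod.
#' @param rise Vertical spacing (A) between consecutive residues of a rod.
#' @param twist Azimuthal advance (radians) per residue along a rod.
#' @param sidechain_offset Radial offset (A) of side-chain atoms from CA.
#' @param glycine_at Integer vector of global residue indices (1-based over
#'   all subunits, subunit-major) to emit as GLY with no side-chain heavy
#'   atoms.
#' @return An object of class `toy_channel_spec`.
#' @seealso [generate_toy_channel()]
#' @export
toy_channel_spec <- function(n_subunits = 4L, residues_per_subunit = 10L,
                             bundle_radius = 7, rise = 5.5, twist = 0.12,
                             sidechain_offset = 1.5, glycine_at = integer()) {
  n_subunits <- as.integer(n_subunits)
  residues_per_subunit <- as.integer(residues_per_subunit)
  if (is.na(n_subunits) || n_subunits < 1L)
    stop("n_subunits must be >= 1", call. = FALSE)
  if (is.na(residues_per_subunit) || residues_per_subunit < 2L)
    stop("residues_per_subunit must be >= 2", call. = FALSE)
  if (!is.finite(bundle_radius) || bundle_radius <= 0 ||
      !is.finite(rise) || rise <= 0)
    stop("bundle_radius and rise must be positive and finite", call. = FALSE)
  structure(list(n_subunits = n_subunits,
                 residues_per_subunit = residues_per_subunit,
                 bundle_radius = bundle_radius, rise = rise, twist = twist,
                 sidechain_offset = sidechain_offset,
                 glycine_at = as.integer(glycine_at)),
            class = "toy_channel_spec")
}

toy_residue_atoms <- function(gly) {
  if (gly) c("N", "CA", "C") else c("N", "CA", "C", "CB", "CG")
}

#' Generate the reference structure of a toy channel
#'
#' Builds the reference coordinates described by a [toy_channel_spec()]:
#' subunit k is subunit 1 rotated by exactly 360/n_subunits degrees about the
#' pore axis, so the copies superpose exactly under the cyclic rotation.
#' Optionally a small ligand (residue `LIG`, chain `L`) of nine heavy atoms in
#' three spatial groups is placed near the pore axis, to exercise
#' ligand-fragment nodes and ligand contact analyses.
#'
#' @param spec A [toy_channel_spec()].
#' @param ligand Logical; add the 9-atom toy ligand near the pore axis.
#' @return A `pdb` object (as used by \pkg{bio3d}) with atom table and
#'   reference coordinates; chains are labelled A, B, ... per subunit.
#' @export
generate_toy_channel <- function(spec, ligand = FALSE) {
  if (!inherits(spec, "toy_channel_spec"))
    stop("spec must be a toy_channel_spec", call. = FALSE)
  ns <- spec$n_subunits; nr <- spec$residues_per_subunit
  rows <- list()
  resno_global <- 0L
  for (s in seq_len(ns) - 1L) {
    phi_s <- 2 * pi * s / ns
    for (r in seq_len(nr) - 1L) {
      resno_global <- resno_global + 1L
      gly <- resno_global %in% spec$glycine_at
      phi <- phi_s + r * spec$twist
      ca <- c(spec$bundle_radius * cos(phi),
              spec$bundle_radius * sin(phi),
              r * spec$rise)
      u <- c(cos(phi), sin(phi), 0)          # outward radial unit vector
      ax <- c(-sin(phi), cos(phi), 0)        # tangential unit vector
      pos <- list(N  = ca + 1.2 * ax + c(0, 0, -0.8),
                  CA = ca,
                  C  = ca - 1.2 * ax + c(0, 0, 0.8))
      if (!gly) {
        pos$CB <- ca + spec$sidechain_offset * u
        pos$CG <- ca + 2 * spec$sidechain_offset * u + c(0, 0, 0.6)
      }
      for (a in names(pos)) {
        rows[[length(rows) + 1L]] <- list(
          elety = a, resid = if (gly) "GLY" else "LEU",
          chain = LETTERS[s + 1L], resno = r + 1L, xyz = pos[[a]])
      }
    }
  }
  if (ligand) {
    # placed in the groove just outside subunit A's side chains, spanning
    # the mid-height residues (an interfacial binding site)
    zmid <- (nr - 1L) * spec$rise / 2
    phi_m <- ((nr - 1L) / 2) * spec$twist
    rad <- spec$bundle_radius + 2 * spec$sidechain_offset + 1.5
    u <- c(cos(phi_m), sin(phi_m), 0)
    frag_centers <- rbind(rad * u + c(0, 0, zmid - 4),
                          rad * u + c(0, 0, zmid),
                          rad * u + c(0, 0, zmid + 4))
    offs <- rbind(c(0.8, 0, 0), c(-0.4, 0.7, 0), c(-0.4, -0.7, 0))
    nm <- paste0("C", 1:9)
    for (i in 1:3) for (j in 1:3) {
      rows[[length(rows) + 1L]] <- list(
        elety = nm[(i - 1) * 3 + j], resid = "LIG", chain = "L",
        resno = 1L, xyz = frag_centers[i, ] + offs[j, ])
    }
  }
  atom <- data.frame(
    type = "ATOM",
    eleno = seq_along(rows),
    elety = vapply(rows, `[[`, "", "elety"),
    alt = NA_character_,
    resid = vapply(rows, `[[`, "", "resid"),
    chain = vapply(rows, `[[`, "", "chain"),
    resno = vapply(rows, function(x) x$resno, 0L),
    insert = NA_character_,
    x = vapply(rows, function(x) x$xyz[1], 0),
    y = vapply(rows, function(x) x$xyz[2], 0),
    z = vapply(rows, function(x) x$xyz[3], 0),
    o = 1, b = 0, segid = NA_character_,
    elesy = substr(vapply(rows, `[[`, "", "elety"), 1, 1),
    charge = NA_character_,
    stringsAsFactors = FALSE)
  xyz <- as.numeric(t(as.matrix(atom[, c("x", "y", "z")])))
  pdb <- list(atom = atom, xyz = bio3d::as.xyz(matrix(xyz, nrow = 1)),
              calpha = atom$elety == "CA" & atom$resid != "LIG")
  class(pdb) <- c("pdb", "sse")
  stopifnot(all(is.finite(xyz)))
  pdb
}

#' Specify planted covariance for a synthetic trajectory
#'
#' Describes the per-residue displacement covariance to plant in a synthetic
#' trajectory. Nodes along `path_nodes` form a first-order correlation chain:
#' consecutive path nodes have correlation `rho_path`, and nodes `l` steps
#' apart along the chain have correlation `rho_path^l` (the chain structure
#' keeps the matrix positive semi-definite by construction). All off-path
#' node pairs share the background correlation `rho_background`, and
#' path/background cross-correlations are zero. The same correlation matrix
#' is applied independently to the x, y and z displacement coordinates, each
#' with standard deviation `noise_sd`.
#'
#' @param path_nodes Ordered integer vector of distinct global residue
#'   indices forming the correlated chain.
#' @param rho_path Correlation between consecutive path nodes, in (-1, 1).
#' @param rho_background Correlation among non-path nodes (default 0).
#' @param noise_sd Displacement standard deviation per coordinate (A).
#' @return An object of class `planted_covariance`.
#' @export
planted_covariance <- function(path_nodes = integer(), rho_path = 0.9,
                               rho_background = 0, noise_sd = 0.8) {
  path_nodes <- as.integer(path_nodes)
  if (anyDuplicated(path_nodes))
    stop("path_nodes must be distinct", call. = FALSE)
  if (!is.finite(rho_path) || abs(rho_path) >= 1)
    stop("rho_path must lie in (-1, 1)", call. = FALSE)
  if (!is.finite(rho_background) || abs(rho_background) >= 1)
    stop("rho_background must lie in (-1, 1)", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)
  structure(list(path_nodes = path_nodes, rho_path = rho_path,
                 rho_background = rho_background, noise_sd = noise_sd),
            class = "planted_covariance")
}

#' Realize the planted correlation matrix over n nodes
#'
#' Expands a [planted_covariance()] into an n x n correlation matrix and
#' repairs it to positive semi-definite form if needed by clipping negative
#' eigenvalues at zero (with a warning; the repair is recorded in the
#' `"psd_repaired"` attribute).
#'
#' @param cov A [planted_covariance()].
#' @param n_nodes Total number of nodes.
#' @param repair_tol Most negative eigenvalue (relative to the largest)
#'   accepted for silent repair; beyond it an error is raised.
#' @return Correlation matrix with attribute `psd_repaired`.
#' @export
planted_correlation_matrix <- function(cov, n_nodes, repair_tol = 0.5) {
  stopifnot(inherits(cov, "planted_covariance"))
  if (length(cov$path_nodes) && max(cov$path_nodes) > n_nodes)
    stop("path_nodes exceed n_nodes", call. = FALSE)
  R <- diag(n_nodes)
  off <- setdiff(seq_len(n_nodes), cov$path_nodes)
  if (length(off) > 1 && cov$rho_background != 0)
    R[off, off] <- cov$rho_background + diag(1 - cov$rho_background,
                                             length(off))
  m <- length(cov$path_nodes)
  if (m > 1) {
    lag <- abs(outer(seq_len(m), seq_len(m), "-"))
    R[cov$path_nodes, cov$path_nodes] <- cov$rho_path^lag
  }
  e <- eigen(R, symmetric = TRUE)
  repaired <- FALSE
  if (min(e$values) < -1e-10) {
    if (min(e$values) < -repair_tol * max(e$values))
      stop("planted correlation matrix is non-PSD beyond repair tolerance",
           call. = FALSE)
    warning("planted correlation matrix was not PSD; ",
            "negative eigenvalues clipped at 0")
    v <- pmax(e$values, 0)
    R <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(R)); R <- R / outer(d, d)
    repaired <- TRUE
  }
  attr(R, "psd_repaired") <- repaired
  R
}

#' Generate a synthetic trajectory with planted covariance
#'
#' Draws `n_frames` independent multivariate-Gaussian displacement vectors
#' per coordinate dimension with the planted node covariance, and applies
#' each node's displacement rigidly to all atoms of the corresponding
#' residue. Frames are i.i.d. (no autocorrelation): downstream estimators
#' treat frames as samples. The ligand, if present, is kept fixed at its
#' reference coordinates unless it is listed among the nodes.
#'
#' @param ref Reference structure from [generate_toy_channel()].
#' @param cov A [planted_covariance()].
#' @param n_frames Number of frames (>= 10).
#' @param seed Integer seed; identical seeds give bit-identical trajectories.
#' @return A `traj_system` (see [load_system()]) whose `ground_truth` field
#'   records the planted correlation matrix, path nodes and seed.
#' @export
generate_trajectory <- function(ref, cov, n_frames = 500L, seed = 1L) {
  stopifnot(inherits(ref, "pdb"), inherits(cov, "planted_covariance"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 10L) stop("n_frames must be >= 10", call. = FALSE)
  prot <- ref$atom$resid != "LIG"
  key <- paste(ref$atom$chain, ref$atom$resno)[prot]
  res_keys <- unique(key)
  n_nodes <- length(res_keys)
  R <- planted_correlation_matrix(cov, n_nodes)
  L <- chol_psd(R) * cov$noise_sd
  set.seed(as.integer(seed))
  natom <- nrow(ref$atom)
  xyz <- matrix(rep(as.numeric(ref$xyz[1, ]), each = n_frames),
                nrow = n_frames)
  atom_of_node <- match(key, res_keys)   # node index per protein atom
  prot_idx <- which(prot)
  for (k in 0:2) {                        # x, y, z drawn independently
    D <- matrix(rnorm(n_frames * n_nodes), n_frames) %*% L
    cols <- 3 * (prot_idx - 1) + k + 1
    xyz[, cols] <- xyz[, cols] + D[, atom_of_node]
  }
  new_traj_system(ref, xyz,
                  system_label = "synthetic",
                  ground_truth = list(path_nodes = cov$path_nodes,
                                      rho_path = cov$rho_path,
                                      rho_background = cov$rho_background,
                                      noise_sd = cov$noise_sd,
                                      correlation = R, seed = seed))
}

# Cholesky factor tolerant of PSD (rank-deficient) matrices.
chol_psd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(S, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0))))
}
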