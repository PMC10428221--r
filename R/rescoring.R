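#' Enumerate ligand states
#'
#' Enumerates the discrete ligand state space of the activator: protonation
#' form (zwitterionic `Z` vs neutral `N`), the pyramidalization state of the
#' piperidine nitrogen (substituent R1 at ring position 1 equatorial `e` or
#' axial `a`), and the ring pseudorotation state. The substituents at ring
#' positions 3 and 4 sit in a syn relationship and always adopt opposite
#' axial/equatorial orientations, so pseudorotation toggles them jointly
#' between (e, a) and (a, e). States are named `<Z|N>(<o1><o3><o4>)`.
#' Retention keeps only states with R1 equatorial.
#'
#' @param protonation_forms Character vector of protonation prefixes.
#' @param r1_orientations Orientations available to R1 (pyramidalization).
#' @param ring_states List of length-2 vectors: the (position 3, position 4)
#'   orientation pairs reachable by pseudorotation.
#' @return List with data frames `full` and `retained` (columns `state_id`,
#'   `protonation`, `o1`, `o3`, `o4`).
#' @export
enumerate_ligand_states <- function(protonation_forms = c("Z", "N"),
                                    r1_orientations = c("e", "a"),
                                    ring_states = list(c("e", "a"),
                                                       c("a", "e"))) {
  stopifnot(length(protonation_forms) >= 1, length(r1_orientations) >= 1,
            length(ring_states) >= 1)
  grid <- expand.grid(ring = seq_along(ring_states),
                      o1 = r1_orientations,
                      protonation = protonation_forms,
                      stringsAsFactors = FALSE)
  full <- data.frame(
    protonation = grid$protonation,
    o1 = grid$o1,
    o3 = vapply(ring_states, `[`, "", 1)[grid$ring],
    o4 = vapply(ring_states, `[`, "", 2)[grid$ring],
    stringsAsFactors = FALSE)
  full$state_id <- sprintf("%s(%s%s%s)", full$protonation, full$o1,
                           full$o3, full$o4)
  full <- full[, c("state_id", "protonation", "o1", "o3", "o4")]
  list(full = full, retained = full[full$o1 == "e", , drop = FALSE])
}

pose_rmsd_to <- function(coords, ref) {
  # coords: n_poses x 3m matrix; ref: length 3m; RMSD without refitting
  d2 <- sweep(coords, 2, ref)^2
  sqrt(rowSums(d2) / (length(ref) / 3))
}

#' Cluster docking poses by RMSD (energy-ordered leader algorithm)
#'
#' AutoDock-style pose clustering: poses are visited in order of increasing
#' energy; each pose joins the first existing cluster whose seed (its
#' lowest-energy member) lies within `rmsd_threshold` heavy-atom RMSD, else
#' it founds a new cluster. No superposition is applied — docked poses share
#' the receptor frame. The cluster energy E_I is the lowest member energy
#' and the population P_I is the member fraction of the input.
#'
#' @param poses Pose data frame (one ligand state and receptor cluster; see
#'   [read_pose_table()]).
#' @param rmsd_threshold Clustering threshold (A).
#' @return An object of class `pose_cluster_set`: `clusters` data frame
#'   (`cluster`, `n`, `population`, `energy`, `seed_pose_id`), `assignments`
#'   (cluster per input pose) and `rmsd_threshold`.
#' @export
cluster_poses <- function(poses, rmsd_threshold = 2.0) {
  validate_pose_table(poses)
  if (length(unique(poses$ligand_state)) > 1)
    stop("cluster_poses expects a single ligand state; ",
         "use rescore_pose_table() for mixed tables", call. = FALSE)
  cc <- pose_coord_columns(poses)
  X <- as.matrix(poses[, cc, drop = FALSE])
  if (any(!is.finite(X))) stop("pose coordinates must be finite",
                               call. = FALSE)
  ord <- order(poses$energy, poses$pose_id)
  seeds <- integer(); assign <- integer(nrow(poses))
  for (i in ord) {
    placed <- FALSE
    if (length(seeds)) {
      r <- pose_rmsd_to(X[seeds, , drop = FALSE], X[i, ])
      hit <- which(r <= rmsd_threshold)
      if (length(hit)) { assign[i] <- hit[1]; placed <- TRUE }
    }
    if (!placed) { seeds <- c(seeds, i); assign[i] <- length(seeds) }
  }
  n_I <- tabulate(assign, length(seeds))
  clusters <- data.frame(
    cluster = seq_along(seeds),
    n = n_I,
    population = n_I / nrow(poses),
    energy = vapply(seq_along(seeds),
                    function(I) min(poses$energy[assign == I]), 0),
    seed_pose_id = poses$pose_id[seeds])
  structure(list(clusters = clusters, assignments = assign,
                 rmsd_threshold = rmsd_threshold,
                 receptor_cluster = poses$receptor_cluster[1],
                 ligand_state = poses$ligand_state[1],
                 n_poses = nrow(poses)),
            class = "pose_cluster_set")
}

#' MaxP rescoring of pose clusters
#'
#' Scores each pose cluster as the Boltzmann-weighted population
#' `score_I = P_I * exp(-E_I / kT)` and ranks descending. The additive
#' equivalent `G_I = E_I - kT ln(P_I)` (identical ranking) is reported
#' alongside. Ties are broken by lower E_I, then cluster id. The plain
#' energy ranking (E_AD4) is included for comparison.
#'
#' @param clusters A `pose_cluster_set` (or its `clusters` data frame,
#'   optionally with `receptor_cluster` / `ligand_state` columns).
#' @param kT Thermal energy (kcal/mol); default 0.593 (298 K).
#' @return Data frame ranked by MaxP with columns `rank_maxp`,
#'   `rank_energy`, `score_maxp`, `g_maxp`, plus the cluster fields.
#' @export
maxp_score <- function(clusters, kT = 0.593) {
  cl <- if (inherits(clusters, "pose_cluster_set")) {
    df <- clusters$clusters
    df$receptor_cluster <- clusters$receptor_cluster
    df$ligand_state <- clusters$ligand_state
    df
  } else as.data.frame(clusters)
  if (abs(sum(cl$population) - 1) > 1e-8)
    stop("cluster populations must sum to 1", call. = FALSE)
  cl$score_maxp <- cl$population * exp(-cl$energy / kT)
  cl$g_maxp <- cl$energy - kT * log(cl$population)
  ord <- order(-cl$score_maxp, cl$energy, cl$cluster)
  cl <- cl[ord, , drop = FALSE]
  cl$rank_maxp <- seq_len(nrow(cl))
  cl$rank_energy <- rank(cl$energy, ties.method = "first")
  rownames(cl) <- NULL
  attr(cl, "kT") <- kT
  cl
}

#' MaxP-prime rescoring over a receptor-conformation ensemble
#'
#' Extends MaxP with the relative population of the receptor conformation:
#' `score_{I,J} = P_J * P_I * exp(-E_I / kT)`, ranked descending over all
#' (receptor cluster J, pose cluster I) pairs. Pose-cluster populations P_I
#' are normalized within their own receptor cluster (and ligand state);
#' P_J must be supplied for every receptor cluster referenced and sum to 1.
#'
#' @param cluster_sets List of `pose_cluster_set` objects (one per receptor
#'   cluster x ligand state).
#' @param receptor_populations Named numeric vector P_J keyed by receptor
#'   cluster id.
#' @param kT Thermal energy (kcal/mol).
#' @return Data frame ranked by MaxP-prime (`rank_maxp_prime`,
#'   `score_maxp_prime`, and the per-set MaxP fields).
#' @export
maxp_prime_score <- function(cluster_sets, receptor_populations,
                             kT = 0.593) {
  if (inherits(cluster_sets, "pose_cluster_set"))
    cluster_sets <- list(cluster_sets)
  if (abs(sum(receptor_populations) - 1) > 1e-6)
    stop("receptor populations must sum to 1", call. = FALSE)
  rows <- lapply(cluster_sets, function(cs) {
    df <- maxp_score(cs, kT = kT)
    J <- as.character(df$receptor_cluster[1])
    if (!J %in% names(receptor_populations))
      stop("missing receptor population for cluster ", J, call. = FALSE)
    df$p_receptor <- receptor_populations[[J]]
    df
  })
  out <- do.call(rbind, rows)
  out$score_maxp_prime <- out$p_receptor * out$score_maxp
  ord <- order(-out$score_maxp_prime, out$energy, out$cluster)
  out <- out[ord, , drop = FALSE]
  out$rank_maxp_prime <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "kT") <- kT
  out
}

#' Cluster and rescore a full pose table
#'
#' Splits a mixed pose table by (receptor cluster, ligand state), clusters
#' each group with [cluster_poses()], and pools the clusters into one ranked
#' table under the energy (E_AD4), MaxP and — when receptor populations are
#' given — MaxP-prime criteria. Pose-cluster populations refer to the
#' per-state pose total of their own group.
#'
#' @param poses Pose data frame (see [read_pose_table()]).
#' @param rmsd_threshold Pose clustering threshold (A).
#' @param receptor_populations Optional named P_J vector enabling
#'   MaxP-prime.
#' @param kT Thermal energy (kcal/mol).
#' @return Ranked data frame (per cluster) with scores and ranks; the
#'   `cluster_sets` attribute carries the per-group `pose_cluster_set`s.
#' @export
rescore_pose_table <- function(poses, rmsd_threshold = 2.0,
                               receptor_populations = NULL, kT = 0.593) {
  validate_pose_table(poses)
  groups <- split(poses,
                  list(poses$receptor_cluster, poses$ligand_state),
                  drop = TRUE)
  sets <- lapply(groups, cluster_poses, rmsd_threshold = rmsd_threshold)
  if (!is.null(receptor_populations)) {
    out <- maxp_prime_score(sets, receptor_populations, kT = kT)
  } else {
    out <- do.call(rbind, lapply(sets, maxp_score, kT = kT))
    ord <- order(-out$score_maxp, out$energy, out$cluster)
    out <- out[ord, , drop = FALSE]
    out$rank_maxp <- seq_len(nrow(out))
    out$rank_energy <- rank(out$energy, ties.method = "first")
    rownames(out) <- NULL
  }
  attr(out, "cluster_sets") <- sets
  out
}
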