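#' Selection of atoms for receptor clustering
#'
#' @param resno Integer vector of residue numbers (within-subunit numbering)
#'   to include; `NULL` keeps all.
#' @param chains Chains to include; `NULL` keeps all non-ligand chains.
#' @param heavy Keep heavy atoms only.
#' @return An object of class `cluster_selection`.
#' @export
cluster_selection <- function(resno = NULL, chains = NULL, heavy = TRUE) {
  structure(list(resno = resno, chains = chains, heavy = heavy),
            class = "cluster_selection")
}

selection_indices <- function(system, selection) {
  a <- system$pdb$atom
  keep <- a$resid != "LIG"
  if (!is.null(selection$chains)) keep <- keep & a$chain %in% selection$chains
  if (!is.null(selection$resno)) keep <- keep & a$resno %in% selection$resno
  if (selection$heavy) keep <- keep & is_heavy(a$elety)
  idx <- which(keep)
  if (!length(idx)) stop("selection matches no atoms", call. = FALSE)
  idx
}

subunit_blocks <- function(system) {
  a <- system$pdb$atom
  chains <- unique(a$chain[a$resid != "LIG"])
  blocks <- lapply(chains, function(ch) which(a$chain == ch &
                                                a$resid != "LIG"))
  sig <- lapply(blocks, function(ix) paste(a$elety[ix], a$resno[ix]))
  if (length(unique(vapply(sig, paste, "", collapse = "|"))) != 1)
    stop("subunits are not structurally congruent ",
         "(atom names/numbering differ across chains)", call. = FALSE)
  names(blocks) <- chains
  blocks
}

#' Expand frames under cyclic subunit relabeling
#'
#' Each frame contributes one copy per cyclic relabeling of the subunits
#' (chain A's slot receives chain B's coordinates, and so on). Because the
#' clustering metric is RMSD after superposition, the relabeled copies make
#' the four symmetry-equivalent binding sites of a homotetramer explicit:
#' conformations that differ only by which subunit carries a feature land
#' in the same cluster.
#'
#' @param system A `traj_system` whose subunits are congruent (same atom
#'   names and numbering per chain).
#' @return A `traj_system` with `n_subunits * n_frames` frames; its
#'   `meta$provenance$augmentation` data frame records (orig_frame,
#'   rotation) per augmented item.
#' @export
symmetry_expand <- function(system) {
  stopifnot(inherits(system, "traj_system"))
  blocks <- subunit_blocks(system)
  ns <- length(blocks)
  nf <- nrow(system$xyz)
  if (ns == 1) {
    system$meta$provenance$augmentation <-
      data.frame(orig_frame = seq_len(nf), rotation = 0L)
    return(system)
  }
  xyz_cols <- function(ix) as.integer(rbind(3 * ix - 2, 3 * ix - 1, 3 * ix))
  out <- matrix(NA_real_, nf * ns, ncol(system$xyz))
  prov <- data.frame(orig_frame = rep(seq_len(nf), ns),
                     rotation = rep(seq_len(ns) - 1L, each = nf))
  for (r in seq_len(ns) - 1L) {
    rows <- r * nf + seq_len(nf)
    perm <- system$xyz
    for (s in seq_len(ns)) {
      src <- blocks[[((s - 1L + r) %% ns) + 1L]]
      perm[, xyz_cols(blocks[[s]])] <- system$xyz[, xyz_cols(src)]
    }
    out[rows, ] <- perm
  }
  aug <- new_traj_system(system$pdb, out,
                         system_label = system$meta$system_label,
                         ground_truth = system$ground_truth,
                         provenance = c(system$meta$provenance,
                                        list(augmentation = prov)))
  aug
}

farthest_point_centers <- function(X, k, seed) {
  set.seed(as.integer(seed))
  n <- nrow(X)
  centers <- sample.int(n, 1)
  d2min <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  while (length(centers) < k) {
    cand <- which.max(d2min)
    centers <- c(centers, cand)
    d2 <- rowSums(sweep(X, 2, X[cand, ])^2)
    d2min <- pmin(d2min, d2)
  }
  X[centers, , drop = FALSE]
}

#' RMSD k-means clustering of receptor conformations
#'
#' Superposes all (augmented) frames onto their mean structure over the
#' selection, then runs k-means in the flattened coordinate space —
#' Euclidean distance there is proportional to RMSD after alignment. The
#' first centre is drawn from the seed, the rest by the farthest-point
#' heuristic; Lloyd/Hartigan--Wong refinement via [stats::kmeans()]. Each
#' cluster's representative is its medoid (member minimizing mean RMSD to
#' the other members; for clusters above `medoid_exact_max` members the
#' equivalent-in-practice mean-squared-distance minimizer is used).
#'
#' @param system A `traj_system`, typically from [symmetry_expand()].
#' @param selection A [cluster_selection()].
#' @param k Number of clusters.
#' @param seed Integer seed (initialization only; recorded in the result).
#' @param medoid_exact_max Largest cluster size for exact pairwise-RMSD
#'   medoids.
#' @return An object of class `receptor_cluster_set`: `assignments` data
#'   frame (item, orig_frame, rotation, cluster), `populations` (P_J, sums
#'   to 1), `medoids` (item index and provenance per cluster), `k`, `seed`.
#' @export
kmeans_rmsd <- function(system, selection = cluster_selection(), k = 10L,
                        seed = 1L, medoid_exact_max = 500L) {
  stopifnot(inherits(system, "traj_system"))
  idx <- selection_indices(system, selection)
  cols <- as.integer(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  X <- system$xyz[, cols, drop = FALSE]
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of frames", call. = FALSE)
  # two-pass superposition onto the mean structure
  all_inds <- seq_len(ncol(X))
  X <- bio3d::fit.xyz(fixed = X[1, ], mobile = X,
                      fixed.inds = all_inds, mobile.inds = all_inds)
  X <- bio3d::fit.xyz(fixed = colMeans(X), mobile = X,
                      fixed.inds = all_inds, mobile.inds = all_inds)
  n_distinct <- nrow(unique(round(X, 6)))
  k_eff <- as.integer(min(k, n_distinct))
  if (k_eff < k)
    warning("only ", n_distinct, " distinct conformations; using k = ",
            k_eff)
  if (k_eff == 1L) {
    assign <- rep(1L, n)
  } else {
    centers <- farthest_point_centers(X, k_eff, seed)
    km <- tryCatch(
      suppressWarnings(kmeans(X, centers = centers, iter.max = 200L)),
      error = function(e)
        suppressWarnings(kmeans(X, centers = centers, iter.max = 200L,
                                algorithm = "MacQueen")))
    assign <- km$cluster
  }
  m <- length(idx)
  medoid_of <- function(members) {
    if (length(members) == 1) return(members)
    Y <- X[members, , drop = FALSE]
    if (length(members) <= medoid_exact_max) {
      D <- as.matrix(dist(Y)) / sqrt(m)
      members[which.min(rowSums(D))]
    } else {
      ss <- rowSums(sweep(Y, 2, colMeans(Y))^2)
      members[which.min(ss)]
    }
  }
  medoid_items <- vapply(sort(unique(assign)),
                         function(J) medoid_of(which(assign == J)), 0L)
  prov <- system$meta$provenance$augmentation %||%
    data.frame(orig_frame = seq_len(n), rotation = 0L)
  pops <- as.numeric(table(factor(assign, levels = seq_len(k_eff))) / n)
  structure(list(
    assignments = data.frame(item = seq_len(n),
                             orig_frame = prov$orig_frame,
                             rotation = prov$rotation,
                             cluster = assign),
    populations = setNames(pops, seq_len(k_eff)),
    medoids = data.frame(cluster = seq_len(k_eff),
                         item = medoid_items,
                         orig_frame = prov$orig_frame[medoid_items],
                         rotation = prov$rotation[medoid_items]),
    k = k_eff, k_requested = as.integer(k), seed = as.integer(seed),
    selection = selection, aligned_xyz = X),
    class = "receptor_cluster_set")
}

#' @export
print.receptor_cluster_set <- function(x, ...) {
  cat(sprintf("receptor_cluster_set: k = %d over %d items; populations: %s\n",
              x$k, nrow(x$assignments),
              paste(sprintf("%.3f", x$populations), collapse = ", ")))
  invisible(x)
}

#' Write cluster representatives as PDB files
#'
#' @param set A `receptor_cluster_set`.
#' @param system The `traj_system` the set was computed from (same frame
#'   indexing).
#' @param dir Output directory.
#' @return Character vector of the files written.
#' @export
write_representatives <- function(set, system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- system$pdb$atom
  out <- character(set$k)
  for (J in seq_len(set$k)) {
    f <- file.path(dir, sprintf("representative_cluster%02d.pdb", J))
    bio3d::write.pdb(file = f,
                     xyz = as.numeric(system$xyz[set$medoids$item[J], ]),
                     resno = a$resno, resid = a$resid, eleno = a$eleno,
                     elety = a$elety, chain = a$chain)
    out[J] <- f
  }
  out
}
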