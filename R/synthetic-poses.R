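#' Specify planted docking pose modes
#'
#' Describes a synthetic docking outcome as a mixture of spatial modes: each
#' mode has a centre geometry (heavy-atom coordinates), a well energy
#' (kcal/mol), a pose count and an isotropic spatial spread. All modes must
#' share one atom count (poses of a single ligand state are congruent).
#'
#' @param modes List of modes; each a list with `center` (n_atoms x 3
#'   matrix), `energy` (kcal/mol), `n_poses` (>= 1) and `spread_sd` (A, > 0).
#' @param receptor_cluster Receptor-conformation cluster id for the table.
#' @param ligand_state Ligand state id (e.g. `"Z(eae)"`).
#' @param energy_jitter_sd Per-pose Gaussian jitter of the mode energy
#'   (kcal/mol).
#' @return An object of class `planted_pose_model`.
#' @export
planted_pose_model <- function(modes, receptor_cluster = 1L,
                               ligand_state = "Z(eae)",
                               energy_jitter_sd = 0.1) {
  if (!length(modes)) stop("modes must be non-empty", call. = FALSE)
  na <- unique(vapply(modes, function(m) nrow(as.matrix(m$center)), 0L))
  if (length(na) != 1)
    stop("all modes must share one atom count", call. = FALSE)
  for (m in modes) {
    if (is.null(m$n_poses) || m$n_poses < 1)
      stop("each mode needs n_poses >= 1", call. = FALSE)
    if (is.null(m$spread_sd) || m$spread_sd <= 0)
      stop("each mode needs spread_sd > 0", call. = FALSE)
    if (!is.finite(m$energy)) stop("mode energies must be finite",
                                   call. = FALSE)
  }
  structure(list(modes = modes, receptor_cluster = receptor_cluster,
                 ligand_state = ligand_state,
                 energy_jitter_sd = energy_jitter_sd, n_atoms = na),
            class = "planted_pose_model")
}

#' Generate a synthetic docking pose table
#'
#' Draws poses around each planted mode: coordinates are the mode centre
#' plus isotropic Gaussian scatter of `spread_sd`, energies are the mode
#' energy plus Gaussian jitter. The ground-truth mode membership of each
#' pose is recorded in the `true_mode` attribute (not a table column, so the
#' table mimics real docking output).
#'
#' @param model A [planted_pose_model()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Pose data frame (see [read_pose_table()] for the dialect) with
#'   attribute `true_mode` (integer vector).
#' @export
generate_pose_ensemble <- function(model, seed = 1L) {
  stopifnot(inherits(model, "planted_pose_model"))
  set.seed(as.integer(seed))
  na <- model$n_atoms
  rows <- list(); true_mode <- integer()
  pid <- 0L
  for (im in seq_along(model$modes)) {
    m <- model$modes[[im]]
    ctr <- as.numeric(t(as.matrix(m$center)))   # x1,y1,z1,...
    for (p in seq_len(m$n_poses)) {
      pid <- pid + 1L
      rows[[pid]] <- c(ctr + rnorm(3 * na, sd = m$spread_sd),
                       energy = m$energy + rnorm(1, sd = model$energy_jitter_sd))
      true_mode[pid] <- im
    }
  }
  M <- do.call(rbind, rows)
  coords <- M[, seq_len(3 * na), drop = FALSE]
  colnames(coords) <- paste0(c("x", "y", "z"), rep(seq_len(na), each = 3))
  df <- data.frame(pose_id = seq_len(pid),
                   receptor_cluster = model$receptor_cluster,
                   ligand_state = model$ligand_state,
                   energy = M[, 3 * na + 1],
                   coords, check.names = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "true_mode") <- true_mode
  df
}
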