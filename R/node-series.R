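BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

is_heavy <- function(elety) !grepl("^[0-9]*H", elety)

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, K = 39.098,
                  B = 10.81, I = 126.904)

# Atomic masses from PDB atom names (remote-position digits stripped,
# element = leading letter; adequate for protein/organic-ligand atoms).
atom_masses <- function(elety) {
  el <- substr(gsub("^[0-9]+", "", elety), 1, 1)
  m <- ELEMENT_MASS[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Extract per-node coordinate and displacement series
#'
#' Defines the network nodes of a trajectory system — one per protein
#' residue plus, when a ligand and a fragment map are supplied, one per
#' ligand fragment — and extracts per-frame series:
#' \itemize{
#'   \item \strong{anchor}: the CA position for residues, the mass-weighted
#'     heavy-atom centre of mass (COM) for ligand fragments; used for
#'     contact maps and region detection.
#'   \item \strong{displacement}: the side-chain heavy-atom COM (fragment
#'     COM for ligand nodes) minus its time average, so each node's mean
#'     displacement is the zero vector. Glycine, having no side-chain heavy
#'     atoms, falls back to its CA position.
#' }
#'
#' @param system A `traj_system` from [load_system()] or
#'   [generate_trajectory()].
#' @param ligand_map Named list mapping fragment ids to ligand atom-name
#'   vectors; the fragments must partition the ligand's heavy atoms.
#'   `NULL` for apo systems (an error if combined with `ligand_resname`
#'   atoms being present and `require_ligand = TRUE`).
#' @param ligand_resname Residue name identifying the ligand.
#' @param align Superpose all frames onto the mean structure (CA
#'   least-squares) before extracting series; off by default, and logged in
#'   the result when used.
#' @return An object of class `node_series`: `nodes` (data frame with
#'   `node_id`, `kind`, `chain`, `resno`, `resname`), `anchor` and `disp`
#'   arrays of dimension frames x nodes x 3, and `n_frames`.
#' @export
extract_node_series <- function(system, ligand_map = NULL,
                                ligand_resname = "LIG", align = FALSE) {
  stopifnot(inherits(system, "traj_system"))
  atom <- system$pdb$atom
  xyz <- system$xyz
  if (align) {
    ref <- colMeans(xyz)
    ca <- which(atom$elety == "CA" & atom$resid != ligand_resname)
    ca_xyz <- as.integer(rbind(3 * ca - 2, 3 * ca - 1, 3 * ca))
    xyz <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                          fixed.inds = ca_xyz, mobile.inds = ca_xyz)
  }
  nf <- nrow(xyz)
  mass <- atom_masses(atom$elety)

  is_lig <- atom$resid == ligand_resname
  prot <- which(!is_lig)
  key <- paste(atom$chain[prot], atom$resno[prot], sep = ":")
  res_keys <- unique(key)

  groups <- list(); meta <- list()
  for (rk in res_keys) {
    idx <- prot[key == rk]
    ca <- idx[atom$elety[idx] == "CA"]
    if (length(ca) != 1)
      stop("residue ", rk, " (", atom$resid[idx][1],
           ") lacks a unique CA atom", call. = FALSE)
    sc <- idx[!(atom$elety[idx] %in% BACKBONE_ATOMS) &
                is_heavy(atom$elety[idx])]
    if (length(sc) == 0) sc <- ca       # glycine fallback
    groups[[rk]] <- list(anchor = ca, com = sc)
    meta[[rk]] <- data.frame(node_id = rk, kind = "residue",
                             chain = atom$chain[ca], resno = atom$resno[ca],
                             resname = atom$resid[ca],
                             stringsAsFactors = FALSE)
  }
  if (!is.null(ligand_map)) {
    if (!any(is_lig))
      stop("ligand_map supplied but no '", ligand_resname,
           "' residue present", call. = FALSE)
    lig_idx <- which(is_lig & is_heavy(atom$elety))
    lig_names <- atom$elety[lig_idx]
    mapped <- unlist(ligand_map, use.names = FALSE)
    if (anyDuplicated(mapped) ||
        !setequal(mapped, lig_names))
      stop("ligand_map fragments must partition the ligand heavy atoms",
           call. = FALSE)
    for (fid in names(ligand_map)) {
      idx <- lig_idx[lig_names %in% ligand_map[[fid]]]
      nid <- paste0(ligand_resname, ":", fid)
      groups[[nid]] <- list(anchor = idx, com = idx)  # fragment COM anchors
      meta[[nid]] <- data.frame(node_id = nid, kind = "fragment",
                                chain = atom$chain[idx[1]], resno = NA_integer_,
                                resname = ligand_resname,
                                stringsAsFactors = FALSE)
    }
  }
  nodes <- do.call(rbind, meta)
  rownames(nodes) <- NULL
  nn <- nrow(nodes)
  anchor <- array(NA_real_, c(nf, nn, 3))
  disp <- array(NA_real_, c(nf, nn, 3))
  for (i in seq_len(nn)) {
    g <- groups[[nodes$node_id[i]]]
    anchor[, i, ] <- com_series(xyz, g$anchor, mass)
    com <- com_series(xyz, g$com, mass)
    disp[, i, ] <- sweep(com, 2, colMeans(com))
  }
  dimnames(anchor) <- dimnames(disp) <- list(NULL, nodes$node_id, c("x", "y", "z"))
  structure(list(nodes = nodes, anchor = anchor, disp = disp,
                 n_frames = nf, aligned = align),
            class = "node_series")
}

# frames x 3 mass-weighted COM of a set of atom indices
com_series <- function(xyz, idx, mass) {
  w <- mass[idx] / sum(mass[idx])
  out <- matrix(0, nrow(xyz), 3)
  for (k in 0:2)
    out[, k + 1] <- xyz[, 3 * (idx - 1) + k + 1, drop = FALSE] %*% w
  out
}

#' @export
print.node_series <- function(x, ...) {
  cat(sprintf("node_series: %d nodes (%d residues, %d fragments), %d frames\n",
              nrow(x$nodes), sum(x$nodes$kind == "residue"),
              sum(x$nodes$kind == "fragment"), x$n_frames))
  invisible(x)
}
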