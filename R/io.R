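new_traj_system <- function(pdb, xyz, frame_range_used = NULL,
                            system_label = "", ground_truth = NULL,
                            provenance = list()) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3 * nrow(pdb$atom))
  structure(list(
    pdb = pdb, xyz = xyz,
    meta = list(n_frames = nrow(xyz),
                frame_range_used = frame_range_used %||% c(1L, nrow(xyz)),
                system_label = system_label,
                ligand_present = any(pdb$atom$resid == "LIG"),
                provenance = provenance),
    ground_truth = ground_truth), class = "traj_system")
}

#' @export
print.traj_system <- function(x, ...) {
  cat(sprintf("traj_system: %d atoms, %d frames (%s)%s\n",
              nrow(x$pdb$atom), x$meta$n_frames, x$meta$system_label,
              if (x$meta$ligand_present) ", ligand present" else ""))
  invisible(x)
}

#' Write a trajectory to a CHARMM-style DCD file
#'
#' Minimal single-dialect DCD writer (no unit cell, 32-bit coordinates,
#' native byte order) compatible with [bio3d::read.dcd()] and the common MD
#' analysis readers.
#'
#' @param xyz Numeric matrix, frames in rows, coordinates as
#'   (x1, y1, z1, x2, ...) in columns.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dcd <- function(xyz, path) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) %% 3 != 0) stop("xyz columns must be a multiple of 3")
  nf <- nrow(xyz); natom <- as.integer(ncol(xyz) / 3)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  writeBin(icntrl[1:9], con, size = 4)
  writeBin(1.0, con, size = 4)   # timestep slot, stored as a 32-bit float
  writeBin(icntrl[11:20], con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(sprintf("%-80s", "written by allopath"), con, nchars = 80,
            eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4); writeBin(natom, con, size = 4)
  writeBin(4L, con, size = 4)
  ix <- seq(1L, 3L * natom, by = 3L)
  for (f in seq_len(nf)) {
    for (k in 0:2) {
      writeBin(4L * natom, con, size = 4)
      writeBin(as.numeric(xyz[f, ix + k]), con, size = 4)
      writeBin(4L * natom, con, size = 4)
    }
  }
  invisible(path)
}

#' Write a synthetic system to disk (topology + trajectory + ground truth)
#'
#' Emits the PDB topology, the DCD trajectory, and (for generated systems) a
#' JSON sidecar with the planted ground truth.
#'
#' @param system A `traj_system`.
#' @param prefix Path prefix; writes `<prefix>.pdb`, `<prefix>.dcd` and,
#'   when ground truth is present, `<prefix>_truth.json`.
#' @return Named character vector of the files written.
#' @export
write_trajectory <- function(system, prefix) {
  stopifnot(inherits(system, "traj_system"))
  pdb_path <- paste0(prefix, ".pdb")
  dcd_path <- paste0(prefix, ".dcd")
  a <- system$pdb$atom
  bio3d::write.pdb(file = pdb_path, xyz = as.numeric(system$pdb$xyz[1, ]),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain)
  write_dcd(system$xyz, dcd_path)
  out <- c(pdb = pdb_path, dcd = dcd_path)
  if (!is.null(system$ground_truth)) {
    gt <- system$ground_truth
    gt$correlation <- NULL   # matrices stay in memory; sidecar is summary
    json_path <- paste0(prefix, "_truth.json")
    jsonlite::write_json(gt, json_path, auto_unbox = TRUE, digits = NA)
    out <- c(out, truth = json_path)
  }
  out
}

parse_frame_selection <- function(sel, n_frames) {
  if (is.null(sel)) return(seq_len(n_frames))
  if (is.character(sel) && length(sel) == 1) {
    m <- regmatches(sel, regexec("^(first|last)\\s+(\\d+)$", sel))[[1]]
    if (length(m) != 3)
      stop("frame_selection string must be 'first N' or 'last N'",
           call. = FALSE)
    n <- min(as.integer(m[3]), n_frames)
    idx <- if (m[2] == "first") seq_len(n)
           else seq.int(n_frames - n + 1L, n_frames)
    return(idx)
  }
  idx <- as.integer(sel)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_frames))
    stop("frame_selection indices out of range [1, ", n_frames, "]",
         call. = FALSE)
  idx
}

#' Load a topology + trajectory into a trajectory system
#'
#' Reads a PDB topology and a DCD trajectory (via \pkg{bio3d}), checks that
#' atom counts agree, and slices frames.
#'
#' @param topology Path to a PDB file, or a `pdb` object.
#' @param trajectory Path to a DCD file, or a frames-by-3N coordinate
#'   matrix. `NULL` uses the topology's own coordinates as a single frame.
#' @param frame_selection `NULL` (all frames), an integer vector of frame
#'   indices, or a string `"first N"` / `"last N"`.
#' @param system_label Free-text label stored in the metadata (e.g. a
#'   gating-charge tag).
#' @return A `traj_system`: list with `pdb`, `xyz` (frames x 3N matrix) and
#'   `meta` (frame count, range used, label, ligand flag, provenance).
#' @export
load_system <- function(topology, trajectory = NULL, frame_selection = NULL,
                        system_label = "") {
  prov <- list()
  if (is.character(topology)) {
    prov$topology <- topology
    topology <- bio3d::read.pdb(topology)
  }
  if (!inherits(topology, "pdb"))
    stop("topology must be a PDB path or bio3d pdb object", call. = FALSE)
  if (is.null(trajectory)) {
    xyz <- matrix(as.numeric(topology$xyz[1, ]), nrow = 1)
  } else if (is.character(trajectory)) {
    prov$trajectory <- trajectory
    xyz <- tryCatch(
      unclass(bio3d::read.dcd(trajectory, verbose = FALSE)),
      error = function(e) stop("unreadable trajectory '", trajectory,
                               "': ", conditionMessage(e), call. = FALSE))
  } else {
    xyz <- as.matrix(trajectory)
  }
  if (ncol(xyz) != 3 * nrow(topology$atom))
    stop(sprintf(
      "atom count mismatch: topology has %d atoms, trajectory has %g",
      nrow(topology$atom), ncol(xyz) / 3), call. = FALSE)
  idx <- parse_frame_selection(frame_selection, nrow(xyz))
  if (length(idx) == 0) stop("empty frame selection", call. = FALSE)
  new_traj_system(topology, xyz[idx, , drop = FALSE],
                  frame_range_used = range(idx),
                  system_label = system_label, provenance = prov)
}

#' Write a network as edge list (TSV) and GraphML
#'
#' @param net An `igraph` network from [build_network()].
#' @param prefix Path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @return Named character vector of the files written.
#' @export
write_network <- function(net, prefix) {
  el <- igraph::as_data_frame(net, what = "edges")
  tsv <- paste0(prefix, "_edges.tsv")
  write.table(el, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(net, gml, format = "graphml")
  c(edges = tsv, graphml = gml)
}

#' Read/write docking pose tables
#'
#' Pose tables are TSV/CSV with columns `pose_id`, `receptor_cluster`,
#' `ligand_state`, `energy` (kcal/mol) followed by heavy-atom coordinate
#' triplets `x1,y1,z1,x2,...` (A); all poses of one ligand state must carry
#' the same atom count.
#'
#' @param path File path; `sep` is inferred from the extension (`.csv` vs
#'   `.tsv`).
#' @return `read_pose_table()` returns the pose data frame.
#' @export
read_pose_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  validate_pose_table(df)
  df
}

#' @rdname read_pose_table
#' @param poses Pose data frame.
#' @export
write_pose_table <- function(poses, path) {
  validate_pose_table(poses)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(poses, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_pose_table <- function(df) {
  need <- c("pose_id", "receptor_cluster", "ligand_state", "energy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pose table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(df$energy)))
    stop("pose energies must be finite", call. = FALSE)
  cc <- pose_coord_columns(df)
  if (length(cc) == 0 || length(cc) %% 3 != 0)
    stop("pose table needs coordinate triplets x1,y1,z1,...", call. = FALSE)
  invisible(df)
}

pose_coord_columns <- function(df) {
  grep("^[xyz][0-9]+$", names(df), value = TRUE)
}
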