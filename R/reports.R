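#' Ligand-residue contact fractions
#'
#' For each protein residue, the fraction of frames in which any ligand
#' heavy atom lies within `cutoff` of any side-chain heavy atom of the
#' residue (CA for glycine). A fraction of 1 means the contact persists for
#' the whole trajectory.
#'
#' @param system A `traj_system` containing the ligand.
#' @param cutoff Contact cutoff (A); default 4.5.
#' @param ligand_resname Residue name identifying the ligand.
#' @return Data frame with `node_id`, `chain`, `resno`, `resname`,
#'   `fraction`; attribute `cutoff` records the convention.
#' @export
contact_fractions <- function(system, cutoff = 4.5,
                              ligand_resname = "LIG") {
  stopifnot(inherits(system, "traj_system"))
  a <- system$pdb$atom
  lig <- which(a$resid == ligand_resname & is_heavy(a$elety))
  if (!length(lig)) stop("no ligand ('", ligand_resname,
                         "') present", call. = FALSE)
  xyz <- system$xyz
  nf <- nrow(xyz)
  cols <- function(ix) as.integer(rbind(3 * ix - 2, 3 * ix - 1, 3 * ix))
  prot <- which(a$resid != ligand_resname)
  key <- paste(a$chain[prot], a$resno[prot], sep = ":")
  res_keys <- unique(key)
  frac <- numeric(length(res_keys))
  lx <- xyz[, cols(lig), drop = FALSE]
  nl <- length(lig)
  for (ri in seq_along(res_keys)) {
    idx <- prot[key == res_keys[ri]]
    sc <- idx[!(a$elety[idx] %in% BACKBONE_ATOMS) & is_heavy(a$elety[idx])]
    if (!length(sc)) sc <- idx[a$elety[idx] == "CA"]
    hit <- rep(FALSE, nf)
    for (s in sc) {
      sx <- xyz[, cols(s), drop = FALSE]
      for (l in seq_len(nl)) {
        d2 <- (sx[, 1] - lx[, 3 * l - 2])^2 + (sx[, 2] - lx[, 3 * l - 1])^2 +
          (sx[, 3] - lx[, 3 * l])^2
        hit <- hit | d2 <= cutoff^2
      }
    }
    frac[ri] <- mean(hit)
  }
  first <- prot[match(res_keys, key)]
  out <- data.frame(node_id = res_keys, chain = a$chain[first],
                    resno = a$resno[first], resname = a$resid[first],
                    fraction = frac, stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}

#' Pore-integrity distance series
#'
#' Per-frame CA-CA distances between the marker residue of diagonally
#' opposite subunits (two pairs in a tetramer), the standard check that the
#' conduction pore neither collapses nor dilates during a simulation.
#'
#' @param system A `traj_system` with an even number of subunits.
#' @param marker_resno Within-subunit residue number of the marker (the
#'   selectivity-filter glycine in the real channel).
#' @return An object of class `pore_integrity`: `distances` (frames x
#'   pairs matrix), `pairs` (chain pairs), `mean`, `sd`.
#' @export
pore_integrity <- function(system, marker_resno) {
  stopifnot(inherits(system, "traj_system"))
  a <- system$pdb$atom
  chains <- unique(a$chain[a$resid != "LIG"])
  ns <- length(chains)
  if (ns %% 2 != 0)
    stop("diagonal pairs require an even subunit count", call. = FALSE)
  ca <- vapply(chains, function(ch) {
    i <- which(a$chain == ch & a$resno == marker_resno & a$elety == "CA")
    if (length(i) != 1)
      stop("marker residue ", marker_resno, " missing (or not unique) in ",
           "subunit ", ch, call. = FALSE)
    i
  }, 0L)
  half <- ns / 2
  pairs <- cbind(seq_len(half), seq_len(half) + half)
  D <- matrix(NA_real_, nrow(system$xyz), half)
  for (p in seq_len(half)) {
    i <- ca[pairs[p, 1]]; j <- ca[pairs[p, 2]]
    d2 <- 0
    for (k in 0:2)
      d2 <- d2 + (system$xyz[, 3 * (i - 1) + k + 1] -
                    system$xyz[, 3 * (j - 1) + k + 1])^2
    D[, p] <- sqrt(d2)
  }
  colnames(D) <- apply(pairs, 1, function(pr)
    paste(chains[pr[1]], chains[pr[2]], sep = "-"))
  structure(list(distances = D,
                 pairs = colnames(D),
                 mean = colMeans(D),
                 sd = apply(D, 2, sd)),
            class = "pore_integrity")
}

#' @export
print.pore_integrity <- function(x, ...) {
  cat("pore_integrity:",
      paste(sprintf("%s %.2f +/- %.2f A", x$pairs, x$mean, x$sd),
            collapse = "; "), "\n")
  invisible(x)
}
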