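#' Truncated-Gaussian contact kernel parameters
#'
#' The semi-binary contact kernel is 1 for distances up to the cutoff `c`,
#' decays as a shifted Gaussian `exp(-(d - c)^2 / (2 sigma^2))` beyond it,
#' and is truncated to exactly 0 at `d_cut`. By default `sigma` is solved
#' from the constraint K(`d_cut`) = `epsilon`:
#' `sigma = (d_cut - c) / sqrt(-2 log(epsilon))`, giving 0.6252 A for the
#' defaults (c = 7 A, d_cut = 10 A, epsilon = 1e-5). A different sigma
#' (e.g. a broader tail) may be supplied explicitly.
#'
#' @param cutoff Contact cutoff c (A); kernel is 1 inside it.
#' @param d_cut Hard truncation distance (A); kernel is 0 at and beyond it.
#' @param epsilon Kernel value imposed at `d_cut` when solving for sigma.
#' @param sigma Gaussian width (A); `NULL` solves it from the constraint.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(cutoff = 7, d_cut = 10, epsilon = 1e-5,
                          sigma = NULL) {
  if (!(cutoff > 0 && cutoff < d_cut))
    stop("need 0 < cutoff < d_cut", call. = FALSE)
  if (!(epsilon > 0 && epsilon < 1))
    stop("epsilon must lie in (0, 1)", call. = FALSE)
  if (is.null(sigma)) sigma <- sigma_from_constraint(cutoff, d_cut, epsilon)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  structure(list(cutoff = cutoff, d_cut = d_cut, epsilon = epsilon,
                 sigma = sigma), class = "kernel_params")
}

#' @rdname kernel_params
#' @export
sigma_from_constraint <- function(cutoff = 7, d_cut = 10, epsilon = 1e-5) {
  (d_cut - cutoff) / sqrt(-2 * log(epsilon))
}

#' Evaluate the contact kernel
#'
#' @param d Distances (A), vectorized.
#' @param params A [kernel_params()].
#' @return Kernel values in \[0, 1\].
#' @export
contact_kernel <- function(d, params = kernel_params()) {
  stopifnot(all(d >= 0))
  k <- exp(-(d - params$cutoff)^2 / (2 * params$sigma^2))
  k[d <= params$cutoff] <- 1
  k[d >= params$d_cut] <- 0
  k
}

#' Frame-averaged contact map
#'
#' Computes C_ij as the average over frames of the contact kernel evaluated
#' at the inter-anchor distance d_ij(t) (CA for residues, fragment COM for
#' ligand nodes). The diagonal is 1.
#'
#' @param series A `node_series`, or a frames x nodes x 3 anchor array.
#' @param params A [kernel_params()].
#' @return Symmetric nodes x nodes matrix in \[0, 1\] with attribute
#'   `params`.
#' @export
contact_map <- function(series, params = kernel_params()) {
  anchor <- if (inherits(series, "node_series")) series$anchor else series
  stopifnot(length(dim(anchor)) == 3)
  nf <- dim(anchor)[1]; nn <- dim(anchor)[2]
  if (nf < 1) stop("need at least one frame", call. = FALSE)
  if (nn < 2) stop("need at least two nodes", call. = FALSE)
  C <- matrix(0, nn, nn)
  for (f in seq_len(nf)) {
    D <- as.matrix(dist(anchor[f, , ]))
    C <- C + contact_kernel(D, params)
  }
  C <- C / nf
  diag(C) <- 1
  dimnames(C) <- dimnames(anchor)[c(2, 2)]
  attr(C, "params") <- params
  C
}

#' Mutual-information estimator settings
#'
#' @param method `"histogram"` (discrete Shannon entropies; default) or
#'   `"gaussian"` (parametric, closed-form from correlations; useful for
#'   closed-form validation).
#' @param bins Histogram bins per dimension.
#' @param range_sd Half-width of the binning range in SD units; samples
#'   beyond it are clamped into the edge bins.
#' @param correction Apply the Miller--Madow bias correction to each
#'   histogram entropy.
#' @param dims `"sum"` (default): estimate MI per coordinate dimension with
#'   2-D joint histograms and sum over x/y/z (exact when dimensions are
#'   independent, and well-sampled at typical frame counts); `"joint"`: bin
#'   the full 3-D vectors (B^3 marginal, B^6 joint cells — requires far more
#'   frames than bins^6 to be meaningful).
#' @param min_frames Minimum series length accepted.
#' @return An object of class `mi_settings`.
#' @export
mi_settings <- function(method = c("histogram", "gaussian"), bins = 16L,
                        range_sd = 3, correction = TRUE,
                        dims = c("sum", "joint"), min_frames = 100L) {
  structure(list(method = match.arg(method), bins = as.integer(bins),
                 range_sd = range_sd, correction = correction,
                 dims = match.arg(dims), min_frames = as.integer(min_frames)),
            class = "mi_settings")
}

bin_index <- function(x, bins, range_sd) {
  s <- sd(x)
  if (s == 0) return(rep(0L, length(x)))
  w <- 2 * range_sd * s / bins
  pmin(pmax(floor((x - mean(x) + range_sd * s) / w), 0L), bins - 1L)
}

entropy_counts <- function(codes, ncells, n, correction) {
  cnt <- tabulate(codes + 1L, ncells)
  p <- cnt[cnt > 0] / n
  h <- -sum(p * log(p))
  if (correction) h <- h + (sum(cnt > 0) - 1) / (2 * n)
  h
}

#' Mutual information between two displacement series
#'
#' Estimates the mutual information M (nats) between two per-frame
#' displacement vectors, the marginal and joint Shannon entropies, and the
#' normalized mutual information `M_hat = M / H_ij`, clipped to \[0, 1\].
#' With the histogram estimator the identity `M = H_i + H_j - H_ij` holds
#' exactly by construction. Degenerate (zero-variance) series yield
#' `M_hat = 0` with a warning.
#'
#' @param di,dj Numeric matrices, frames x d (d = 3 for displacement
#'   vectors; 1-column input gives per-dimension MI).
#' @param settings An [mi_settings()].
#' @return List with `M`, `H_i`, `H_j`, `H_ij`, `M_hat`.
#' @export
mutual_information <- function(di, dj, settings = mi_settings()) {
  di <- as.matrix(di); dj <- as.matrix(dj)
  if (nrow(di) != nrow(dj)) stop("series lengths differ", call. = FALSE)
  if (nrow(di) < settings$min_frames)
    stop("series shorter than min_frames = ", settings$min_frames,
         call. = FALSE)
  sds_i <- apply(di, 2, sd); sds_j <- apply(dj, 2, sd)
  if (all(sds_i == 0) || all(sds_j == 0)) {
    warning("zero-variance node; M_hat defined as 0")
    return(list(M = 0, H_i = 0, H_j = 0, H_ij = 0, M_hat = 0))
  }
  out <- if (settings$method == "gaussian") mi_gaussian(di, dj)
         else mi_histogram(di, dj, settings)
  out$M_hat <- if (out$H_ij > 0) min(max(out$M / out$H_ij, 0), 1) else 0
  out
}

mi_histogram <- function(di, dj, st) {
  n <- nrow(di); B <- st$bins
  if (st$dims == "sum") {
    M <- H_i <- H_j <- H_ij <- 0
    for (k in seq_len(ncol(di))) {
      if (sd(di[, k]) == 0 || sd(dj[, k]) == 0) next
      bi <- bin_index(di[, k], B, st$range_sd)
      bj <- bin_index(dj[, k], B, st$range_sd)
      hi <- entropy_counts(bi, B, n, st$correction)
      hj <- entropy_counts(bj, B, n, st$correction)
      hij <- entropy_counts(bi * B + bj, B * B, n, st$correction)
      H_i <- H_i + hi; H_j <- H_j + hj; H_ij <- H_ij + hij
      M <- M + (hi + hj - hij)
    }
  } else {
    d <- ncol(di)
    code <- function(x) {
      cd <- rep(0L, nrow(x))
      for (k in seq_len(d)) cd <- cd * B + bin_index(x[, k], B, st$range_sd)
      cd
    }
    ci <- code(di); cj <- code(dj)
    H_i <- entropy_counts(ci, B^d, n, st$correction)
    H_j <- entropy_counts(cj, B^d, n, st$correction)
    H_ij <- entropy_counts(ci * B^d + cj, B^(2 * d), n, st$correction)
    M <- H_i + H_j - H_ij
  }
  list(M = max(M, 0), H_i = H_i, H_j = H_j, H_ij = H_ij)
}

# Parametric estimator: treats each coordinate dimension as bivariate
# Gaussian; entropies are differential (nats), so H_ij can be <= 0 for
# narrow displacements and M_hat is then reported as 0.
mi_gaussian <- function(di, dj) {
  M <- H_i <- H_j <- H_ij <- 0
  for (k in seq_len(ncol(di))) {
    si <- sd(di[, k]); sj <- sd(dj[, k])
    if (si == 0 || sj == 0) next
    r <- min(max(cor(di[, k], dj[, k]), -1 + 1e-12), 1 - 1e-12)
    M <- M - 0.5 * log(1 - r^2)
    hi <- 0.5 * log(2 * pi * exp(1) * si^2)
    hj <- 0.5 * log(2 * pi * exp(1) * sj^2)
    H_i <- H_i + hi; H_j <- H_j + hj
    H_ij <- H_ij + hi + hj + 0.5 * log(1 - r^2)
  }
  list(M = M, H_i = H_i, H_j = H_j, H_ij = H_ij)
}

#' Pairwise mutual-information matrices for all nodes
#'
#' @param series A `node_series`.
#' @param settings An [mi_settings()].
#' @return List of symmetric matrices `M` (nats) and `M_hat` (normalized,
#'   diagonal 1), with node ids as dimnames.
#' @export
mi_matrix <- function(series, settings = mi_settings()) {
  stopifnot(inherits(series, "node_series"))
  nn <- nrow(series$nodes); nf <- series$n_frames
  if (nf < settings$min_frames)
    stop("trajectory shorter than min_frames = ", settings$min_frames,
         call. = FALSE)
  M <- Mh <- diag(nn)
  if (settings$method == "histogram" && settings$dims == "sum") {
    B <- settings$bins
    idx <- lapply(seq_len(nn), function(i)
      lapply(1:3, function(k) {
        x <- series$disp[, i, k]
        if (sd(x) == 0) NULL else bin_index(x, B, settings$range_sd)
      }))
    Hm <- lapply(idx, function(bs) lapply(bs, function(b)
      if (is.null(b)) NULL
      else entropy_counts(b, B, nf, settings$correction)))
    degen <- vapply(idx, function(bs) all(vapply(bs, is.null, TRUE)), TRUE)
    if (any(degen)) warning("zero-variance node(s); M_hat set to 0: ",
                            paste(series$nodes$node_id[degen], collapse = ", "))
    for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
      if (degen[i] || degen[j]) next
      m <- hij <- 0
      for (k in 1:3) {
        bi <- idx[[i]][[k]]; bj <- idx[[j]][[k]]
        if (is.null(bi) || is.null(bj)) next
        h2 <- entropy_counts(bi * B + bj, B * B, nf, settings$correction)
        m <- m + Hm[[i]][[k]] + Hm[[j]][[k]] - h2
        hij <- hij + h2
      }
      M[i, j] <- M[j, i] <- max(m, 0)
      Mh[i, j] <- Mh[j, i] <- if (hij > 0) min(max(m / hij, 0), 1) else 0
    }
  } else {
    for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
      r <- suppressWarnings(
        mutual_information(series$disp[, i, ], series$disp[, j, ], settings))
      M[i, j] <- M[j, i] <- r$M
      Mh[i, j] <- Mh[j, i] <- r$M_hat
    }
  }
  dimnames(M) <- dimnames(Mh) <- list(series$nodes$node_id,
                                      series$nodes$node_id)
  list(M = M, M_hat = Mh, settings = settings)
}

#' Build the weighted allosteric network
#'
#' Combines the contact map and the normalized mutual information into an
#' undirected graph with edge weights `w_ij = -ln(C_ij * M_hat_ij)`. An edge
#' exists iff `C_ij * M_hat_ij > 0`; perfect coupling (C = M_hat = 1) gives
#' weight 0. Self-edges are excluded. Optionally, edges between
#' sequence-adjacent residues of the same chain can be masked.
#'
#' @param C Contact map from [contact_map()].
#' @param M_hat Normalized MI matrix from [mi_matrix()].
#' @param nodes Optional node table (from a `node_series`) enabling the
#'   adjacency mask.
#' @param exclude_adjacent Mask edges between residues of the same chain at
#'   most this many sequence positions apart (0 = keep all; default).
#' @return An `igraph` graph with `weight` edge attribute and provenance
#'   graph attributes.
#' @export
build_network <- function(C, M_hat, nodes = NULL, exclude_adjacent = 0L) {
  stopifnot(all(dim(C) == dim(M_hat)))
  A <- C * M_hat
  A[lower.tri(A, diag = TRUE)] <- 0
  keep <- which(A > 0, arr.ind = TRUE)
  ids <- rownames(C) %||% as.character(seq_len(nrow(C)))
  if (exclude_adjacent > 0L && !is.null(nodes)) {
    ii <- keep[, 1]; jj <- keep[, 2]
    same <- nodes$kind[ii] == "residue" & nodes$kind[jj] == "residue" &
      nodes$chain[ii] == nodes$chain[jj] &
      abs(nodes$resno[ii] - nodes$resno[jj]) <= exclude_adjacent
    keep <- keep[!same, , drop = FALSE]
  }
  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      weight = -log(A[keep]),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  kp <- attr(C, "params")
  if (!is.null(kp)) {
    g <- igraph::set_graph_attr(g, "kernel_cutoff", kp$cutoff)
    g <- igraph::set_graph_attr(g, "kernel_sigma", kp$sigma)
    g <- igraph::set_graph_attr(g, "kernel_d_cut", kp$d_cut)
  }
  igraph::set_graph_attr(g, "weight_def", "-ln(C_ij * M_hat_ij)")
}

#' Detect a source/sink region around a node
#'
#' Returns the nodes whose anchor lies within `radius` of the centre node's
#' anchor in at least `occupancy` of the frames (the sphere moves with the
#' centre node). The centre is always included.
#'
#' @param series A `node_series`.
#' @param center_node Node id of the sphere centre.
#' @param radius Sphere radius (A).
#' @param occupancy Minimum occupied fraction of frames.
#' @return Character vector of node ids.
#' @export
detect_region <- function(series, center_node, radius = 7,
                          occupancy = 0.70) {
  stopifnot(inherits(series, "node_series"))
  i <- match(center_node, series$nodes$node_id)
  if (is.na(i)) stop("unknown node: ", center_node, call. = FALSE)
  nf <- series$n_frames
  d2 <- 0
  for (k in 1:3) {
    A <- series$anchor[, , k, drop = FALSE]
    dim(A) <- dim(A)[1:2]
    d2 <- d2 + (A - A[, i])^2
  }
  frac <- colMeans(d2 <= radius^2)
  out <- series$nodes$node_id[frac >= occupancy]
  union(center_node, out)
}

#' Minimal source-to-sink path
#'
#' Dijkstra shortest paths over all (source, sink) pairs; `d_min` is the
#' smallest total edge weight found. All co-minimal paths (over all
#' achieving pairs) are reported; the lexicographically smallest node
#' sequence is designated `best_path` for determinism. Unreachable sinks
#' give `d_min = Inf` with `reachable = FALSE`.
#'
#' @param net Network from [build_network()].
#' @param source_set,sink_set Non-empty, disjoint character vectors of node
#'   ids.
#' @return An object of class `path_result`: `d_min`, `best_path`,
#'   `all_paths`, `source_set`, `sink_set`, `reachable`.
#' @export
min_path <- function(net, source_set, sink_set) {
  if (!length(source_set) || !length(sink_set))
    stop("source and sink sets must be non-empty", call. = FALSE)
  if (length(intersect(source_set, sink_set)))
    stop("source and sink sets must be disjoint", call. = FALSE)
  vn <- igraph::V(net)$name
  miss <- setdiff(c(source_set, sink_set), vn)
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  D <- igraph::distances(net, v = source_set, to = sink_set,
                         weights = igraph::E(net)$weight,
                         algorithm = "dijkstra")
  d_min <- min(D)
  if (!is.finite(d_min)) {
    return(structure(list(d_min = Inf, best_path = character(),
                          all_paths = list(), source_set = source_set,
                          sink_set = sink_set, reachable = FALSE),
                     class = "path_result"))
  }
  hits <- which(D <= d_min + 1e-12, arr.ind = TRUE)
  paths <- list()
  for (h in seq_len(nrow(hits))) {
    s <- source_set[hits[h, 1]]; t <- sink_set[hits[h, 2]]
    ap <- igraph::all_shortest_paths(net, from = s, to = t,
                                     weights = igraph::E(net)$weight)
    vp <- ap$vpaths %||% ap$res
    for (p in vp) paths[[length(paths) + 1L]] <- names(p)
  }
  paths <- unique(paths)
  keys <- vapply(paths, paste, "", collapse = "\r")
  best <- paths[[order(keys)[1]]]
  structure(list(d_min = d_min, best_path = best, all_paths = paths,
                 source_set = source_set, sink_set = sink_set,
                 reachable = TRUE),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$reachable) cat("path_result: sink unreachable (d_min = Inf)\n")
  else cat(sprintf("path_result: d_min = %.4f via %s (%d co-minimal)\n",
                   x$d_min, paste(x$best_path, collapse = " -> "),
                   length(x$all_paths)))
  invisible(x)
}

#' Weighted betweenness centrality
#'
#' Brandes betweenness over the weighted network (each unordered pair
#' counted once, endpoints excluded — the \pkg{igraph} undirected
#' convention, recorded in the result's `convention` attribute).
#'
#' @param net Network from [build_network()].
#' @param normalized Divide by the number of ordered pairs
#'   `(n - 1)(n - 2) / 2`.
#' @return Named numeric vector of per-node centralities.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  b <- igraph::betweenness(net, directed = FALSE,
                           weights = igraph::E(net)$weight,
                           normalized = normalized)
  attr(b, "convention") <-
    "Brandes; undirected, pairs counted once, endpoints excluded"
  b
}
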