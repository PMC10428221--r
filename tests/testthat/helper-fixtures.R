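# Shared fixtures and independent oracles for the test suite.

# Small synthetic channel trajectory used across tests.
make_toy_system <- function(n_frames = 500, seed = 1, rho_path = 0.9,
                            path_nodes = 2:9, ligand = FALSE,
                            glycine_at = integer(), n_subunits = 4L,
                            residues_per_subunit = 10L) {
  spec <- toy_channel_spec(n_subunits = n_subunits,
                           residues_per_subunit = residues_per_subunit,
                           glycine_at = glycine_at)
  ref <- generate_toy_channel(spec, ligand = ligand)
  cov <- planted_covariance(path_nodes = path_nodes, rho_path = rho_path)
  generate_trajectory(ref, cov, n_frames = n_frames, seed = seed)
}

toy_ligand_map <- function() {
  list(frag1 = paste0("C", 1:3), frag2 = paste0("C", 4:6),
       frag3 = paste0("C", 7:9))
}

# --- brute-force graph oracles (independent of igraph) ---------------------

# Enumerate all simple paths between two nodes of a weighted edge list.
# edges: data.frame(from, to, weight), undirected.
enumerate_simple_paths <- function(edges, from, to) {
  adj <- list()
  add <- function(a, b, w) {
    adj[[a]] <<- rbind(adj[[a]], data.frame(nb = b, w = w))
  }
  for (i in seq_len(nrow(edges))) {
    add(edges$from[i], edges$to[i], edges$weight[i])
    add(edges$to[i], edges$from[i], edges$weight[i])
  }
  paths <- list()
  walk <- function(node, visited, w) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- list(path = visited, weight = w)
      return(invisible())
    }
    nbs <- adj[[node]]
    if (is.null(nbs)) return(invisible())
    for (i in seq_len(nrow(nbs))) {
      nb <- nbs$nb[i]
      if (nb %in% visited) next
      walk(nb, c(visited, nb), w + nbs$w[i])
    }
  }
  walk(from, from, 0)
  paths
}

brute_force_dmin <- function(edges, sources, sinks) {
  best <- Inf; best_paths <- list()
  for (s in sources) for (t in sinks) {
    for (p in enumerate_simple_paths(edges, s, t)) {
      if (p$weight < best - 1e-12) {
        best <- p$weight; best_paths <- list(p$path)
      } else if (abs(p$weight - best) <= 1e-12) {
        best_paths <- c(best_paths, list(p$path))
      }
    }
  }
  list(d_min = best, paths = unique(best_paths))
}

# Brandes-convention betweenness by exhaustive enumeration: for each
# unordered pair, count the fraction of minimum-weight simple paths passing
# through each interior node.
brute_force_betweenness <- function(edges, nodes) {
  b <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    ps <- enumerate_simple_paths(edges, nodes[i], nodes[j])
    if (!length(ps)) next
    w <- vapply(ps, `[[`, 0, "weight")
    sp <- ps[abs(w - min(w)) <= 1e-12]
    for (p in sp) {
      interior <- setdiff(p$path, c(nodes[i], nodes[j]))
      b[interior] <- b[interior] + 1 / length(sp)
    }
  }
  b
}

# Random connected weighted graph for oracle-equivalence checks.
random_graph_edges <- function(n_nodes, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  nodes <- letters[seq_len(n_nodes)]
  edges <- NULL
  for (i in seq_len(n_nodes - 1)) {
    # spanning chain guarantees connectivity
    edges <- rbind(edges, data.frame(from = nodes[i], to = nodes[i + 1],
                                     weight = round(runif(1, 0.5, 4), 3)))
  }
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (j <= i + 1) next
    if (runif(1) < p_edge)
      edges <- rbind(edges, data.frame(from = nodes[i], to = nodes[j],
                                       weight = round(runif(1, 0.5, 4), 3)))
  }
  edges
}

graph_from_edges <- function(edges) {
  igraph::graph_from_data_frame(edges, directed = FALSE)
}
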