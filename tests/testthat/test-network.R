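test_that("contact kernel matches its piecewise definition", {
  p <- kernel_params()   # c = 7, d_cut = 10, epsilon = 1e-5
  expect_equal(p$sigma, 0.6252, tolerance = 1e-4)
  expect_equal(contact_kernel(5, p), 1)
  expect_equal(contact_kernel(7, p), 1)
  expect_equal(contact_kernel(10, p), 0)   # hard truncation at d_cut
  expect_equal(contact_kernel(10 - 1e-9, p), 1e-5, tolerance = 1e-3)
  expect_equal(contact_kernel(25, p), 0)
  # a supplied sigma (e.g. a broader literature value) is accepted as-is
  p2 <- kernel_params(sigma = 1.48)
  expect_equal(contact_kernel(8, p2),
               exp(-(8 - 7)^2 / (2 * 1.48^2)))
  expect_error(kernel_params(cutoff = 11), "cutoff")
})

test_that("contact map is the frame average of the kernel", {
  # two nodes: in contact (4 A) in 50 frames, far (>= d_cut) in 50
  anchor <- array(0, c(100, 2, 3))
  anchor[, 2, 1] <- c(rep(4, 50), rep(15, 50))
  C <- contact_map(anchor, kernel_params())
  expect_equal(C[1, 2], 0.5)
  expect_equal(C[2, 1], 0.5)
  expect_equal(diag(C), c(1, 1))
  # permanently touching pair
  anchor[, 2, 1] <- 4
  expect_equal(contact_map(anchor)[1, 2], 1)
  expect_error(contact_map(array(0, c(0, 2, 3))), "frame")
})

test_that("mutual information obeys identity, null and closed form", {
  set.seed(20)
  n <- 2000
  x <- matrix(rnorm(3 * n), n)
  # identical non-degenerate series: M_hat = 1 (H_i = H_ij)
  r <- mutual_information(x, x)
  expect_equal(r$M_hat, 1)
  expect_equal(r$M, r$H_i + r$H_j - r$H_ij)
  # independent series: estimate below the permutation-null 95th percentile
  y <- matrix(rnorm(3 * n), n)
  obs <- mutual_information(x, y)$M
  null <- replicate(40, mutual_information(x, y[sample(n), ])$M)
  expect_lt(obs, quantile(null, 0.95) + 1e-9)
  # zero-variance series
  expect_warning(r0 <- mutual_information(x, matrix(0, n, 3)), "zero-variance")
  expect_equal(r0$M_hat, 0)
  expect_error(mutual_information(x[1:50, ], y[1:50, ]), "min_frames")
})

test_that("joint-vector binning agrees with the per-dimension sum where exact", {
  set.seed(22)
  n <- 4000
  # 1-D input: "sum" and "joint" are the same computation
  x <- cbind(rnorm(n)); y <- cbind(0.8 * x[, 1] + 0.6 * rnorm(n))
  s_sum <- mutual_information(x, y, mi_settings(bins = 8, dims = "sum"))
  s_joint <- mutual_information(x, y, mi_settings(bins = 8, dims = "joint"))
  expect_equal(s_sum$M, s_joint$M)
  expect_equal(s_sum$H_ij, s_joint$H_ij)
  # multi-D joint estimator still satisfies the entropy identity
  x3 <- matrix(rnorm(3 * n), n); y3 <- matrix(rnorm(3 * n), n)
  r <- mutual_information(x3, y3, mi_settings(bins = 4, dims = "joint",
                                              correction = FALSE))
  expect_gte(r$M, 0)
  expect_equal(r$M, r$H_i + r$H_j - r$H_ij)
})

test_that("gaussian estimator matches the bivariate closed form", {
  set.seed(21)
  n <- 5000
  for (rho in c(0.5, 0.9)) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r <- mutual_information(cbind(x), cbind(y),
                            mi_settings(method = "gaussian"))
    expect_equal(r$M, -0.5 * log(1 - rho^2), tolerance = 0.05)
  }
})

test_that("network weights follow -ln(C * M_hat) with edges only on coupling", {
  C <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  Mh <- matrix(c(1, exp(-2), 0.5, exp(-2), 1, 0, 0.5, 0, 1), 3, 3,
               dimnames = dimnames(C))
  net <- build_network(C, Mh)
  w <- igraph::E(net)$weight
  ends <- igraph::as_data_frame(net)
  expect_equal(nrow(ends), 1)            # b-c has M_hat = 0; a-c has C = 0
  expect_equal(ends$from, "a"); expect_equal(ends$to, "b")
  expect_equal(w, 2)                     # -ln(1 * e^-2)
  # perfect coupling gives weight 0 but the edge still exists
  Mh2 <- Mh; Mh2[1, 2] <- Mh2[2, 1] <- 1
  net2 <- build_network(C, Mh2)
  expect_equal(igraph::E(net2)$weight, 0)
  expect_equal(igraph::ecount(net2), 1)
})

test_that("sequence-adjacency mask removes bonded-neighbour edges", {
  sys <- make_toy_system(n_frames = 120, seed = 30, path_nodes = integer())
  ns <- extract_node_series(sys)
  C <- contact_map(ns)
  mi <- mi_matrix(ns)
  net0 <- build_network(C, mi$M_hat, nodes = ns$nodes)
  net1 <- build_network(C, mi$M_hat, nodes = ns$nodes,
                        exclude_adjacent = 1L)
  d0 <- igraph::as_data_frame(net0); d1 <- igraph::as_data_frame(net1)
  adj <- function(df) {
    a <- do.call(rbind, strsplit(df$from, ":"))
    b <- do.call(rbind, strsplit(df$to, ":"))
    sum(a[, 1] == b[, 1] &
          abs(as.integer(a[, 2]) - as.integer(b[, 2])) <= 1)
  }
  expect_gt(adj(d0), 0)
  expect_equal(adj(d1), 0)
  expect_lt(igraph::ecount(net1), igraph::ecount(net0))
})

test_that("region detection applies the occupancy rule", {
  # center fixed at origin; nodes at controlled distances
  nf <- 100
  anchor <- array(0, c(nf, 4, 3))
  anchor[, 2, 1] <- 5                                 # always inside 7 A
  anchor[, 3, 1] <- c(rep(5, 60), rep(20, 40))        # inside 60% of frames
  anchor[, 4, 1] <- 30                                # never inside
  nodes <- data.frame(node_id = c("c", "in", "part", "out"),
                      kind = "residue", chain = "A", resno = 1:4,
                      resname = "LEU")
  ns <- structure(list(nodes = nodes, anchor = anchor,
                       disp = anchor, n_frames = nf),
                  class = "node_series")
  expect_setequal(detect_region(ns, "c", 7, 0.70), c("c", "in"))
  expect_setequal(detect_region(ns, "c", 7, 0.60), c("c", "in", "part"))
  expect_equal(detect_region(ns, "c", 0, 0.70), "c")  # degenerate radius
  expect_error(detect_region(ns, "nope"), "unknown")
})

test_that("min_path matches brute-force enumeration on a printed graph", {
  edges <- data.frame(
    from = c("s", "s", "a", "a", "b", "c", "d"),
    to   = c("a", "b", "b", "c", "d", "t", "t"),
    weight = c(1.0, 2.5, 0.5, 2.0, 1.0, 1.2, 2.0))
  net <- graph_from_edges(edges)
  pr <- min_path(net, "s", "t")
  oracle <- brute_force_dmin(edges, "s", "t")
  expect_equal(pr$d_min, oracle$d_min)
  expect_equal(pr$d_min, 4.2)            # s-a-c-t = 1.0 + 2.0 + 1.2
  expect_true(list(pr$best_path) %in% oracle$paths ||
                identical(pr$best_path, oracle$paths[[1]]))
  # single edge
  net1 <- graph_from_edges(data.frame(from = "s", to = "t", weight = 3))
  pr1 <- min_path(net1, "s", "t")
  expect_equal(pr1$d_min, 3)
  expect_equal(pr1$best_path, c("s", "t"))
  # unreachable sink
  edges2 <- rbind(edges, data.frame(from = "u", to = "v", weight = 1))
  pr2 <- min_path(graph_from_edges(edges2), "s", "v")
  expect_false(pr2$reachable)
  expect_equal(pr2$d_min, Inf)
  expect_error(min_path(net, character(), "t"), "non-empty")
  expect_error(min_path(net, "s", "s"), "disjoint")
})

test_that("co-minimal ties are all reported with deterministic best path", {
  edges <- data.frame(from = c("s", "s", "a", "b"),
                      to   = c("a", "b", "t", "t"),
                      weight = c(1, 1, 1, 1))
  pr <- min_path(graph_from_edges(edges), "s", "t")
  expect_equal(length(pr$all_paths), 2)
  expect_equal(pr$best_path, c("s", "a", "t"))   # lexicographically first
})

test_that("betweenness matches closed forms and brute force", {
  # path graph a-b-c: b carries the single a..c shortest path
  pathg <- graph_from_edges(data.frame(from = c("a", "b"), to = c("b", "c"),
                                       weight = 1))
  b <- betweenness_centrality(pathg)
  expect_equal(as.numeric(b[c("a", "b", "c")]), c(0, 1, 0))
  # star graph: hub carries all leaf pairs
  star <- graph_from_edges(data.frame(from = "h", to = c("l1", "l2", "l3"),
                                      weight = 1))
  bs <- betweenness_centrality(star)
  expect_equal(as.numeric(bs["h"]), 3)   # choose(3, 2) leaf pairs
  expect_true(all(bs[c("l1", "l2", "l3")] == 0))
  # random 8-node weighted graph vs exhaustive enumeration
  edges <- random_graph_edges(8, p_edge = 0.4, seed = 17)
  net <- graph_from_edges(edges)
  oracle <- brute_force_betweenness(edges, igraph::V(net)$name)
  got <- betweenness_centrality(net)
  expect_equal(as.numeric(got[names(oracle)]), as.numeric(oracle),
               tolerance = 1e-10)
})
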