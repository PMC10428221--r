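test_that("contact fractions equal brute-force per-frame counting", {
  sys <- make_toy_system(n_frames = 100, seed = 16, ligand = TRUE)
  cf <- contact_fractions(sys, cutoff = 4.5)
  expect_true(all(cf$fraction >= 0 & cf$fraction <= 1))
  # brute-force oracle on a handful of residues
  a <- sys$pdb$atom
  lig <- which(a$resid == "LIG")
  cols <- function(ix) as.integer(rbind(3 * ix - 2, 3 * ix - 1, 3 * ix))
  for (rid in c("A:5", "B:5", "C:1")) {
    ch <- sub(":.*", "", rid); rn <- as.integer(sub(".*:", "", rid))
    sc <- which(a$chain == ch & a$resno == rn & a$elety %in% c("CB", "CG"))
    hits <- vapply(seq_len(nrow(sys$xyz)), function(f) {
      pl <- matrix(sys$xyz[f, cols(lig)], ncol = 3, byrow = TRUE)
      ps <- matrix(sys$xyz[f, cols(sc)], ncol = 3, byrow = TRUE)
      min(as.matrix(dist(rbind(ps, pl)))[seq_len(nrow(ps)),
                                         nrow(ps) + seq_len(nrow(pl))]) <= 4.5
    }, TRUE)
    expect_equal(cf$fraction[cf$node_id == rid], mean(hits))
  }
  expect_error(contact_fractions(make_toy_system(n_frames = 20, seed = 16)),
               "no ligand")
})

test_that("contact fractions hit exact endpoints for fixed geometries", {
  # one residue 3 A from the ligand, one 30 A away, static frames
  ref <- generate_toy_channel(toy_channel_spec(1, 4), ligand = TRUE)
  xyz <- matrix(rep(as.numeric(ref$xyz[1, ]), 10), nrow = 10, byrow = TRUE)
  a <- ref$atom
  lig1 <- which(a$elety == "C1")
  cb1 <- which(a$chain == "A" & a$resno == 1 & a$elety == "CB")
  # move residue 1's side chain to 3 A from ligand atom C1
  xyz[, (3 * cb1 - 2):(3 * cb1)] <-
    rep(xyz[1, (3 * lig1 - 2):(3 * lig1)] + c(3, 0, 0), each = 10)
  cg1 <- which(a$chain == "A" & a$resno == 1 & a$elety == "CG")
  xyz[, (3 * cg1 - 2):(3 * cg1)] <-
    rep(xyz[1, (3 * lig1 - 2):(3 * lig1)] + c(3, 0.5, 0), each = 10)
  sys <- load_system(ref, xyz)
  cf <- contact_fractions(sys, cutoff = 4.5)
  expect_equal(cf$fraction[cf$node_id == "A:1"], 1)
  # in contact 30 of 100 frames
  xyz2 <- matrix(rep(as.numeric(ref$xyz[1, ]), 100), nrow = 100,
                 byrow = TRUE)
  near <- xyz2[1, (3 * lig1 - 2):(3 * lig1)] + c(3, 0, 0)
  far <- near + c(30, 0, 0)
  xyz2[, (3 * cb1 - 2):(3 * cb1)] <- t(replicate(100, far))
  xyz2[, (3 * cg1 - 2):(3 * cg1)] <- t(replicate(100, far + c(0, 0.5, 0)))
  xyz2[1:30, (3 * cb1 - 2):(3 * cb1)] <- t(replicate(30, near))
  cf2 <- contact_fractions(load_system(ref, xyz2), cutoff = 4.5)
  expect_equal(cf2$fraction[cf2$node_id == "A:1"], 0.30)
})

test_that("pore integrity reports diagonal distances and their spread", {
  # square arrangement: 4 subunits at bundle radius r -> diagonal 2r
  spec <- toy_channel_spec(n_subunits = 4, residues_per_subunit = 3,
                           bundle_radius = 5)
  ref <- generate_toy_channel(spec)
  sys <- load_system(ref, matrix(rep(as.numeric(ref$xyz[1, ]), 5),
                                 nrow = 5, byrow = TRUE))
  pi0 <- pore_integrity(sys, marker_resno = 2)
  expect_equal(length(pi0$pairs), 2)
  expect_equal(unname(pi0$mean), c(10, 10), tolerance = 1e-10)
  expect_equal(unname(pi0$sd), c(0, 0))
  # synthetic dilation: distances increase monotonically over frames
  nf <- 20
  xyz <- matrix(rep(as.numeric(ref$xyz[1, ]), nf), nrow = nf, byrow = TRUE)
  for (f in seq_len(nf)) {
    scale <- 1 + 0.02 * (f - 1)
    M <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
    M[, 1:2] <- M[, 1:2] * scale
    xyz[f, ] <- as.numeric(t(M))
  }
  pid <- pore_integrity(load_system(ref, xyz), marker_resno = 2)
  expect_true(all(diff(pid$distances[, 1]) > 0))
  expect_true(all(diff(pid$distances[, 2]) > 0))
  expect_error(pore_integrity(sys, marker_resno = 99), "marker")
  odd <- load_system(generate_toy_channel(toy_channel_spec(3, 3)), NULL)
  expect_error(pore_integrity(odd, 2), "even")
})

test_that("pipeline runs end-to-end, deterministically, from a config", {
  dir <- withr::local_tempdir()
  # pose table fixture on disk
  pm <- planted_pose_model(modes = list(
    list(center = matrix(0, 4, 3), energy = -9, n_poses = 10,
         spread_sd = 0.2),
    list(center = matrix(7, 4, 3), energy = -8, n_poses = 30,
         spread_sd = 0.2)))
  write_pose_table(generate_pose_ensemble(pm, seed = 6),
                   file.path(dir, "poses.tsv"))
  cfg <- list(
    output_dir = file.path(dir, "out"),
    seed = 7,
    simulate = list(n_subunits = 4, residues_per_subunit = 6,
                    n_frames = 120, path_nodes = 2:5, rho_path = 0.9,
                    ligand = TRUE),
    ligand_map = toy_ligand_map(),
    network = list(mi = list(bins = 8),
                   source = list(center = "A:2"),
                   sink = list(center = "A:5")),
    cluster = list(k = 2),
    rescore = list(poses = file.path(dir, "poses.tsv")),
    contacts = list(cutoff = 4.5))
  res <- suppressWarnings(run_pipeline(cfg))
  out <- cfg$output_dir
  expected <- c("contact_map.csv", "mi_normalized.csv", "network_edges.tsv",
                "network.graphml", "path_result.json", "betweenness.csv",
                "cluster_assignments.csv", "cluster_populations.json",
                "rescored_clusters.csv", "contact_fractions.csv",
                "manifest.json")
  expect_true(all(file.exists(file.path(out, expected))))
  expect_true(res$path$reachable)
  # deterministic rerun: identical checksums for every artefact
  cfg2 <- cfg; cfg2$output_dir <- file.path(dir, "out2")
  res2 <- suppressWarnings(run_pipeline(cfg2))
  for (f in setdiff(expected, "manifest.json"))
    expect_equal(unname(tools::md5sum(file.path(out, f))),
                 unname(tools::md5sum(file.path(cfg2$output_dir, f))),
                 label = f)
  # schema errors name the missing field; stage errors are tagged
  expect_error(run_pipeline(list(seed = 1)), "output_dir")
  bad <- list(output_dir = file.path(dir, "o3"),
              rescore = list(poses = file.path(dir, "nope.tsv")))
  expect_error(run_pipeline(bad), "\\[stage rescore\\].*not found")
})
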