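test_that("ligand state enumeration yields 8 states, 4 retained", {
  st <- enumerate_ligand_states()
  expect_equal(nrow(st$full), 8)
  expect_equal(nrow(st$retained), 4)
  expect_setequal(st$retained$state_id,
                  c("Z(eea)", "Z(eae)", "N(eea)", "N(eae)"))
  # positions 3 and 4 always opposite (syn relationship)
  expect_true(all(st$full$o3 != st$full$o4))
  # single protonation form: product arithmetic
  stZ <- enumerate_ligand_states(protonation_forms = "Z")
  expect_equal(nrow(stZ$full), 4)
  expect_equal(nrow(stZ$retained), 2)
})

test_that("leader clustering partitions poses with E_I = min member energy", {
  ctrA <- matrix(0, 6, 3); ctrB <- matrix(c(8, 0, 0), 6, 3, byrow = TRUE)
  pm <- planted_pose_model(modes = list(
    list(center = ctrA, energy = -9, n_poses = 25, spread_sd = 0.3),
    list(center = ctrB, energy = -7.5, n_poses = 75, spread_sd = 0.3)))
  poses <- generate_pose_ensemble(pm, seed = 8)
  cs <- cluster_poses(poses, rmsd_threshold = 2)
  expect_equal(nrow(cs$clusters), 2)
  # partition: every pose assigned exactly once, populations sum to 1
  expect_equal(sort(unique(cs$assignments)), 1:2)
  expect_equal(sum(cs$clusters$population), 1)
  # E_I equals the lowest member energy in every cluster
  for (I in 1:2)
    expect_equal(cs$clusters$energy[I],
                 min(poses$energy[cs$assignments == I]))
  # all poses within threshold of one another -> single cluster
  one <- generate_pose_ensemble(planted_pose_model(modes = list(
    list(center = ctrA, energy = -8, n_poses = 40, spread_sd = 0.2))),
    seed = 9)
  expect_equal(nrow(cluster_poses(one)$clusters), 1)
  expect_error(cluster_poses(poses[, -4]), "missing column")
})

test_that("MaxP is monotone in population and energy, matches direct formula", {
  mk <- function(P, E) data.frame(cluster = seq_along(P), n = P * 100,
                                  population = P, energy = E,
                                  seed_pose_id = seq_along(P))
  # equal energies: higher population first
  r1 <- maxp_score(mk(c(0.9, 0.1), c(-8, -8)))
  expect_equal(r1$cluster[1], 1)
  # equal populations: lower energy first
  r2 <- maxp_score(mk(c(0.5, 0.5), c(-8, -6)))
  expect_equal(r2$cluster[1], 1)
  expect_equal(r2$energy[1], -8)
  # hand-evaluated formula oracle
  kT <- 0.593
  r3 <- maxp_score(mk(c(0.2, 0.8), c(-9.0, -8.5)), kT = kT)
  direct <- c(0.2 * exp(9.0 / kT), 0.8 * exp(8.5 / kT))
  expect_equal(sort(r3$score_maxp, decreasing = TRUE),
               sort(direct, decreasing = TRUE))
  expect_equal(r3$cluster[1], which.max(direct))
  # additive form gives the identical ranking
  expect_equal(order(r3$g_maxp), order(-r3$score_maxp))
  expect_error(maxp_score(mk(c(0.5, 0.4), c(-8, -6))), "sum to 1")
})

test_that("E_AD4 and MaxP can disagree: singleton best energy vs large cluster", {
  ctrA <- matrix(0, 6, 3); ctrB <- matrix(c(9, 0, 0), 6, 3, byrow = TRUE)
  pm <- planted_pose_model(modes = list(
    list(center = ctrA, energy = -9.6, n_poses = 1, spread_sd = 0.05),
    list(center = ctrB, energy = -9.0, n_poses = 199, spread_sd = 0.3)),
    energy_jitter_sd = 0.01)
  poses <- generate_pose_ensemble(pm, seed = 12)
  ranked <- maxp_score(cluster_poses(poses))
  top_maxp <- ranked[ranked$rank_maxp == 1, ]
  top_energy <- ranked[ranked$rank_energy == 1, ]
  expect_gt(top_maxp$population, 0.9)
  expect_lt(top_energy$population, 0.01)
  expect_false(top_maxp$cluster == top_energy$cluster)
})

test_that("MaxP-prime weighs receptor populations as specified", {
  mkset <- function(J) {
    ctr <- matrix(0, 4, 3)
    pm <- planted_pose_model(modes = list(
      list(center = ctr, energy = -8, n_poses = 20, spread_sd = 0.2)),
      receptor_cluster = J)
    cluster_poses(generate_pose_ensemble(pm, seed = 21))
  }
  sets <- list(mkset("3"), mkset("7"))
  # identical pose clusters; populations 17.3% vs 5.6%: higher P_J first
  r <- maxp_prime_score(sets, c("3" = 0.173 / 0.229, "7" = 0.056 / 0.229))
  expect_equal(as.character(r$receptor_cluster[1]), "3")
  expect_equal(r$score_maxp_prime,
               r$p_receptor * r$population * exp(-r$energy / 0.593))
  # single receptor cluster with P_J = 1: MaxP' == MaxP
  r1 <- maxp_prime_score(sets[1], c("3" = 1))
  expect_equal(r1$score_maxp_prime, r1$score_maxp)
  expect_error(maxp_prime_score(sets, c("3" = 0.6, "7" = 0.3)), "sum to 1")
  expect_error(maxp_prime_score(sets, c("3" = 0.6, "9" = 0.4)),
               "missing receptor population")
})

test_that("uniform receptor populations preserve the MaxP order", {
  ctrA <- matrix(0, 4, 3); ctrB <- matrix(c(7, 0, 0), 4, 3, byrow = TRUE)
  mkset <- function(J, seed) {
    pm <- planted_pose_model(modes = list(
      list(center = ctrA, energy = -9, n_poses = 30, spread_sd = 0.2),
      list(center = ctrB, energy = -8, n_poses = 70, spread_sd = 0.2)),
      receptor_cluster = J)
    cluster_poses(generate_pose_ensemble(pm, seed = seed))
  }
  sets <- list(mkset("1", 31), mkset("2", 31))
  rp <- maxp_prime_score(sets, c("1" = 0.5, "2" = 0.5))
  within1 <- rp[rp$receptor_cluster == "1", ]
  expect_equal(order(-within1$score_maxp_prime), order(-within1$score_maxp))
})

test_that("pose tables round-trip and full-table rescoring pools groups", {
  ctr <- matrix(0, 4, 3)
  tabs <- lapply(c("Z(eae)", "N(eea)"), function(st) {
    pm <- planted_pose_model(modes = list(
      list(center = ctr, energy = -8, n_poses = 10, spread_sd = 0.2),
      list(center = ctr + 8, energy = -7, n_poses = 10, spread_sd = 0.2)),
      ligand_state = st)
    generate_pose_ensemble(pm, seed = 41)
  })
  poses <- do.call(rbind, tabs)
  poses$pose_id <- seq_len(nrow(poses))
  f <- file.path(withr::local_tempdir(), "poses.tsv")
  write_pose_table(poses, f)
  back <- read_pose_table(f)
  expect_equal(back$energy, poses$energy)
  ranked <- rescore_pose_table(back)
  expect_equal(nrow(ranked), 4)          # 2 states x 2 clusters
  # populations refer to the per-state pose totals
  expect_true(all(abs(tapply(ranked$population, ranked$ligand_state, sum)
                      - 1) < 1e-12))
})
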