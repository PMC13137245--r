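test_that("Cremer-Pople puckering: planar ring, ideal chair, degenerate input", {
  expect_equal(unname(puckering(make_ring(pucker = 0))["q"]), 0)
  chair <- puckering(make_ring(pucker = 0.25))
  expect_true(abs(chair[["theta"]]) < 1e-6 || abs(chair[["theta"]] - 180) < 1e-6)
  expect_equal(chair[["q"]], sqrt(6 * 0.25^2), tolerance = 1e-8)
  collinear <- cbind(seq_len(6), 2 * seq_len(6), -seq_len(6))
  expect_error(puckering(collinear), "degenerate")
})

test_that("puckering is invariant under rigid motion", {
  set.seed(42)
  ring <- make_ring(pucker = 0.3) + matrix(rnorm(18, sd = 0.05), 6, 3)
  ref <- puckering(ring)
  for (i in 1:10) {
    moved <- rigid_motion(ring)
    expect_equal(puckering(moved), ref, tolerance = 1e-8)
  }
})

test_that("puckering under ring-index rotation follows the phase convention", {
  set.seed(7)
  ring <- make_ring(pucker = 0.3) + matrix(rnorm(18, sd = 0.05), 6, 3)
  ref <- puckering(ring)
  rot2 <- ring[c(3:6, 1:2), ]    # even index rotation
  p2 <- puckering(rot2)
  expect_equal(p2[["q"]], ref[["q"]], tolerance = 1e-8)
  expect_equal(p2[["theta"]], ref[["theta"]], tolerance = 1e-6)
  dphi <- (p2[["phi"]] - ref[["phi"]]) %% 120
  expect_lt(min(dphi, 120 - dphi), 1e-4)
  rot1 <- ring[c(2:6, 1), ]      # odd rotation flips the q3 hemisphere
  p1 <- puckering(rot1)
  expect_equal(p1[["q"]], ref[["q"]], tolerance = 1e-8)
  expect_equal(p1[["theta"]] + ref[["theta"]], 180, tolerance = 1e-6)
})

test_that("coordination number has the right limits and r0 continuity", {
  expect_equal(coordination_number(c(0, 0, 0), matrix(c(2.5, 0, 0), 1), 2.5, 6, 12), 0.5)
  expect_equal(coordination_number(c(0, 0, 0), matrix(c(1e-4, 0, 0), 1), 2.5, 6, 12), 1,
               tolerance = 1e-10)
  expect_lt(coordination_number(c(0, 0, 0), matrix(c(25, 0, 0), 1), 2.5, 6, 12), 1e-5)
  # continuity across r0
  lo <- coordination_number(c(0, 0, 0), matrix(c(2.5 - 1e-7, 0, 0), 1), 2.5, 6, 12)
  hi <- coordination_number(c(0, 0, 0), matrix(c(2.5 + 1e-7, 0, 0), 1), 2.5, 6, 12)
  expect_equal(lo, 0.5, tolerance = 1e-5)
  expect_equal(hi, 0.5, tolerance = 1e-5)
  # sums over several oxygens
  o3 <- rbind(c(1, 0, 0), c(0, 2.5, 0), c(0, 0, 30))
  expect_equal(coordination_number(c(0, 0, 0), o3, 2.5, 6, 12),
               coordination_number(c(0, 0, 0), o3[1, , drop = FALSE], 2.5, 6, 12) + 0.5,
               tolerance = 1e-5)
  expect_error(coordination_number(c(0, 0, 0), o3, 2.5, 12, 6))
})

test_that("USR descriptors match a direct re-evaluation and are rigid-motion invariant", {
  set.seed(13)
  for (i in 1:5) {
    cloud <- matrix(rnorm(60, sd = 2), 20, 3)
    expect_equal(usr_descriptors(cloud), oracle_usr(cloud), tolerance = 1e-10)
    expect_equal(usr_similarity(cloud, cloud), 1)
    moved <- rigid_motion(cloud)
    expect_gt(usr_similarity(cloud, moved), 1 - 1e-6)
    other <- matrix(rnorm(60, sd = 2), 20, 3)
    expect_equal(usr_similarity(cloud, other), oracle_usr_similarity(cloud, other),
                 tolerance = 1e-10)
  }
  expect_error(usr_descriptors(matrix(0, 3, 3)), "n >= 4")
})

test_that("deduplication keeps distinct conformers and drops duplicates", {
  set.seed(99)
  frames <- lapply(1:6, function(i) matrix(rnorm(36, sd = 2), 12, 3))
  frames[[4]] <- frames[[1]]  # exact duplicate, higher energy
  ens <- conformer_ensemble(rep("C", 12), frames, energy = c(1, 2, 3, 4, 5, 6))
  kept <- dedup(ens, threshold = 0.97)
  expect_false(4 %in% kept)
  expect_true(1 %in% kept)

  # all-distinct set at threshold 0.99: verified distinct by the oracle
  distinct <- lapply(1:5, function(i) matrix(rnorm(36, sd = 2 + i), 12, 3))
  sims <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    sims <- c(sims, oracle_usr_similarity(distinct[[i]], distinct[[j]]))
  }
  expect_true(all(sims < 0.99))
  ens2 <- conformer_ensemble(rep("C", 12), distinct, energy = 5:1)
  expect_equal(dedup(ens2, threshold = 0.99), 1:5)

  # a vanishing threshold keeps only the lowest-energy structure
  expect_equal(dedup(ens2, threshold = 1e-6), 5L)
})

test_that("candidate selection applies both criteria and recovers planted truth", {
  gen <- gen_ensemble(100, 30, seed = 1)
  sel <- select_candidates(gen$ensemble, gen$roles,
                           candidate_criteria(min_candidates = 30))
  expect_length(sel$indices, 30)
  expect_setequal(sel$indices, which(gen$truth$pass))
  expect_equal(sel$window, c(3.0, 3.5))
  expect_equal(nrow(sel$iterations), 1)

  # sodium 2.6 A from both donor and acceptor is excluded even with a
  # perfect donor-acceptor distance
  coords <- list(rbind(c(0, 0, 2.6), c(0, 0, 0), c(3.2, 0, 0), matrix(5, 9, 3)))
  ens1 <- conformer_ensemble(c("Na", "O", "O", rep("C", 9)), coords, 0)
  s1 <- select_candidates(ens1, list(na = 1, donor = 2, acceptor = 3),
                          candidate_criteria(min_candidates = 1))
  expect_length(s1$indices, 0)
})

test_that("the donor-acceptor window widens adaptively and is logged", {
  mk <- function(dd) rbind(c(0, 0, -2.0), c(0, 0, 0), c(dd, 0, 0), matrix(5, 9, 3))
  ens <- conformer_ensemble(c("Na", "O", "O", rep("C", 9)),
                            lapply(c(3.2, 3.8, 4.2, 7.0), mk), energy = 1:4)
  crit <- candidate_criteria(min_candidates = 3, widen_step = 0.5, dd_hard_max = 6)
  sel <- select_candidates(ens, list(na = 1, donor = 2, acceptor = 3), crit)
  expect_setequal(sel$indices, 1:3)
  expect_equal(sel$window[2], 4.5)
  expect_equal(sel$iterations$n_pass, c(1L, 2L, 3L))
  # widening never removes a previously passing structure
  for (i in seq_len(nrow(sel$iterations) - 1)) {
    expect_lte(sel$iterations$n_pass[i], sel$iterations$n_pass[i + 1])
  }
  # insufficient candidates even at the hard bound: all passing returned
  crit2 <- candidate_criteria(min_candidates = 2000, widen_step = 0.5, dd_hard_max = 6)
  sel2 <- select_candidates(ens, list(na = 1, donor = 2, acceptor = 3), crit2)
  expect_setequal(sel2$indices, 1:3)
  expect_equal(sel2$window[2], 6)
})
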