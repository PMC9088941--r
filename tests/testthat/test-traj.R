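test_that("superposed RMSD removes rigid motion and stays proper", {
  base <- matrix(rnorm(30, sd = 3), 10, 3)
  rot <- rotation_matrix(0.4, -1.1, 2.2)
  moved <- base %*% t(rot) + matrix(c(5, -3, 11), 10, 3, byrow = TRUE)
  tr <- toy_traj(list(base, moved))
  out <- rmsd_series(tr)
  expect_equal(out$rmsd[1], 0, tolerance = 1e-12)
  expect_lt(out$rmsd[2], 1e-9)

  # reflection trap: a mirror image must NOT superpose to zero
  mirrored <- base %*% diag(c(-1, 1, 1))
  k <- kabsch(mirrored, base)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_gt(k$rmsd, 0.1)
})

test_that("kabsch matches a brute-force rotation-grid search on 4-atom toys", {
  set.seed(5)
  for (i in 1:3) {
    a <- matrix(rnorm(12, sd = 2), 4, 3)
    b <- matrix(rnorm(12, sd = 2), 4, 3)
    oracle <- grid_rmsd_oracle(a, b)
    expect_equal(kabsch(a, b)$rmsd, oracle, tolerance = 1e-3)
    # oracle can never beat the analytic optimum
    expect_lte(kabsch(a, b)$rmsd, oracle + 1e-6)
  }
})

test_that("RMSF is zero for static trajectories and tracks jitter ratios", {
  still <- simulate_trajectory(traj_sim_spec(n_frames = 5, n_atoms = 8,
                                             jitter_sd = 0))
  expect_true(all(rmsf_per_residue(still)$rmsf < 1e-12))

  # doubling jitter on one residue doubles its RMSF (no superposition noise:
  # many anchor atoms keep the frame alignment stable)
  set.seed(31)
  n_at <- 40; n_fr <- 600
  base <- matrix(rnorm(n_at * 3, sd = 8), n_at, 3)
  frames <- lapply(seq_len(n_fr), function(f) {
    sdv <- rep(0.3, n_at); sdv[7] <- 0.6
    base + matrix(rnorm(n_at * 3, 0, rep(sdv, 3)), n_at, 3)
  })
  rf <- rmsf_per_residue(toy_traj(frames))
  ratio <- rf$rmsf[rf$resid == 7] / median(rf$rmsf[rf$resid != 7])
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("Gaussian jitter gives RMSF near sigma * sqrt(3)", {
  tr <- simulate_trajectory(traj_sim_spec(n_frames = 400, n_atoms = 50,
                                          jitter_sd = 0.5, seed = 12L))
  rf <- rmsf_per_residue(tr)
  expect_equal(mean(rf$rmsf), 0.5 * sqrt(3), tolerance = 0.08)
})

test_that("radius of gyration is analytic, rigid-invariant and homogeneous", {
  sq <- toy_traj(list(cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(0, 0, 0, 0))))
  expect_equal(radius_of_gyration(sq)$rg, sqrt(2), tolerance = 1e-14)

  base <- matrix(rnorm(24, sd = 4), 8, 3)
  rot <- rotation_matrix(1.2, 0.3, -0.7)
  tr <- toy_traj(list(base, base %*% t(rot) +
                        matrix(c(2, 9, -4), 8, 3, byrow = TRUE)))
  rg <- radius_of_gyration(tr)$rg
  expect_equal(rg[1], rg[2], tolerance = 1e-12)
  scaled <- toy_traj(list(base * 3))
  expect_equal(radius_of_gyration(scaled)$rg[1], rg[1] * 3, tolerance = 1e-12)
  # mass weighting shifts Rg when elements differ
  mixed <- toy_traj(list(base), element = c(rep("C", 4), rep("H", 4)))
  expect_false(isTRUE(all.equal(
    radius_of_gyration(mixed, mass_weighted = TRUE)$rg,
    radius_of_gyration(mixed)$rg)))
})

test_that("ligand-residue distances match exhaustive pair enumeration", {
  # 3-frame toy: 2-atom ligand + 2 residues of 2 atoms each
  set.seed(77)
  frames <- lapply(1:3, function(f) matrix(rnorm(18, sd = 5), 6, 3))
  lig <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  resid <- c(99, 99, 1, 1, 2, 2)
  tr <- toy_traj(frames, ligand = lig, resid = resid)
  out <- ligand_residue_distance(tr, resid = 2)
  oracle <- vapply(frames, function(m) {
    min(as.matrix(dist(m))[1:2, 5:6])
  }, numeric(1))
  expect_equal(out$series$distance, oracle, tolerance = 1e-12)
  expect_equal(out$mean, mean(oracle))
  expect_equal(out$min, min(oracle))
  expect_lte(out$min, out$mean)

  # coincident atoms give zero; two single atoms give the fixed distance
  co <- toy_traj(list(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))),
                 ligand = c(TRUE, FALSE, FALSE), resid = c(9, 3, 4))
  expect_equal(ligand_residue_distance(co, resid = 3)$min, 0)
  expect_error(ligand_residue_distance(co, resid = 42), "Available")
})

test_that("hydrogen-bond counting obeys the distance-angle criterion", {
  # linear O-H...O at 1.9 A, 180 degrees: one bond
  lin <- toy_traj(list(rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.86, 0, 0))),
                  element = c("O", "H", "O"), name = c("O1", "H1", "O2"))
  out <- hbond_count(lin, donors = name == "O1", acceptors = name == "O2")
  expect_equal(out$n_hbonds, 1L)
  # bent to 90 degrees: rejected at angle_min = 120
  bent <- toy_traj(list(rbind(c(0, 0, 0), c(0.96, 0, 0), c(0.96, 1.9, 0))),
                   element = c("O", "H", "O"), name = c("O1", "H1", "O2"))
  expect_equal(hbond_count(bent, donors = name == "O1",
                           acceptors = name == "O2")$n_hbonds, 0L)
  # donor with no attached hydrogen is an error naming the atom
  expect_error(hbond_count(lin, donors = name == "O2",
                           acceptors = name == "O1"), "without an attached")
})

test_that("hydrogen-bond counts match brute-force triple enumeration", {
  set.seed(13)
  # 5 donors (O, each with one H at ~0.96 A) and 5 acceptors in a 6 A box
  don <- matrix(runif(15, 0, 6), 5, 3)
  hyd <- don + matrix(rnorm(15, 0, 0.3), 5, 3)
  hyd <- don + 0.96 * (hyd - don) / sqrt(rowSums((hyd - don)^2))
  acc <- matrix(runif(15, 0, 6), 5, 3)
  xyz <- rbind(don, hyd, acc)
  tr <- toy_traj(list(xyz),
                 element = c(rep("O", 5), rep("H", 5), rep("N", 5)),
                 name = c(paste0("OD", 1:5), paste0("HD", 1:5),
                          paste0("NA", 1:5)))
  got <- hbond_count(tr, donors = element == "O", acceptors = element == "N",
                     d_max = 3.5, angle_min = 120)
  want <- hbond_oracle(xyz, 1:5, 6:10, 11:15, 3.5, 120)
  expect_equal(got$n_hbonds, want)
})

test_that("selection predicates and combined metrics behave", {
  tr <- simulate_trajectory(traj_sim_spec(n_frames = 6, n_atoms = 12,
                                          jitter_sd = 0.2, seed = 2L))
  expect_error(rmsd_series(tr, name == "CB"), "Empty")
  tm <- traj_metrics(tr)
  expect_setequal(unique(tm$metric), c("rmsd", "rg"))
  expect_equal(nrow(tm), 12)
  expect_true(all(tm$value[tm$metric == "rg"] > 0))
  expect_equal(tm$value[tm$metric == "rmsd"][1], 0, tolerance = 1e-12)
})
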