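# Structural metrics: superposition, Rg, RMSF, distances, salt bridges.

test_that("Kabsch superposition is exact on rigid copies and symmetric", {
  set.seed(7)
  A <- matrix(rnorm(24), ncol = 3)
  expect_equal(superpose(A, A)$rmsd, 0, tolerance = 1e-12)

  rt <- random_rigid(13)
  B <- A %*% rt$R + matrix(rt$t, nrow(A), 3, byrow = TRUE)
  sp <- superpose(A, B)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(sp$mobile_fitted, B, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  # symmetry and invariance to proper rigid transforms of either argument
  C <- B + 0.1 * matrix(rnorm(24), ncol = 3)
  expect_equal(superpose(A, C)$rmsd, superpose(C, A)$rmsd, tolerance = 1e-9)
  rt2 <- random_rigid(14)
  C2 <- C %*% rt2$R + matrix(rt2$t, nrow(C), 3, byrow = TRUE)
  expect_equal(superpose(A, C2)$rmsd, superpose(A, C)$rmsd, tolerance = 1e-9)

  expect_error(superpose(A[1:2, ], A[1:2, ]), "3 atoms")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition matches the brute-force rotation-grid oracle", {
  # 4-point asymmetric set, one atom displaced by 0.2 nm
  A <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 0.8), ncol = 3,
              byrow = TRUE)
  B <- A; B[4, ] <- B[4, ] + c(0, 0, 0.2)
  expect_equal(rmsd_raw(A, B), 0.2 / sqrt(4))
  opt <- superpose(A, B)$rmsd
  oracle <- brute_force_rmsd(A, B)
  expect_lte(opt, oracle + 1e-9)          # implementation is the optimum
  expect_lt(oracle - opt, 2e-3)           # oracle closes in at grid resolution
  expect_lte(opt, rmsd_raw(A, B))

  # larger random cases, against bio3d as an independent reference
  for (seed in c(1, 2)) {
    set.seed(seed)
    M <- matrix(rnorm(18), ncol = 3)
    N <- M %*% random_rigid(seed + 50)$R + 0.05 * matrix(rnorm(18), ncol = 3)
    ours <- superpose(M, N)$rmsd
    bf <- brute_force_rmsd(M, N)
    expect_lte(ours, bf + 1e-9)
    expect_lt(bf - ours, 2e-3)
    ref <- bio3d::rmsd(as.numeric(t(N)), as.numeric(t(M)), fit = TRUE)
    expect_lt(abs(ours - ref), 6e-4)  # bio3d rounds to 3 decimals
  }
})

test_that("radius of gyration matches closed forms", {
  # two unit masses 1 nm apart: Rg = d/2
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))), 0.5,
               tolerance = 1e-12)
  # single atom
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), ncol = 3)), 0)
  # ring of radius r: Rg = r
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  ring <- cbind(2 * cos(th), 2 * sin(th), 0)
  expect_equal(radius_of_gyration(ring), 2, tolerance = 1e-9)
  # uniform rod of length L: Rg = L/sqrt(12)
  L <- 3
  rod <- cbind(seq(-L / 2, L / 2, length.out = 20000), 0, 0)
  expect_equal(radius_of_gyration(rod), L / sqrt(12), tolerance = 1e-4)
  # mass weighting: zero-mass atoms do not contribute
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0), c(9, 9, 9)),
                                  masses = c(1, 1, 0)), 0.5)
  expect_error(radius_of_gyration(rbind(c(0, 0, 0)), masses = 0), "mass")
})

test_that("rmsd trace is zero on static trajectories and windows correctly", {
  tr <- gen_jitter_trajectory(n_frames = 24, n_res = 6, sigma = 0, seed = 1)
  rt <- rmsd_trace(tr, selection = "CA")
  expect_equal(rt$values, rep(0, 24), tolerance = 1e-12)
  # window contract: last 110 of 120 frames
  tr2 <- gen_jitter_trajectory(n_frames = 120, n_res = 6, sigma = 0.02,
                               seed = 2)
  rt2 <- rmsd_trace(tr2, selection = "CA")
  expect_equal(rt2$window, 11:120)
  expect_equal(rt2$mean, mean(rt2$values[11:120]))
  rt3 <- rmsd_trace(tr2, selection = "CA", window = 100:120)
  expect_equal(rt3$mean, mean(rt2$values[100:120]))
  expect_error(rmsd_trace(tr2, selection = "XX"), "empty")
})

test_that("rmsd and rmsf converge to sigma*sqrt(3) on isotropic jitter", {
  sigma <- 0.02
  tr <- gen_jitter_trajectory(n_frames = 2000, n_res = 30, sigma = sigma,
                              seed = 5)
  base <- attr(tr, "truth")$base
  rt <- rmsd_trace(tr, reference = base, selection = "CA",
                   window = seq_len(2000))
  expect_equal(rt$mean, sigma * sqrt(3), tolerance = 0.05)

  rf <- rmsf_per_residue(tr, window = seq_len(2000))
  expect_false(anyNA(rf$rmsf))
  expect_equal(mean(rf$rmsf), sigma * sqrt(3), tolerance = 0.05)

  # doubling sigma doubles the fluctuation
  tr2 <- gen_jitter_trajectory(n_frames = 400, n_res = 30, sigma = 2 * sigma,
                               seed = 5)
  tr1 <- gen_jitter_trajectory(n_frames = 400, n_res = 30, sigma = sigma,
                               seed = 5)
  r2 <- mean(rmsf_per_residue(tr2, window = 1:400)$rmsf)
  r1 <- mean(rmsf_per_residue(tr1, window = 1:400)$rmsf)
  expect_equal(r2 / r1, 2, tolerance = 0.05)

  # static trajectory: all zeros; residues lacking CA are NA, not zero
  st <- gen_jitter_trajectory(n_frames = 12, n_res = 6, sigma = 0, seed = 3)
  expect_equal(rmsf_per_residue(st, window = 1:12)$rmsf, rep(0, 12),
               tolerance = 1e-12)
  st$atoms$atom[1] <- "CB"
  rfna <- rmsf_per_residue(st, window = 1:12)
  expect_true(is.na(rfna$rmsf[1]))
})

test_that("helix centroid distance reproduces the generator separation", {
  tr <- gen_jitter_trajectory(n_frames = 10, n_res = 8, separation = 1.14,
                              sigma = 0, seed = 1,
                              resno_a = 276, resno_b = 466)
  hd <- helix_distance(tr, helix_range("H3", 276, 306),
                       helix_range("H12", 466, 477))
  expect_equal(hd$mean, 1.14, tolerance = 1e-9)
  expect_equal(hd$sd, 0, tolerance = 1e-12)

  # distance to itself is zero; rigid translation leaves it unchanged
  expect_equal(helix_distance(tr, helix_range("a", 276, 306),
                              helix_range("a", 276, 306))$mean, 0)
  tr_shift <- tr
  tr_shift$coords <- tr$coords + 5
  hd2 <- helix_distance(tr_shift, helix_range("H3", 276, 306),
                        helix_range("H12", 466, 477))
  expect_equal(hd2$mean, hd$mean, tolerance = 1e-9)
  expect_error(helix_distance(tr, helix_range("none", 1, 5),
                              helix_range("H12", 466, 477)), "no C-alpha")

  # sampled separation under jitter: within sampling error at 1.44 nm
  trj <- gen_jitter_trajectory(n_frames = 500, n_res = 8, separation = 1.44,
                               sigma = 0.02, seed = 9)
  hdj <- helix_distance(trj, helix_range("H3", 276, 306),
                        helix_range("H12", 466, 477), window = 1:500)
  expect_equal(hdj$mean, 1.44, tolerance = 0.02)
})

test_that("salt-bridge traces report distances and occupancy", {
  tr <- make_salt_bridge_traj(min_dist = 0.28)
  spec <- salt_bridge_spec(10, "GLU", 20, "ARG", cutoff = 0.40)
  sb <- salt_bridge_trace(tr, spec)
  expect_equal(sb$values, rep(0.28, 5), tolerance = 1e-9)
  expect_equal(sb$occupancy, 1.0)

  far <- make_salt_bridge_traj(min_dist = 2.0)
  expect_equal(salt_bridge_trace(far, spec)$occupancy, 0.0)

  # occupancy is monotone non-decreasing in the cutoff
  set.seed(4)
  jit <- make_salt_bridge_traj(min_dist = 0.35, n_frames = 40)
  jit$coords <- jit$coords + array(rnorm(length(jit$coords), 0, 0.03),
                                   dim(jit$coords))
  occ <- vapply(seq(0.2, 0.8, by = 0.05), function(cut) {
    salt_bridge_trace(jit, salt_bridge_spec(10, "GLU", 20, "ARG",
                                            cutoff = cut))$occupancy
  }, numeric(1))
  expect_true(all(diff(occ) >= 0))

  # missing side-chain atoms are named in the error
  broken <- tr
  broken$atoms$atom[broken$atoms$atom == "NE"] <- "XX"
  broken$atoms$atom[broken$atoms$atom == "NH1"] <- "XY"
  broken$atoms$atom[broken$atoms$atom == "NH2"] <- "XZ"
  expect_error(salt_bridge_trace(broken, spec), "ARG20.*NE/NH1/NH2")
  expect_error(salt_bridge_spec(10, "ALA", 20, "ARG"), "GLU or ASP")
})

test_that("metrics are invariant to atom reordering with consistent metadata", {
  tr <- gen_jitter_trajectory(n_frames = 20, n_res = 8, sigma = 0.01, seed = 6)
  perm <- sample(seq_len(nrow(tr$atoms)))
  tr2 <- trajectory(tr$coords[, perm, , drop = FALSE], tr$atoms[perm, ])
  hd1 <- helix_distance(tr, helix_range("H3", 276, 306),
                        helix_range("H12", 466, 477))
  hd2 <- helix_distance(tr2, helix_range("H3", 276, 306),
                        helix_range("H12", 466, 477))
  expect_equal(hd1$values, hd2$values, tolerance = 1e-12)
  expect_equal(rg_trace(tr)$values, rg_trace(tr2)$values, tolerance = 1e-12)
})

test_that("multi-model PDB round trip preserves coordinates and metadata", {
  tr <- gen_jitter_trajectory(n_frames = 3, n_res = 5, sigma = 0.01, seed = 2)
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f), add = TRUE)
  write_trajectory_pdb(tr, f)
  back <- read_trajectory_pdb(f)
  expect_equal(dim(back$coords), dim(tr$coords))
  # PDB format carries 3 decimals in Angstrom = 1e-4 nm resolution
  expect_equal(back$coords, tr$coords, tolerance = 1e-3)
  expect_equal(back$atoms$resno, tr$atoms$resno)
  expect_equal(back$atoms$atom, tr$atoms$atom)
})
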