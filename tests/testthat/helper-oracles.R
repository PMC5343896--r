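# Independent oracles and small fixture builders shared across tests.

# Brute-force rotation-grid superposition: minimum RMSD over a ZYZ Euler
# grid after centroid removal. Independent of the SVD-based implementation.
brute_force_rmsd <- function(A, B, step_deg = 9, refine = TRUE) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  rot_zyz <- function(a, b, g) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  scan <- function(as, bs, gs) {
    best <- Inf; arg <- c(0, 0, 0)
    for (a in as) for (b in bs) for (g in gs) {
      v <- sqrt(sum((A0 %*% rot_zyz(a, b, g) - B0)^2) / nrow(A0))
      if (v < best) { best <- v; arg <- c(a, b, g) }
    }
    list(best = best, arg = arg)
  }
  s <- pi / 180 * step_deg
  coarse <- scan(seq(0, 2 * pi - s, by = s), seq(0, pi, by = s),
                 seq(0, 2 * pi - s, by = s))
  if (!refine) return(coarse$best)
  fs <- pi / 180
  fine <- scan(coarse$arg[1] + seq(-s, s, by = fs),
               coarse$arg[2] + seq(-s, s, by = fs),
               coarse$arg[3] + seq(-s, s, by = fs))
  fine$best
}

# Coarse grid-search minimizer for the two-state model with fixed (zero)
# baseline slopes: independent check of the nonlinear least-squares route.
grid_search_two_state <- function(x, y, dG_grid, m_grid, yN_grid, yU_grid,
                                  temperature_K = 283.15) {
  best <- Inf; arg <- NULL
  for (dG in dG_grid) for (m in m_grid) for (yN in yN_grid) for (yU in yU_grid) {
    pred <- two_state_model(x, dG, m, yN, 0, yU, 0,
                            temperature_K = temperature_K)
    rss <- sum((y - pred)^2)
    if (rss < best) { best <- rss; arg <- c(dG = dG, m = m, yN = yN, yU = yU) }
  }
  list(par = arg, rss = best)
}

# Random rigid transform (proper rotation + translation) for invariance tests.
random_rigid <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, sd = 2))
}

# Minimal static trajectory holding a GLU side-chain carboxylate and an ARG
# guanidinium group with a set minimum O-N distance (nm).
make_salt_bridge_traj <- function(min_dist, n_frames = 5) {
  atoms <- data.frame(
    resno = c(10, 10, 10, 20, 20, 20, 20),
    resname = c("GLU", "GLU", "GLU", "ARG", "ARG", "ARG", "ARG"),
    atom = c("CD", "OE1", "OE2", "CZ", "NE", "NH1", "NH2"),
    chain = "A", stringsAsFactors = FALSE)
  base <- rbind(
    c(0, 0, 0),                       # CD
    c(0.12, 0, 0),                    # OE1 (closest O)
    c(-0.12, 0, 0),                   # OE2
    c(0.12 + min_dist + 0.10, 0, 0),  # CZ
    c(0.12 + min_dist, 0, 0),         # NE  (closest N)
    c(0.12 + min_dist + 0.15, 0.1, 0),
    c(0.12 + min_dist + 0.15, -0.1, 0))
  coords <- array(NA_real_, c(n_frames, nrow(base), 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- base
  trajectory(coords, atoms)
}
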