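test_that("ANM of non-collinear points has exactly six zero modes", {
  tri <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3, 1))
  sp <- anm_modes(tri, 13)
  expect_equal(sp$n_zero_modes, 6L)
  expect_length(sp$values, 3L)  # 3N - 6
  expect_equal(sp$dim, 3L)
})

test_that("rigid translations lie in the ANM null space", {
  toy <- toy_system()
  xyz <- toy$coords[toy$domain1, ]
  n <- nrow(xyz)
  sp <- anm_modes(xyz, 13)
  ## reconstruct H action from the eigenpairs: H v = sum lambda u (u.v)
  tvec <- rep(c(1, 0, 0), n) / sqrt(n)
  hv <- sp$vectors %*% (sp$values * crossprod(sp$vectors, tvec))
  expect_lt(max(abs(hv)), 1e-10)
})

test_that("ANM eigenpairs satisfy the Hessian residual equation", {
  set.seed(51)
  toy <- toy_system()
  xyz <- toy$coords[1:30, ]
  sp <- anm_modes(xyz, 13, n_modes = 10)
  ## independent Hessian build (plain double loop)
  n <- nrow(xyz)
  h <- matrix(0, 3 * n, 3 * n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    rij <- xyz[j, ] - xyz[i, ]
    d2 <- sum(rij^2)
    if (sqrt(d2) > 13) next
    blk <- -outer(rij, rij) / d2
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    h[ii, jj] <- blk; h[jj, ii] <- blk
    h[ii, ii] <- h[ii, ii] - blk; h[jj, jj] <- h[jj, jj] - blk
  }
  for (k in seq_along(sp$values)) {
    resid <- h %*% sp$vectors[, k] - sp$values[k] * sp$vectors[, k]
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("disconnected ANM networks are rejected", {
  far <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3, 0),
               c(100, 0, 0), c(104, 0, 0), c(102, 3, 0))
  expect_error(anm_modes(far, 13), "disconnected")
})

test_that("best-mode selection matches an exhaustive scan", {
  toy <- toy_system()
  pair <- make_conformer_pair(toy, angle = 20)
  fit <- kabsch_superpose(pair$open, pair$closed)
  pool <- anm_modes(pair$open, 13, n_modes = 50)
  sel <- select_best_mode(pool, pair$open, fit$yfit)
  full <- anm_modes(pair$open, 13)  # all 3N - 6 modes
  d <- as.vector(t(fit$yfit - pair$open))
  ov_full <- abs(crossprod(full$vectors, d)) / sqrt(sum(d^2))
  expect_equal(sel$index, which.max(ov_full[1:50]))
  expect_equal(sel$overlap, max(ov_full[1:50]), tolerance = 1e-9)
  expect_true(all(sel$overlaps <= sel$overlap + 1e-12))
  ## a difference equal to an eigenvector selects that mode with overlap 1
  sel2 <- select_best_mode(pool, pair$open,
                           pair$open + matrix(pool$vectors[, 3], ncol = 3,
                                              byrow = TRUE))
  expect_equal(sel2$index, 3L)
  expect_equal(sel2$overlap, 1, tolerance = 1e-9)
  expect_error(select_best_mode(pool, pair$open, pair$open), "zero difference")
})

test_that("deformation steps have exactly the requested C-alpha RMSD", {
  toy <- toy_system()
  xyz <- toy$coords
  sp <- anm_modes(xyz, 13, n_modes = 5)
  u <- sp$vectors[, 1]
  for (df in c(0.4, 1.3)) {
    moved <- apply_deformation(xyz, u, df)
    disp_rmsd <- sqrt(mean(rowSums((moved - xyz)^2)))
    expect_equal(disp_rmsd, df, tolerance = 1e-9)
  }
  ## df = 0 is the identity; step then its negation restores the input
  expect_equal(apply_deformation(xyz, u, 0), xyz, tolerance = 1e-12)
  fwd <- apply_deformation(xyz, u, 0.4)
  back <- apply_deformation(fwd, -u, 0.4)
  expect_lt(max(abs(back - xyz)), 1e-12)
  ## max scaling bounds the largest per-residue displacement
  mv <- apply_deformation(xyz, u, 0.4, scaling = "max")
  expect_equal(max(sqrt(rowSums((mv - xyz)^2))), 0.4, tolerance = 1e-9)
})

test_that("relaxation fixes the pre-deformation conformer at zero temperature", {
  toy <- toy_system()
  xyz <- toy$coords
  cfg <- anmld_config(temperature = 0, min_steps = 100, ld_steps = 20)
  out <- relax(xyz, xyz, cfg)
  expect_lt(max(abs(out - xyz)), 1e-6)
})

test_that("relaxation preserves chain geometry after a deformation step", {
  toy <- toy_system()
  xyz <- toy$coords
  sp <- anm_modes(xyz, 13, n_modes = 5)
  cfg <- anmld_config(seed = 3)
  set.seed(cfg$seed)
  deformed <- apply_deformation(xyz, sp$vectors[, 1], 0.4)
  relaxed <- relax(deformed, xyz, cfg)
  d0 <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
  d1 <- sqrt(rowSums((relaxed[-1, ] - relaxed[-nrow(relaxed), ])^2))
  expect_lt(max(abs(d1 - d0)), 0.3)
  ## fixed seed reproduces bit-identically
  set.seed(cfg$seed)
  relaxed2 <- relax(deformed, xyz, cfg)
  expect_identical(relaxed, relaxed2)
})

test_that("a transition starting at the target converges immediately", {
  toy <- toy_system()
  tr <- run_transition(toy$coords, toy$coords, anmld_config(seed = 1))
  expect_true(tr$converged)
  expect_length(tr$selected_mode, 0L)
  expect_lt(tr$rmsd_to_target[1], 1e-6)
})

test_that("the toy 20-degree closure converges below 0.5 A in 50 cycles", {
  toy <- toy_system()
  pair <- make_conformer_pair(toy, angle = 20)
  tr <- run_transition(pair$open, pair$closed,
                       anmld_config(max_cycles = 50, seed = 5))
  expect_lte(length(tr$selected_mode), 50L)
  expect_lt(tr$rmsd_to_target[length(tr$rmsd_to_target)], 0.5)
  ## RMSD is non-increasing within a DF tolerance
  expect_true(all(diff(tr$rmsd_to_target) <= tr$config$df + 1e-9))
  expect_true(all(tr$overlap >= 0 & tr$overlap <= 1))
})

test_that("transitions are reproducible and rigid-body invariant", {
  toy <- toy_system()
  pair <- make_conformer_pair(toy, angle = 15)
  cfg <- anmld_config(max_cycles = 6, seed = 9)
  a <- run_transition(pair$open, pair$closed, cfg)
  b <- run_transition(pair$open, pair$closed, cfg)
  expect_identical(a$rmsd_to_target, b$rmsd_to_target)
  expect_identical(a$selected_mode, b$selected_mode)
  ## pre-rotating the start conformer leaves the RMSD series unchanged
  ## (checked with the deterministic backend: lab-frame thermal noise is
  ## rotation-equivariant only in distribution, not pathwise)
  cfg0 <- anmld_config(max_cycles = 6, seed = 9, temperature = 0)
  a0 <- run_transition(pair$open, pair$closed, cfg0)
  r <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot_start <- sweep(pair$open %*% t(r), 2, c(10, -4, 2), "+")
  c0 <- run_transition(rot_start, pair$closed, cfg0)
  expect_lt(max(abs(c0$rmsd_to_target - a0$rmsd_to_target)), 1e-6)
})

test_that("trajectory PDB export round trips frame counts", {
  toy <- toy_system()
  pair <- make_conformer_pair(toy, angle = 10)
  tr <- run_transition(pair$open, pair$closed,
                       anmld_config(max_cycles = 3, seed = 2, patience = 99))
  tf <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, tf)
  txt <- readLines(tf)
  expect_equal(sum(grepl("^MODEL", txt)), length(tr$conformers))
})
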