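## ANM-LD: conformational transition simulation by iterated anisotropic
## network model mode selection, deformation along the best-overlapping
## mode, and coarse-grained relaxation.
##
## Each cycle: superpose the target onto the current conformer, pick the
## ANM mode best overlapping the difference vector, step along it
## (deformation factor DF, in C-alpha RMSD units), then relax under a
## C-alpha potential (pseudo-bonds at their cycle-start lengths, soft
## excluded volume, weak tether to the pre-deformation conformer) by
## steepest descent followed by overdamped Langevin steps.

#' ANM-LD configuration
#'
#' @param anm_cutoff ANM contact cutoff in Angstrom (default 13).
#' @param df Deformation factor: C-alpha RMSD of each ANM step, Angstrom
#'   (default 0.4).
#' @param max_cycles Maximum number of ANM-LD cycles (default 50).
#' @param mode_pool Number of lowest non-zero ANM modes searched
#'   (default 50).
#' @param min_steps Steepest-descent relaxation steps per cycle
#'   (default 500).
#' @param ld_steps Langevin steps per cycle (default 100).
#' @param temperature Nominal temperature in K (default 310); mapped to
#'   reduced thermal energy by `temp_scale` (A^2/K), so only the
#'   noise-to-restoring-force ratio matters at C-alpha resolution.
#' @param temp_scale Reduced-unit thermal energy per kelvin (default
#'   1e-6, chosen so the thermal RMS displacement along the softest
#'   restrained directions stays an order of magnitude below `df`).
#' @param rmsd_tol Convergence: minimum RMSD improvement (Angstrom) over
#'   `patience` cycles (default 0.01).
#' @param patience Cycles without improvement tolerated before stopping
#'   (default 5).
#' @param df_scaling `"rmsd"` (DF is the C-alpha RMSD of the step,
#'   default) or `"max"` (DF is the maximum per-residue displacement).
#' @param seed RNG seed for the Langevin noise.
#' @return A list of class `anmld_config`.
#' @export
anmld_config <- function(anm_cutoff = 13, df = 0.4, max_cycles = 50L,
                         mode_pool = 50L, min_steps = 500L, ld_steps = 100L,
                         temperature = 310, temp_scale = 1e-6,
                         rmsd_tol = 0.01, patience = 5L,
                         df_scaling = c("rmsd", "max"), seed = 1L) {
  stopifnot(df > 0, anm_cutoff > 0, max_cycles >= 1)
  structure(list(anm_cutoff = anm_cutoff, df = df, max_cycles = max_cycles,
                 mode_pool = mode_pool, min_steps = min_steps,
                 ld_steps = ld_steps, temperature = temperature,
                 temp_scale = temp_scale, rmsd_tol = rmsd_tol,
                 patience = patience, df_scaling = match.arg(df_scaling),
                 seed = seed),
            class = "anmld_config")
}

#' Anisotropic network model modes
#'
#' Builds the 3N x 3N ANM Hessian from pairwise harmonic potentials (unit
#' spring constant) at the given cutoff and returns the lowest non-zero
#' eigenpairs. A connected network has exactly six zero modes (rigid-body
#' translations/rotations); more indicates a disconnected network and is
#' an error.
#'
#' @param coords N x 3 coordinates (Angstrom), N >= 3.
#' @param cutoff Contact cutoff in Angstrom (default 13).
#' @param n_modes Number of non-zero modes to return (default all).
#' @return A `mode_spectrum` with `dim = 3`; eigenvectors are 3N-vectors
#'   in (x1, y1, z1, x2, ...) order.
#' @export
anm_modes <- function(coords, cutoff = 13, n_modes = NULL) {
  assert_coords(coords, 3L)
  n <- nrow(coords)
  d <- pair_dist(coords)
  h <- matrix(0, 3 * n, 3 * n)
  contacts <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  for (r in seq_len(nrow(contacts))) {
    i <- contacts[r, 1]; j <- contacts[r, 2]
    rij <- coords[j, ] - coords[i, ]
    blk <- -tcrossprod(rij) / sum(rij^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    h[ii, jj] <- blk
    h[jj, ii] <- blk
    h[ii, ii] <- h[ii, ii] - blk
    h[jj, jj] <- h[jj, jj] - blk
  }
  e <- eigen(h, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  zero <- vals < 1e-8 * max(vals)
  if (sum(zero) > 6)
    stop("disconnected ANM network: ", sum(zero), " near-zero modes",
         call. = FALSE)
  keep <- which(!zero)
  if (!is.null(n_modes)) keep <- keep[seq_len(min(n_modes, length(keep)))]
  structure(list(values = vals[keep], vectors = vecs[, keep, drop = FALSE],
                 n_zero_modes = sum(zero), dim = 3L, n_nodes = n),
            class = "mode_spectrum")
}

#' Select the ANM mode best overlapping a conformational difference
#'
#' Overlap is the absolute normalized dot product between each pool mode
#' and the 3N difference vector between the (already superposed) target
#' and current conformations; the sign orients the step to reduce the
#' difference.
#'
#' @param modes A 3-D `mode_spectrum` from [anm_modes()].
#' @param current,target N x 3 coordinate matrices (target superposed
#'   onto current).
#' @return List: `index` (mode), `overlap` (in `[0, 1]`), `direction`
#'   (+1/-1), `projection` (signed scalar projection of the difference on
#'   the mode, Angstrom units).
#' @export
select_best_mode <- function(modes, current, target) {
  d <- as.vector(t(target - current))
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) stop("zero difference vector: already at target",
                      call. = FALSE)
  proj <- as.vector(crossprod(modes$vectors, d))   # modes orthonormal
  ov <- abs(proj) / nd
  k <- which.max(ov)
  list(index = k, overlap = ov[k], direction = sign(proj[k]),
       projection = proj[k], overlaps = ov)
}

#' Deform coordinates along a mode
#'
#' The unit 3N mode vector is scaled so that the C-alpha RMSD of the
#' displacement equals `df` (or so the maximum per-residue displacement
#' equals `df` with `scaling = "max"`).
#'
#' @param coords N x 3 coordinates.
#' @param mode Unit 3N mode vector (signed).
#' @param df Deformation factor in Angstrom (default 0.4).
#' @param scaling `"rmsd"` or `"max"`.
#' @return Deformed N x 3 coordinates.
#' @export
apply_deformation <- function(coords, mode, df = 0.4,
                              scaling = c("rmsd", "max")) {
  scaling <- match.arg(scaling)
  n <- nrow(coords)
  disp <- matrix(mode, n, 3, byrow = TRUE)
  per_res <- sqrt(rowSums(disp^2))
  s <- if (scaling == "rmsd") df / sqrt(mean(per_res^2))
       else df / max(per_res)
  coords + s * disp
}

## Potential terms for the relaxation backend. `ref` is the
## pre-deformation conformer: pseudo-bond equilibria and the native-contact
## carve-out for the repulsion are taken from it, so `relax(ref, ref)` with
## zero temperature is a fixed point.
relax_terms <- function(ref, bond_max = 4.5, rep_cut = 4) {
  n <- nrow(ref)
  dref <- pair_dist(ref)
  bi <- seq_len(n - 1L)
  bonded <- dref[cbind(bi, bi + 1L)] <= bond_max
  bonds <- cbind(bi[bonded], bi[bonded] + 1L)
  b0 <- dref[bonds]
  ## repulsion equilibrium: min(rep_cut, native distance) so native
  ## sub-4 A pairs are not pushed apart
  list(bonds = bonds, b0 = b0, dref = dref, rep_cut = rep_cut, n = n)
}

## Scatter-add `add` (m x 3) into g rows `idx`, aggregating duplicates.
scatter_add <- function(g, idx, add) {
  ag <- rowsum(add, idx)
  rows <- as.integer(rownames(ag))
  g[rows, ] <- g[rows, ] + ag
  g
}

relax_gradient <- function(x, terms, ref, k_bond = 10, k_rep = 10,
                           k_tether = 0.05) {
  g <- k_tether * (x - ref)
  d <- pair_dist(x)
  ## pseudo-bonds at their cycle-start lengths
  bd <- d[terms$bonds]
  coefb <- k_bond * (bd - terms$b0) / pmax(bd, 1e-8)
  dx <- x[terms$bonds[, 1], , drop = FALSE] - x[terms$bonds[, 2], , drop = FALSE]
  gb <- coefb * dx
  g <- scatter_add(g, terms$bonds[, 1], gb)
  g <- scatter_add(g, terms$bonds[, 2], -gb)
  ## excluded volume: pairs below their carve-out equilibrium
  ## (matrix first in pmin so the dim attribute survives)
  d0 <- pmin(terms$dref, terms$rep_cut)
  viol <- which(d < d0 - 1e-9 & upper.tri(d), arr.ind = TRUE)
  if (nrow(viol)) {
    i <- viol[, 1]; j <- viol[, 2]
    dij <- d[viol]
    coefr <- -k_rep * (d0[viol] - dij) / pmax(dij, 1e-8)
    gr <- coefr * (x[i, , drop = FALSE] - x[j, , drop = FALSE])
    g <- scatter_add(g, i, gr)
    g <- scatter_add(g, j, -gr)
  }
  g
}

#' Coarse-grained relaxation of a deformed conformer
#'
#' Steepest descent (`min_steps`) followed by overdamped Langevin steps
#' (`ld_steps`) under a C-alpha potential: harmonic pseudo-bonds between
#' consecutive residues at their pre-deformation lengths, soft excluded
#' volume below 4 Angstrom (native close pairs exempt), and a weak
#' positional tether to the pre-deformation conformer.
#'
#' @param coords Deformed N x 3 coordinates.
#' @param ref Pre-deformation N x 3 coordinates.
#' @param config An `anmld_config`.
#' @return Relaxed N x 3 coordinates.
#' @export
relax <- function(coords, ref, config = anmld_config()) {
  terms <- relax_terms(ref)
  lr <- 0.01
  x <- coords
  for (s in seq_len(config$min_steps)) {
    g <- relax_gradient(x, terms, ref)
    if (!all(is.finite(g))) stop("non-finite gradient during minimization",
                                 call. = FALSE)
    x <- x - lr * g
  }
  kt <- config$temperature * config$temp_scale
  amp <- sqrt(2 * kt * lr)
  for (s in seq_len(config$ld_steps)) {
    g <- relax_gradient(x, terms, ref)
    x <- x - lr * g + amp * matrix(stats::rnorm(3 * terms$n), terms$n, 3)
  }
  if (!all(is.finite(x))) stop("non-finite coordinates after relaxation",
                               call. = FALSE)
  bd <- pair_dist(x)[terms$bonds]
  if (any(bd > 4.5 + 0.5))
    warning("chain connectivity strained after relaxation", call. = FALSE)
  x
}

#' Simulate a conformational transition by ANM-LD
#'
#' Iterates {superpose target, select best-overlapping ANM mode, deform by
#' DF along it, relax} until the RMSD to the target stops improving or
#' `max_cycles` is reached. The per-cycle step never exceeds the optimal
#' least-squares projection of the remaining difference on the selected
#' mode, so the fixed DF cannot overshoot near convergence.
#'
#' @param start,target `structure_model` objects or N x 3 coordinate
#'   matrices.
#' @param config An [anmld_config()].
#' @param exclude Residue ranges (author numbering) excluded before
#'   mapping, e.g. an unmodeled regulatory domain.
#' @return Object of class `anmld_trajectory`: `conformers` (list of
#'   frames, cycle 0 = start), `selected_mode`, `overlap`,
#'   `rmsd_to_target`, `converged`, `config`, `map`.
#' @export
run_transition <- function(start, target, config = anmld_config(),
                           exclude = NULL) {
  if (inherits(start, "structure_model") && inherits(target, "structure_model")) {
    sx <- extract_ca(start, exclude)
    tx <- extract_ca(target, exclude)
    sm <- structure_model(sx$xyz, chain = start$residues$chain[sx$index],
                          resno = start$residues$resno[sx$index],
                          insert = start$residues$insert[sx$index])
    tm <- structure_model(tx$xyz, chain = target$residues$chain[tx$index],
                          resno = target$residues$resno[tx$index],
                          insert = target$residues$insert[tx$index])
    map <- map_common_residues(sm, tm)
    cur <- sm$xyz[map$ia, , drop = FALSE]
    tgt <- tm$xyz[map$ib, , drop = FALSE]
  } else {
    cur <- as.matrix(start); tgt <- as.matrix(target)
    stopifnot(nrow(cur) == nrow(tgt))
    map <- NULL
  }
  if (nrow(cur) < 3) stop("need at least 3 common residues", call. = FALSE)
  set.seed(config$seed)
  rmsd0 <- kabsch_superpose(cur, tgt)$rmsd
  frames <- list(cur)
  sel_mode <- integer(0); ovl <- numeric(0); rmsd_series <- rmsd0
  converged <- rmsd0 < 1e-6
  n <- nrow(cur)
  stall <- 0L; grow <- 0L
  cycle <- 0L
  while (!converged && cycle < config$max_cycles) {
    cycle <- cycle + 1L
    fit <- kabsch_superpose(cur, tgt)
    modes <- anm_modes(cur, config$anm_cutoff, config$mode_pool)
    sel <- select_best_mode(modes, cur, fit$yfit)
    u <- sel$direction * modes$vectors[, sel$index]
    ## optimal amplitude along the mode, in RMSD units, capped at DF
    proj_rmsd <- abs(sel$projection) / sqrt(n)
    df_eff <- min(config$df, proj_rmsd)
    deformed <- apply_deformation(cur, u, df_eff, config$df_scaling)
    cur2 <- relax(deformed, cur, config)
    r <- kabsch_superpose(cur2, tgt)$rmsd
    prev <- rmsd_series[length(rmsd_series)]
    grow <- if (r > prev + 1) grow + 1L else 0L
    if (grow >= 3L)
      stop(sprintf("divergence at cycle %d: RMSD %.2f A (was %.2f)",
                   cycle, r, prev), call. = FALSE)
    cur <- cur2
    frames[[cycle + 1L]] <- cur
    sel_mode <- c(sel_mode, sel$index)
    ovl <- c(ovl, sel$overlap)
    rmsd_series <- c(rmsd_series, r)
    best_prev <- min(rmsd_series[-length(rmsd_series)])
    stall <- if (best_prev - r < config$rmsd_tol) stall + 1L else 0L
    if (stall >= config$patience) converged <- TRUE
  }
  structure(list(conformers = frames, selected_mode = sel_mode,
                 overlap = ovl, rmsd_to_target = rmsd_series,
                 converged = converged, config = config, map = map,
                 target = tgt),
            class = "anmld_trajectory")
}

#' @export
print.anmld_trajectory <- function(x, ...) {
  r <- x$rmsd_to_target
  cat(sprintf("ANM-LD trajectory: %d cycles, RMSD %.2f -> %.2f A%s\n",
              length(x$selected_mode), r[1], r[length(r)],
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Plot the RMSD-to-target convergence curve
#' @param x An `anmld_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.anmld_trajectory <- function(x, ...) {
  graphics::plot(seq_along(x$rmsd_to_target) - 1, x$rmsd_to_target,
                 type = "b", xlab = "cycle", ylab = "RMSD to target (A)", ...)
  invisible(x)
}

#' Write an ANM-LD trajectory as a multi-model PDB
#'
#' @param traj An `anmld_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$conformers)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- traj$conformers[[f]]
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(m)), seq_len(nrow(m)), m[, 1], m[, 2], m[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
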