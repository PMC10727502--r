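## Gaussian transfer entropy over GNM modes.
##
## Fluctuations are the scalar (isotropic, 1-D) GNM variables, so all
## covariance blocks are scalars and every entropy is a half-log of a
## determinant built from the mode-filtered time correlations
##   c_ij(tau) = sum_k  lambda_k^-1 u_ki u_kj exp(-lambda_k tau)
## in reduced units (kT = friction = spring constant = 1).

#' Mode-filtered time correlations of GNM fluctuations
#'
#' Computes the equal-time covariance `c(0)` and the lag-`tau` covariance
#' `c(tau)` restricted to a subset of slow modes. With all non-zero modes
#' and `tau = 0` this is the Moore-Penrose pseudoinverse of the Kirchhoff
#' matrix.
#'
#' @param spectrum A GNM `mode_spectrum`.
#' @param subset Mode indices from [mode_subset()].
#' @param tau Dimensionless time delay (>= 0).
#' @return Object of class `te_correlations` with `c0`, `ctau`, `tau`,
#'   `subset`.
#' @export
time_correlations <- function(spectrum, subset, tau) {
  stopifnot(tau >= 0, length(subset) >= 1,
            all(subset >= 1), all(subset <= length(spectrum$values)))
  u <- spectrum$vectors[, subset, drop = FALSE]
  lam <- spectrum$values[subset]
  c0 <- u %*% (t(u) / lam)
  ctau <- u %*% (t(u) * exp(-lam * tau) / lam)
  structure(list(c0 = c0, ctau = ctau, tau = tau, subset = subset),
            class = "te_correlations")
}

## Transfer entropy matrix from scalar Gaussian lag covariances, fully
## vectorized over ordered pairs (i, j). For the triple
##   x = dR_i(0), y = dR_j(0), z = dR_j(tau):
##   var x = c0_ii, var y = var z = c0_jj,
##   cov(x,y) = c0_ij, cov(x,z) = ctau_ij, cov(y,z) = ctau_jj.
## conditioning = "source" follows the formulation in which the first
## conditional entropy conditions on the source's present value:
##   T = S(z | x) - S(z | x, y) = I(z; y | x)
## conditioning = "target" is the Schreiber convention:
##   T = S(z | y) - S(z | x, y) = I(z; x | y)
## Both are conditional mutual informations, hence non-negative.
te_from_correlations <- function(corr, conditioning = c("target", "source")) {
  conditioning <- match.arg(conditioning)
  c0 <- corr$c0; ct <- corr$ctau
  n <- nrow(c0)
  vi <- diag(c0)                        # var x, indexed by i
  vj <- diag(c0)                        # var y = var z, indexed by j
  ctjj <- diag(ct)                      # cov(y, z), indexed by j
  Vi <- matrix(vi, n, n)                # row i
  Vj <- matrix(vj, n, n, byrow = TRUE)  # col j
  Cyz <- matrix(ctjj, n, n, byrow = TRUE)
  det_xz <- Vi * Vj - ct^2              # det cov(x, z)
  det_xy <- Vi * Vj - c0^2              # det cov(x, y)
  det_yz <- Vj * Vj - Cyz^2             # det cov(y, z)
  ## 3x3 determinant, expanded along the first row
  det3 <- Vi * (Vj * Vj - Cyz^2) -
    c0 * (c0 * Vj - Cyz * ct) +
    ct * (c0 * Cyz - Vj * ct)
  ## pairs whose covariance blocks are singular at working precision
  ## (relative to the variance scale) are flagged and zeroed: with a
  ## truncated mode subset some pairs are perfectly collinear and their
  ## conditional entropies are not defined
  scale2 <- Vi * Vj
  scale3 <- Vi * Vj * Vj
  tol <- 1e-10
  bad <- det3 <= tol * scale3 | det_xy <= tol * scale2 |
    (if (conditioning == "source") det_xz <= tol * scale2
     else det_yz <= tol * Vj * Vj)
  eps <- 1e-300
  t_mat <- if (conditioning == "source") {
    0.5 * log(pmax(det_xz, eps) * pmax(det_xy, eps) /
                (pmax(Vi * det3, eps)))
  } else {
    0.5 * log(pmax(det_yz, eps) * pmax(det_xy, eps) /
                (pmax(Vj * det3, eps)))
  }
  bad <- bad | !is.finite(t_mat)
  diag(bad) <- FALSE
  if (any(bad)) {
    warning(sum(bad), " pair(s) with singular covariance set to 0",
            call. = FALSE)
    t_mat[bad] <- 0
  }
  t_mat[t_mat < 0 & t_mat > -1e-8] <- 0   # numerical floor
  diag(t_mat) <- 0
  attr(t_mat, "n_singular") <- sum(bad)
  t_mat
}

#' Pairwise transfer entropy and net transfer entropy
#'
#' Evaluates the Gaussian transfer entropy `T[i, j] = T_{i->j}(tau)` for
#' every ordered residue pair from mode-filtered lag covariances, as
#' differences of Gaussian log-determinant conditional entropies, plus the
#' antisymmetric net matrix `netT = T - t(T)`.
#'
#' @param corr A `te_correlations` object.
#' @param conditioning `"target"` (default; Schreiber convention, the
#'   first conditional entropy conditions on the target's own past) or
#'   `"source"` (conditioning on the source's present value), provided as
#'   a sensitivity switch. Under `"source"` the transfer entropy grows
#'   without bound as `tau -> 0`, so automatic delay selection is only
#'   meaningful under `"target"`.
#' @return Object of class `gnm_te` with elements `T`, `netT`, `tau`,
#'   `subset`, `conditioning` (residue-level scores are added by
#'   [tecol_scores()] or the [gnm_te()] front end).
#' @export
te_matrix <- function(corr, conditioning = c("target", "source")) {
  conditioning <- match.arg(conditioning)
  t_mat <- te_from_correlations(corr, conditioning)
  structure(list(T = t_mat, netT = t_mat - t(t_mat),
                 tau = corr$tau, subset = corr$subset,
                 conditioning = conditioning),
            class = "gnm_te")
}

#' Select the time delay maximizing total transfer entropy
#'
#' Scans a grid of delays for `tau_opt`, the delay maximizing the total
#' transfer entropy (sum of `T` over all ordered pairs); analyses are run
#' at `tau_used = 3 * tau_opt`, the delay at which net-transfer
#' collectivity is typically maximal. The total net positive transfer is
#' reported alongside for each grid point.
#'
#' @param spectrum A GNM `mode_spectrum`.
#' @param subset Mode indices.
#' @param grid Vector of candidate delays; default 60 log-spaced points
#'   spanning `[0.01/lambda_max, 20/lambda_min]` of the subset.
#' @param factor Multiplier applied to `tau_opt` (default 3).
#' @param conditioning Passed to [te_matrix()].
#' @return List with `tau_opt`, `tau_used`, `grid`, `total_te`,
#'   `total_net_positive`.
#' @export
select_tau <- function(spectrum, subset, grid = NULL, factor = 3,
                       conditioning = "target") {
  lam <- spectrum$values[subset]
  if (is.null(grid))
    grid <- exp(seq(log(0.01 / max(lam)), log(20 / min(lam)), length.out = 60))
  stopifnot(length(grid) >= 1, all(grid > 0))
  tot <- netpos <- numeric(length(grid))
  for (g in seq_along(grid)) {
    tm <- te_from_correlations(time_correlations(spectrum, subset, grid[g]),
                               conditioning)
    tot[g] <- sum(tm)
    netpos[g] <- sum(pmax(tm - t(tm), 0))
  }
  if (!any(is.finite(tot))) stop("non-finite TE on entire grid", call. = FALSE)
  tau_opt <- grid[which.max(tot)]
  list(tau_opt = tau_opt, tau_used = factor * tau_opt, grid = grid,
       total_te = tot, total_net_positive = netpos)
}

## Row-wise collectivity of positive net TE (vectorized over rows).
## For each source residue i: zero the negative entries, normalize the
## squared row to sum 1 (alpha), and exponentiate the entropy of that
## distribution; K is 1/N for a one-target row and 1 for a uniform row.
collectivity_rows <- function(netT) {
  n <- ncol(netT)
  pos <- pmax(netT, 0)
  ss <- rowSums(pos^2)
  alpha <- ifelse(ss > 0, 1 / ss, NA_real_)
  p <- pos^2 * ifelse(is.na(alpha), 0, alpha)   # rows sum to 1 (or 0)
  plogp <- ifelse(p > 0, p * log(p), 0)
  k <- (1 / n) * exp(-rowSums(plogp))
  k[is.na(alpha)] <- 1 / n                      # no positive entries
  list(K = k, alpha = alpha, cum_pos = rowSums(pos))
}

#' Collectivity of a residue's outgoing net transfer entropy
#'
#' Exponential-entropy measure of how broadly the positive net transfer
#' from one residue is spread over the structure: 1/N when a single
#' residue receives everything, 1 when all residues receive equally.
#'
#' @param netT Net transfer entropy matrix (or a single row).
#' @return For a matrix: list with per-residue `K`, `alpha` (row
#'   normalization constants) and `cum_pos` (cumulative positive net TE).
#' @export
collectivity <- function(netT) {
  if (is.null(dim(netT))) netT <- matrix(netT, nrow = 1)
  collectivity_rows(netT)
}

#' TECol allosteric-source scores
#'
#' The TECol score of residue i is its cumulative positive net transfer
#' entropy multiplied by its collectivity; high values flag residues that
#' send much information, broadly.
#'
#' @param te A `gnm_te` object from [te_matrix()] or [gnm_te()].
#' @return The object with `K`, `alpha`, `cum_pos`, `tecol` filled.
#' @export
tecol_scores <- function(te) {
  stopifnot(inherits(te, "gnm_te"))
  cc <- collectivity_rows(te$netT)
  te$K <- cc$K
  te$alpha <- cc$alpha
  te$cum_pos <- cc$cum_pos
  te$tecol <- cc$K * cc$cum_pos
  te
}

#' Fit the GNM transfer-entropy model to a structure
#'
#' The front-end fitting function: builds the GNM at the given cutoff,
#' selects the time delay (3 x the total-TE-maximizing delay, unless `tau`
#' is supplied), computes pairwise and net transfer entropy over the
#' requested slow-mode subset, and derives per-residue cumulative positive
#' net TE, collectivity and TECol scores.
#'
#' @param x A `structure_model`, an N x 3 coordinate matrix, or a
#'   fitted `gnm` object.
#' @param cutoff GNM contact cutoff in Angstrom (default 10).
#' @param slowest,drop Slow-mode subset specification (default modes 1-10).
#' @param tau Optional fixed time delay; by default selected via
#'   [select_tau()].
#' @param grid Optional delay grid for [select_tau()].
#' @param conditioning See [te_matrix()].
#' @return Object of class `gnm_te` with matrices `T`, `netT`, scores
#'   `cum_pos`, `K`, `tecol`, the delays `tau`, `tau_opt`, the `subset`,
#'   the underlying `gnm`, and residue metadata when `x` was a
#'   `structure_model`.
#' @seealso [source_profile()], [detect_peaks()], [simulate.gnm_te()]
#' @export
gnm_te <- function(x, cutoff = 10, slowest = 10L, drop = 0L, tau = NULL,
                   grid = NULL, conditioning = c("target", "source")) {
  conditioning <- match.arg(conditioning)
  residues <- NULL
  if (inherits(x, "structure_model")) {
    residues <- x$residues
    x <- x$xyz
  }
  g <- if (inherits(x, "gnm")) x else gnm(x, cutoff)
  slowest <- min(slowest, length(g$spectrum$values))
  subset <- mode_subset(g$spectrum, slowest, drop)
  tau_opt <- NA_real_
  if (is.null(tau)) {
    sel <- select_tau(g$spectrum, subset, grid, conditioning = conditioning)
    tau <- sel$tau_used
    tau_opt <- sel$tau_opt
  }
  te <- te_matrix(time_correlations(g$spectrum, subset, tau), conditioning)
  te <- tecol_scores(te)
  te$tau_opt <- tau_opt
  te$gnm <- g
  te$residues <- residues
  te
}

#' @export
print.gnm_te <- function(x, ...) {
  n <- nrow(x$T)
  cat("GNM transfer entropy fit\n")
  cat(sprintf("  %d residues, modes %d-%d, tau = %.4g%s, conditioning = %s\n",
              n, min(x$subset), max(x$subset), x$tau,
              if (!is.null(x$tau_opt) && is.finite(x$tau_opt))
                sprintf(" (3 x tau_opt = %.4g)", x$tau_opt) else "",
              x$conditioning))
  if (!is.null(x$tecol)) {
    top <- order(x$tecol, decreasing = TRUE)[seq_len(min(5, n))]
    lab <- if (!is.null(x$residues))
      paste0(x$residues$chain[top], ":", x$residues$resno[top]) else top
    cat("  top TECol residues:",
        paste(sprintf("%s (%.3g)", lab, x$tecol[top]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.gnm_te <- function(object, ...) {
  out <- list(n = nrow(object$T), tau = object$tau, subset = object$subset,
              total_te = sum(object$T),
              tecol = summary(object$tecol),
              n_sources = sum(object$cum_pos > mean(object$cum_pos)))
  class(out) <- "summary.gnm_te"
  out
}

#' @export
print.summary.gnm_te <- function(x, ...) {
  cat("GNM-TE summary:", x$n, "residues; total TE", signif(x$total_te, 4),
      "nats at tau =", signif(x$tau, 4), "\n")
  cat("TECol score distribution:\n")
  print(x$tecol)
  invisible(x)
}

#' @export
coef.gnm_te <- function(object, ...) {
  data.frame(residue = seq_along(object$tecol),
             chain = object$residues$chain %||% NA,
             resno = object$residues$resno %||% seq_along(object$tecol),
             cum_pos = object$cum_pos, K = object$K, tecol = object$tecol)
}

#' Plot per-residue transfer-entropy scores
#'
#' @param x A `gnm_te` object.
#' @param which `"tecol"` (default) or `"cum_pos"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gnm_te <- function(x, which = c("tecol", "cum_pos"), ...) {
  which <- match.arg(which)
  y <- x[[which]]
  graphics::plot(seq_along(y), y, type = "h", xlab = "residue index",
                 ylab = which, ...)
  invisible(x)
}

#' Simulate fluctuation trajectories from a fitted GNM-TE model
#'
#' Draws an overdamped Langevin (Ornstein-Uhlenbeck) trajectory whose
#' stationary covariance is the GNM pseudoinverse; a direct route to the
#' empirical estimators that cross-check the analytic transfer entropy.
#'
#' @param object A `gnm_te` object.
#' @param nsim Number of steps.
#' @param seed RNG seed.
#' @param dt Time step in reduced units (default 0.2).
#' @param ... Unused.
#' @return `nsim` x N matrix of scalar residue fluctuations.
#' @export
simulate.gnm_te <- function(object, nsim = 10000, seed = NULL, dt = 0.2, ...) {
  net <- structure(list(kirchhoff = object$gnm$kirchhoff,
                        cutoff = object$gnm$cutoff),
                   class = "gnm_network")
  simulate_gnm_langevin(net, n_steps = nsim, dt = dt, seed = seed)
}

#' Information sent to or received from a set of source residues
#'
#' For `direction = "sent"`, profile entry j is the positive net transfer
#' from the source set to residue j; for `"received"`, the positive net
#' transfer from residue j to the source set (i.e. what the sources
#' receive). Source positions themselves are set to 0.
#'
#' @param te A `gnm_te` object.
#' @param source Integer residue indices, or a residue-set specification
#'   resolvable against the fit's residue table (see
#'   [parse_residue_set()]).
#' @param direction `"sent"` or `"received"`.
#' @return Numeric per-residue profile.
#' @export
source_profile <- function(te, source, direction = c("sent", "received")) {
  direction <- match.arg(direction)
  n <- nrow(te$netT)
  if (!is.numeric(source)) {
    if (is.null(te$residues))
      stop("fit has no residue table; give integer indices", call. = FALSE)
    source <- resolve_residues(list(residues = te$residues),
                               parse_residue_set(source))
  }
  source <- as.integer(source)
  if (!length(source)) stop("empty source set", call. = FALSE)
  stopifnot(all(source >= 1), all(source <= n))
  pos <- pmax(te$netT, 0)
  prof <- if (direction == "sent") colSums(pos[source, , drop = FALSE])
          else colSums(t(pos)[source, , drop = FALSE])
  prof[source] <- 0
  prof
}

#' Pearson correlation between two per-residue profiles
#'
#' @param a,b Equal-length numeric profiles (length >= 3, non-constant).
#' @return Pearson correlation coefficient.
#' @export
profile_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop("profiles must have equal length >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant profile: correlation undefined", call. = FALSE)
  stats::cor(a, b)
}
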