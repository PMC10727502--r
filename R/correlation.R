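## Equal-time and time-delayed dynamic cross-correlations over trajectory
## windows, and leader/follower directionality calls.

#' Windowed residue fluctuations of a trajectory
#'
#' Fluctuation of residue i at frame t is its displacement from its mean
#' position over the selected window.
#'
#' @param traj An `anmld_trajectory` or a list of N x 3 frames.
#' @param window `c(start, length)` in frames (1-based over the stored
#'   frames; default the whole trajectory).
#' @return Object of class `trajectory_fluctuations`: 3-D array
#'   frames x N x 3, with the window-mean conformer as attribute
#'   `mean_conformer`.
#' @export
window_fluctuations <- function(traj, window = NULL) {
  frames <- if (inherits(traj, "anmld_trajectory")) traj$conformers else traj
  nf <- length(frames)
  if (is.null(window)) window <- c(1L, nf)
  start <- window[1]; len <- window[2]
  if (len < 2) stop("window too short (length >= 2 required)", call. = FALSE)
  if (start < 1 || start + len - 1 > nf)
    stop("window outside trajectory (", nf, " frames)", call. = FALSE)
  sel <- frames[seq.int(start, start + len - 1L)]
  n <- nrow(sel[[1]])
  arr <- array(unlist(sel), dim = c(n, 3, len))
  mean_conf <- apply(arr, c(1, 2), mean)
  fl <- aperm(sweep(arr, c(1, 2), mean_conf), c(3, 1, 2))  # t x N x 3
  structure(fl, mean_conformer = mean_conf, window = c(start, len),
            class = "trajectory_fluctuations")
}

#' Time-delayed dynamic cross-correlation map
#'
#' `C[i, j]` is the normalized covariance between the fluctuation of
#' residue i at frame t and residue j at frame t + tau, averaged over all
#' valid t in the window (no padding or wraparound); the normalization
#' uses the average squared fluctuation of i over valid t and of j over
#' valid t + tau. `tau = 0` gives the standard (symmetric) DCCM with unit
#' diagonal.
#'
#' @param fluct A `trajectory_fluctuations` array.
#' @param tau Delay in frames (cycles), `0 <= tau < window length`.
#' @return Object of class `dccm_map`: the N x N matrix with `tau` and the
#'   window as attributes. Zero-variance residues yield 0 with a warning.
#' @export
cross_correlation_map <- function(fluct, tau = 0) {
  nt <- dim(fluct)[1]; n <- dim(fluct)[2]
  if (tau < 0 || tau >= nt) stop("need 0 <= tau < window length", call. = FALSE)
  t1 <- seq_len(nt - tau)
  t2 <- t1 + tau
  ## num[i, j] = mean_t sum_c fluct[t, i, c] * fluct[t + tau, j, c]
  num <- matrix(0, n, n)
  for (c3 in 1:3)
    num <- num + crossprod(fluct[t1, , c3, drop = TRUE],
                           fluct[t2, , c3, drop = TRUE])
  num <- num / length(t1)
  vi <- colSums(matrix(fluct[t1, , , drop = FALSE]^2, length(t1), n * 3)) |>
    matrix(n, 3) |> rowSums()
  vi <- vi / length(t1)
  vj <- colSums(matrix(fluct[t2, , , drop = FALSE]^2, length(t2), n * 3)) |>
    matrix(n, 3) |> rowSums()
  vj <- vj / length(t2)
  denom <- sqrt(outer(vi, vj))
  zero <- vi < 1e-14 | vj < 1e-14
  if (any(zero)) warning(sum(zero), " zero-variance residue(s); entries set 0",
                         call. = FALSE)
  cmap <- num / denom
  cmap[!is.finite(cmap)] <- 0
  structure(cmap, tau = tau, window = attr(fluct, "window"),
            class = "dccm_map")
}

#' @export
print.dccm_map <- function(x, ...) {
  cat(sprintf("DCCM: %d x %d, tau = %d frame(s), range [%.2f, %.2f]\n",
              nrow(x), ncol(x), attr(x, "tau"), min(x), max(x)))
  invisible(x)
}

#' Choose the correlation time delay from the autocorrelation decay
#'
#' Returns the smallest delay at which the residue-averaged
#' autocorrelation `C_ii(tau)` crosses zero; when no crossing occurs
#' within the window, falls back to one third of the window length.
#'
#' @param fluct A `trajectory_fluctuations` array.
#' @param max_tau Largest delay scanned (default window length - 2).
#' @return Integer delay in frames.
#' @export
choose_time_delay <- function(fluct, max_tau = NULL) {
  nt <- dim(fluct)[1]
  if (nt < 4) stop("window length >= 4 required", call. = FALSE)
  if (is.null(max_tau)) max_tau <- nt - 2L
  for (tau in seq_len(max_tau)) {
    ac <- mean(diag(suppressWarnings(cross_correlation_map(fluct, tau))))
    if (ac < 0) return(tau)
  }
  as.integer(round(nt / 3))
}

#' Leader/follower directionality calls from delayed correlations
#'
#' Residue i leads j when `C_ij(tau) > C_ji(tau)` and the larger of the
#' two delayed correlations reaches `min_corr`; calls are antisymmetric.
#'
#' @param fluct A `trajectory_fluctuations` array (or a precomputed
#'   delayed `dccm_map`).
#' @param tau Delay in frames.
#' @param min_corr Minimum delayed correlation for a call (default 0.4).
#' @return Object of class `directionality_map`: integer N x N matrix with
#'   +1 (i leads j), -1 (j leads i), 0 (no call); the delayed map is kept
#'   as attribute `cmap`.
#' @export
directionality_map <- function(fluct, tau, min_corr = 0.4) {
  cmap <- if (inherits(fluct, "dccm_map")) fluct
          else cross_correlation_map(fluct, tau)
  mx <- pmax(cmap, t(cmap))
  call <- sign(cmap - t(cmap))
  call[mx < min_corr] <- 0
  diag(call) <- 0
  structure(call, cmap = cmap, tau = attr(cmap, "tau"), min_corr = min_corr,
            class = "directionality_map")
}

#' @export
print.directionality_map <- function(x, ...) {
  m <- unclass(x)
  cat(sprintf("Directionality map (tau = %d): %d called pairs of %d\n",
              attr(x, "tau"), sum(m[upper.tri(m)] != 0),
              sum(upper.tri(m))))
  invisible(x)
}

#' Directionality calls as an edge list
#'
#' @param dmap A `directionality_map`.
#' @return Data frame (i, j, C_ij, C_ji, call) for called pairs, with
#'   `call` in {"i_leads", "j_leads"}.
#' @export
directionality_edges <- function(dmap) {
  m <- unclass(dmap)
  cmap <- attr(dmap, "cmap")
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             C_ij = cmap[idx], C_ji = t(cmap)[idx],
             call = ifelse(m[idx] > 0, "i_leads", "j_leads"))
}

#' Mean correlation of every residue with a reference set
#'
#' @param cmap A `dccm_map`.
#' @param reference Integer residue indices.
#' @return Per-residue mean correlation with the reference set.
#' @export
set_correlation_profile <- function(cmap, reference) {
  n <- nrow(cmap)
  reference <- as.integer(reference)
  if (!length(reference)) stop("empty reference set", call. = FALSE)
  if (any(reference < 1 | reference > n))
    stop("reference outside model", call. = FALSE)
  colMeans(unclass(cmap)[reference, , drop = FALSE])
}
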