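## Gaussian network model: Kirchhoff matrix construction, mode
## decomposition, slow-mode subsets and hinge identification.
##
## Conventions: uniform unit spring constant, 10 A contact cutoff by
## default, reduced units throughout (kT = friction = spring constant = 1).

#' Build the GNM Kirchhoff (connectivity) matrix
#'
#' Off-diagonal element (i, j) is -1 when residues i and j are within the
#' cutoff distance, 0 otherwise; the diagonal holds node degrees, so every
#' row sums to zero. Coincident nodes are treated as contacts with a
#' warning.
#'
#' @param coords N x 3 C-alpha coordinates (Angstrom).
#' @param cutoff Contact cutoff in Angstrom (default 10).
#' @return Object of class `gnm_network` with `kirchhoff`, `cutoff`,
#'   `coords`.
#' @export
build_kirchhoff <- function(coords, cutoff = 10) {
  assert_coords(coords)
  stopifnot(cutoff > 0)
  d <- pair_dist(coords)
  if (any(d[upper.tri(d)] < 1e-8))
    warning("coincident nodes treated as contacts", call. = FALSE)
  k <- -(d <= cutoff) * 1
  diag(k) <- 0
  diag(k) <- -rowSums(k)
  structure(list(kirchhoff = k, cutoff = cutoff, coords = coords),
            class = "gnm_network")
}

#' @export
print.gnm_network <- function(x, ...) {
  n <- nrow(x$kirchhoff)
  cat("GNM network:", n, "nodes, cutoff", x$cutoff, "A, mean degree",
      round(mean(diag(x$kirchhoff)), 2), "\n")
  invisible(x)
}

#' Eigendecompose a GNM network into modes
#'
#' Eigenvalues are returned ascending over the non-zero modes. Zero modes
#' (eigenvalue below `1e-9 * lambda_max`) are separated; a connected contact
#' graph has exactly one. A disconnected graph is an error (the transfer
#' entropy formulation assumes a single component), reporting the number of
#' components.
#'
#' @param network A `gnm_network`.
#' @return Object of class `mode_spectrum`: `values` (ascending, > 0),
#'   `vectors` (N x K, orthonormal columns), `n_zero_modes`, `dim` (1 for
#'   GNM).
#' @export
decompose_gnm <- function(network) {
  k <- network$kirchhoff
  e <- eigen(k, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  zero <- vals < 1e-9 * max(vals)
  nz <- sum(zero)
  if (nz > 1) {
    comp <- graph_components(k < 0 | diag(TRUE, nrow(k)))
    stop("disconnected contact graph: ", max(comp),
         " components (sizes ", paste(tabulate(comp), collapse = ", "), ")",
         call. = FALSE)
  }
  structure(list(values = vals[!zero],
                 vectors = vecs[, !zero, drop = FALSE],
                 n_zero_modes = nz, dim = 1L,
                 n_nodes = nrow(k)),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(if (x$dim == 1L) "GNM" else "ANM", "mode spectrum:",
      length(x$values), "non-zero modes over", x$n_nodes, "nodes;",
      x$n_zero_modes, "zero mode(s)\n")
  cat("  slowest eigenvalues:",
      paste(signif(utils::head(x$values, 5), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Convenience constructor: GNM network plus spectrum
#'
#' @inheritParams build_kirchhoff
#' @return Object of class `gnm`: the network with a `spectrum` element.
#' @export
gnm <- function(coords, cutoff = 10) {
  net <- build_kirchhoff(coords, cutoff)
  net$spectrum <- decompose_gnm(net)
  class(net) <- c("gnm", class(net))
  net
}

#' Select a subset of slow modes
#'
#' Returns mode indices `{drop+1, ..., slowest}` (1-based over non-zero
#' modes). The analyses in this package use the subsets 1-10, 2-10 and
#' 3-10: dropping the one or two slowest, most collective modes exposes
#' latent signal otherwise overshadowed by global motions.
#'
#' @param spectrum A `mode_spectrum`.
#' @param slowest Number of slowest non-zero modes considered (default 10).
#' @param drop How many of the very slowest to omit (default 0).
#' @return Integer vector of mode indices.
#' @export
mode_subset <- function(spectrum, slowest = 10L, drop = 0L) {
  k <- length(spectrum$values)
  if (slowest > k) stop("slowest = ", slowest, " exceeds available modes (",
                        k, ")", call. = FALSE)
  if (drop < 0 || drop >= slowest)
    stop("need 0 <= drop < slowest", call. = FALSE)
  seq.int(drop + 1L, slowest)
}

#' Identify hinge residues of slow modes
#'
#' A hinge is where a slow-mode eigenvector changes sign between sequence
#' neighbours while the local squared mode amplitude is below the given
#' quantile (low mobility); both residues flanking the crossover are
#' reported, and the result is the union over the modes in `subset`.
#'
#' @param spectrum A `mode_spectrum` (GNM).
#' @param subset Mode indices (default modes 1-2).
#' @param amplitude_quantile Squared-amplitude quantile below which a
#'   crossover counts as a hinge (default 0.5, the median).
#' @param chains Optional chain vector (length N); crossovers are only
#'   considered within a chain.
#' @return Sorted integer vector of residue indices.
#' @export
find_hinges <- function(spectrum, subset = NULL, amplitude_quantile = 0.5,
                        chains = NULL) {
  if (is.null(subset))
    subset <- mode_subset(spectrum, min(2L, length(spectrum$values)))
  stopifnot(all(subset >= 1), all(subset <= length(spectrum$values)))
  n <- spectrum$n_nodes
  same_chain <- if (is.null(chains)) rep(TRUE, n - 1L)
                else chains[-n] == chains[-1L]
  hinges <- integer(0)
  for (k in subset) {
    u <- spectrum$vectors[, k]
    lo <- u^2 <= stats::quantile(u^2, amplitude_quantile)
    cross <- which(u[-n] * u[-1L] < 0 & same_chain)
    for (i in cross)
      if (lo[i] && lo[i + 1L]) hinges <- c(hinges, i, i + 1L)
  }
  sort(unique(hinges))
}
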