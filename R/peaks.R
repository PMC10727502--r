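## Allosteric peak detection on per-residue score profiles and
## randomization statistics for co-localization with reference residue
## sets.

## Local maxima of a 1-D series: strictly greater than both neighbours;
## a flat plateau flanked by lower values reports its leftmost index.
## Series ends are not peaks.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3) return(integer(0))
  mid <- 2:(k - 1L)
  is_peak <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][is_peak]
}

## Topographic prominence of each peak: walk outward in both directions
## until a strictly higher point (or the series end); the base on each
## side is the minimum encountered; prominence = height - max(bases).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    higher <- which(left > h)
    lbase <- min(left[seq.int(if (length(higher)) max(higher) else 1L,
                              p - 1L)])
    right <- x[seq.int(p + 1L, length(x))]
    higher <- which(right > h)
    rbase <- min(right[seq_len(if (length(higher)) min(higher) else
                               length(right))])
    h - max(lbase, rbase)
  }, numeric(1))
}

#' Detect allosteric peaks in a per-residue score profile
#'
#' Finds local maxima (per chain, so chain breaks never create spurious
#' peaks), computes their topographic prominence, and keeps peaks whose
#' score exceeds the profile mean and whose prominence reaches the mean
#' prominence of all local maxima (ties at the mean are kept, so an
#' isolated single bump counts).
#'
#' @param scores Per-residue profile (e.g. TECol scores).
#' @param chains Optional chain id per residue; each chain is treated as a
#'   separate 1-D series.
#' @param residues Optional residue table (chain/resno) carried into the
#'   result.
#' @return Object of class `te_peaks`: data frame of peaks (index, score,
#'   prominence, plus chain/resno when available) with the thresholds as
#'   attributes.
#' @export
detect_peaks <- function(scores, chains = NULL, residues = NULL) {
  n <- length(scores)
  if (is.null(chains)) chains <- rep("A", n)
  stopifnot(length(chains) == n)
  idx <- integer(0); prom <- numeric(0)
  for (ch in unique(chains)) {
    sel <- which(chains == ch)
    lm <- local_maxima(scores[sel])
    if (!length(lm)) next
    idx <- c(idx, sel[lm])
    prom <- c(prom, peak_prominence(scores[sel], lm))
  }
  score_thr <- mean(scores)
  prom_thr <- if (length(prom)) mean(prom) else Inf
  ## ties at the mean prominence are kept, so an isolated single bump
  ## (whose prominence IS the mean) still counts as a peak
  keep <- scores[idx] > score_thr & prom >= prom_thr - 1e-12
  out <- data.frame(index = idx[keep], score = scores[idx][keep],
                    prominence = prom[keep])
  if (!is.null(residues)) {
    out$chain <- residues$chain[out$index]
    out$resno <- residues$resno[out$index]
  }
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "score_threshold") <- score_thr
  attr(out, "prominence_threshold") <- prom_thr
  attr(out, "n_local_maxima") <- length(idx)
  class(out) <- c("te_peaks", class(out))
  out
}

#' @export
print.te_peaks <- function(x, ...) {
  cat("Allosteric peaks:", nrow(x), "of", attr(x, "n_local_maxima"),
      "local maxima (score >", signif(attr(x, "score_threshold"), 3),
      "and prominence >", signif(attr(x, "prominence_threshold"), 3), ")\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Count reference residues co-localizing with peaks
#'
#' Cutoff 0 counts exact index matches; a positive cutoff counts reference
#' residues whose C-alpha lies within that distance of any peak C-alpha.
#'
#' @param peaks Integer residue indices of peaks (or a `te_peaks` object).
#' @param reference Integer residue indices of the reference set.
#' @param coords N x 3 C-alpha coordinates (needed when cutoff > 0).
#' @param cutoff Distance cutoff in Angstrom (0, 4 and 7 in the analyses).
#' @return Integer match count.
#' @export
colocalization_count <- function(peaks, reference, coords = NULL, cutoff = 0) {
  if (inherits(peaks, "te_peaks")) peaks <- peaks$index
  peaks <- as.integer(peaks); reference <- as.integer(reference)
  if (!length(reference)) stop("empty reference set", call. = FALSE)
  if (cutoff <= 0) return(sum(reference %in% peaks))
  stopifnot(!is.null(coords))
  pr <- coords[reference, , drop = FALSE]
  pp <- coords[peaks, , drop = FALSE]
  d2 <- outer(rowSums(pr^2), rowSums(pp^2), "+") - 2 * pr %*% t(pp)
  sum(apply(d2, 1, min) <= cutoff^2 + 1e-9)
}

#' Randomization test for peak/reference co-localization
#'
#' Draws `n_iter` sets of `n_peaks` residues uniformly without replacement
#' from the modeled residues, counts reference co-localization for each,
#' and expresses the observed count as a Z score against that null
#' (one-tailed normal p; the empirical tail probability is reported
#' alongside).
#'
#' @param n_peaks Number of peaks per random set (or a `te_peaks` object,
#'   which also supplies the observed count).
#' @param reference Integer residue indices of the reference set.
#' @param coords N x 3 C-alpha coordinates of all modeled residues; draws
#'   are over these modeled residues only.
#' @param cutoff Distance cutoff in Angstrom.
#' @param n_iter Number of random sets (default 100000).
#' @param seed RNG seed.
#' @param observed Observed match count; computed from `n_peaks` when that
#'   is a `te_peaks` object.
#' @return Object of class `coloc_test`: `X`, `mu`, `sigma`, `Z`, `p`
#'   (normal one-tailed), `p_empirical`, `cutoff`, `n_iter`, `seed`.
#' @export
randomization_test <- function(n_peaks, reference, coords, cutoff = 0,
                               n_iter = 100000L, seed = NULL,
                               observed = NULL) {
  if (inherits(n_peaks, "te_peaks")) {
    if (is.null(observed))
      observed <- colocalization_count(n_peaks$index, reference, coords, cutoff)
    n_peaks <- nrow(n_peaks)
  }
  n <- nrow(coords)
  stopifnot(n_peaks >= 1, n_peaks <= n)
  reference <- as.integer(reference)
  if (!is.null(seed)) set.seed(seed)
  ## Precompute, per candidate residue, which reference residues it covers.
  if (cutoff <= 0) {
    cover <- matrix(FALSE, n, length(reference))
    cover[cbind(reference, seq_along(reference))] <- TRUE
  } else {
    pr <- coords[reference, , drop = FALSE]
    d2 <- outer(rowSums(coords^2), rowSums(pr^2), "+") - 2 * coords %*% t(pr)
    cover <- d2 <= cutoff^2 + 1e-9
  }
  counts <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    s <- sample.int(n, n_peaks)
    counts[it] <- sum(.colSums(cover[s, , drop = FALSE],
                               n_peaks, length(reference)) > 0L)
  }
  mu <- mean(counts); sigma <- stats::sd(counts)
  if (sigma == 0) stop("degenerate null (sigma = 0)", call. = FALSE)
  z <- if (is.null(observed)) NA_real_ else (observed - mu) / sigma
  structure(list(X = observed, mu = mu, sigma = sigma, Z = z,
                 p = if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE),
                 p_empirical = if (is.null(observed)) NA_real_
                               else (sum(counts >= observed) + 1) / (n_iter + 1),
                 counts = counts, cutoff = cutoff, n_iter = n_iter,
                 n_peaks = n_peaks, seed = seed),
            class = "coloc_test")
}

#' @export
print.coloc_test <- function(x, ...) {
  cat(sprintf("Co-localization randomization test (cutoff %g A, %d sets of %d peaks)\n",
              x$cutoff, x$n_iter, x$n_peaks))
  cat(sprintf("  null: mu = %.3f, sigma = %.3f\n", x$mu, x$sigma))
  if (!is.na(x$Z))
    cat(sprintf("  observed X = %d -> Z = %.2f, p(normal) = %.3g, p(empirical) = %.3g\n",
                x$X, x$Z, x$p, x$p_empirical))
  invisible(x)
}
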