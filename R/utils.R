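## Shared internal helpers: distances, RMSD, residue-set parsing, graph
## components, simple matrix export.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Pairwise Euclidean distance matrix for an N x 3 coordinate matrix.
pair_dist <- function(xyz) {
  g <- tcrossprod(xyz)
  d2 <- outer(diag(g), diag(g), "+") - 2 * g
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Plain coordinate RMSD between two already-aligned N x 3 matrices.
coord_rmsd <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  sqrt(mean(rowSums((x - y)^2)))
}

assert_coords <- function(xyz, n_min = 2L, what = "coords") {
  if (!is.matrix(xyz) || ncol(xyz) != 3)
    stop(what, " must be an N x 3 matrix", call. = FALSE)
  if (nrow(xyz) < n_min)
    stop(what, " must have at least ", n_min, " rows", call. = FALSE)
  if (!all(is.finite(xyz)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(xyz)
}

## Connected components of an undirected adjacency matrix (logical or 0/1),
## by breadth-first search. Returns an integer membership vector.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Parse a residue-set specification
#'
#' Residue sets are given as whitespace- or comma-separated author residue
#' numbers with an optional chain prefix, e.g. `"A:551"` or `"551 563 1370"`.
#' A path to a plain-text file with the same tokens is also accepted.
#'
#' @param x Character vector of tokens, a single string, or a file path.
#' @return A data frame with columns `chain` (NA when no prefix was given)
#'   and `resno` (integer author numbering).
#' @export
parse_residue_set <- function(x) {
  if (length(x) == 1L && file.exists(x) && !grepl("[,: ]", x))
    x <- readLines(x, warn = FALSE)
  tokens <- unlist(strsplit(x, "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!grepl("^#", tokens)]
  if (!length(tokens)) stop("empty residue set", call. = FALSE)
  chain <- rep(NA_character_, length(tokens))
  has_chain <- grepl(":", tokens, fixed = TRUE)
  chain[has_chain] <- sub(":.*$", "", tokens[has_chain])
  resno <- suppressWarnings(as.integer(sub("^.*:", "", tokens)))
  if (anyNA(resno)) stop("unparsable residue tokens: ",
                         paste(tokens[is.na(resno)], collapse = ", "),
                         call. = FALSE)
  data.frame(chain = chain, resno = resno, stringsAsFactors = FALSE)
}

#' Write a numeric matrix as CSV
#'
#' Row and column names are preserved; the first column holds row names.
#'
#' @param m Numeric matrix.
#' @param path Output file.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(row = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_csv()]
#' @param path CSV file path.
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

## Map structure residues referenced by (chain, resno) to row indices of the
## model. `ref` is a data frame from parse_residue_set(). Unresolvable
## entries are dropped with a warning.
resolve_residues <- function(model, ref) {
  keys <- paste(model$residues$chain, model$residues$resno, sep = ":")
  want <- ifelse(is.na(ref$chain),
                 as.character(ref$resno),
                 paste(ref$chain, ref$resno, sep = ":"))
  idx <- integer(0)
  miss <- character(0)
  for (k in seq_along(want)) {
    hit <- if (is.na(ref$chain[k])) {
      which(model$residues$resno == ref$resno[k])
    } else {
      which(keys == want[k])
    }
    if (length(hit)) idx <- c(idx, hit[1L]) else miss <- c(miss, want[k])
  }
  if (length(miss))
    warning("dropped unresolvable reference residues: ",
            paste(miss, collapse = ", "), call. = FALSE)
  if (!length(idx)) stop("no reference residues resolved", call. = FALSE)
  unique(idx)
}
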