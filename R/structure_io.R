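## Structure input/output: parsing PDB/mmCIF files to C-alpha models,
## residue mapping between conformers, Kabsch superposition, ligand-contact
## detection and score-painted PDB output. File parsing is delegated to
## bio3d; this layer only shapes the result into the package's model object.

#' Construct a structure model from raw parts
#'
#' Mostly used by the synthetic-structure generators; [read_structure()] is
#' the entry point for real files.
#'
#' @param xyz N x 3 matrix of C-alpha coordinates (Angstrom).
#' @param chain Chain identifier(s), recycled to N.
#' @param resno Author residue numbers (default `1:N`).
#' @param resid Residue names, recycled (default `"ALA"`).
#' @param insert Insertion codes (default none).
#' @param source Character label recording provenance.
#' @return An object of class `structure_model` with elements `residues`
#'   (data frame: chain, resno, insert, resid), `xyz`, `het` (heteroatom
#'   table or NULL) and `source`.
#' @export
structure_model <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                            resid = "ALA", insert = "", source = "in-memory") {
  assert_coords(xyz, n_min = 2L, what = "xyz")
  n <- nrow(xyz)
  residues <- data.frame(chain = rep_len(as.character(chain), n),
                         resno = as.integer(resno),
                         insert = rep_len(as.character(insert), n),
                         resid = rep_len(as.character(resid), n),
                         stringsAsFactors = FALSE)
  key <- paste(residues$chain, residues$resno, residues$insert)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue number, insertion) keys", call. = FALSE)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(residues = residues, xyz = xyz, het = NULL, source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure model:", nrow(x$xyz), "residues,",
      length(unique(x$residues$chain)), "chain(s)",
      if (!is.null(x$het)) sprintf("(+%d heteroatoms)", nrow(x$het)) else "",
      "\n  source:", x$source, "\n")
  invisible(x)
}

residue_keys <- function(model) {
  with(model$residues, paste(chain, resno, insert, sep = "_"))
}

#' Read a protein structure as a C-alpha model
#'
#' Parses a PDB or mmCIF file (by extension: `.cif`/`.mmcif` are mmCIF,
#' anything else PDB), keeps one record per residue possessing a C-alpha
#' atom in chain/sequence order, and retains heteroatoms separately for
#' ligand-contact queries. For atoms with alternate locations the highest
#' occupancy conformer is kept.
#'
#' @param path File path.
#' @param model_index Model (frame) to use for multi-model files; default 1.
#' @param chains Optional character vector restricting to these chain ids.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, model_index = 1L, chains = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  is_cif <- grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, multi = model_index > 1L, verbose = FALSE)
  atoms <- pdb$atom
  if (model_index > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index)
      stop("model_index ", model_index, " not present in ", path, call. = FALSE)
    xyz_frame <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    atoms$x <- xyz_frame[, 1]; atoms$y <- xyz_frame[, 2]; atoms$z <- xyz_frame[, 3]
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  if (!nrow(atoms)) stop("empty selection after chain filter", call. = FALSE)
  ## altloc: keep highest occupancy per (chain, resno, insert, atom name)
  akey <- with(atoms, paste(chain, resno, insert, elety))
  ord <- order(akey, -atoms$o)
  atoms <- atoms[ord, , drop = FALSE][!duplicated(akey[ord]), , drop = FALSE]
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resno, atoms$insert), , drop = FALSE]
  het <- atoms[atoms$type == "HETATM", , drop = FALSE]
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) < 2)
    stop("fewer than two residues with C-alpha atoms in ", path, call. = FALSE)
  m <- structure_model(as.matrix(ca[, c("x", "y", "z")]),
                       chain = ca$chain, resno = ca$resno,
                       resid = ca$resid, insert = ca$insert,
                       source = sprintf("%s (model %d)", path, model_index))
  m$het <- if (nrow(het)) het else NULL
  ## full protein atom table kept for heavy-atom contact queries
  m$protein_atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  m
}

## Parse exclusion ranges given as "A:708-855" / "708-855" strings, or a
## list of c(chain, from, to). Returns data frame chain/from/to.
parse_ranges <- function(exclude) {
  if (is.null(exclude) || !length(exclude)) return(NULL)
  if (is.list(exclude))
    exclude <- vapply(exclude, function(e) paste(e, collapse = ":"), "")
  out <- lapply(exclude, function(tok) {
    chain <- NA_character_
    if (grepl(":", tok)) {
      chain <- sub(":.*$", "", tok)
      tok <- sub("^.*:", "", tok)
    }
    ft <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
    if (length(ft) == 1L) ft <- c(ft, ft)
    data.frame(chain = chain, from = ft[1], to = ft[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract the C-alpha coordinate matrix, with optional exclusions
#'
#' @param model A `structure_model`.
#' @param exclude Residue ranges in author numbering, e.g.
#'   `c("A:708-855")` or `"708-855"` (all chains); NULL keeps everything.
#' @return List with `xyz` (M x 3), `index` (row indices into the model)
#'   and `keys` (residue identity strings).
#' @export
extract_ca <- function(model, exclude = NULL) {
  keep <- rep(TRUE, nrow(model$xyz))
  rng <- parse_ranges(exclude)
  if (!is.null(rng)) {
    for (r in seq_len(nrow(rng))) {
      hit <- model$residues$resno >= rng$from[r] & model$residues$resno <= rng$to[r]
      if (!is.na(rng$chain[r])) hit <- hit & model$residues$chain == rng$chain[r]
      keep[hit] <- FALSE
    }
  }
  if (!any(keep)) stop("exclusion removed all residues", call. = FALSE)
  list(xyz = model$xyz[keep, , drop = FALSE],
       index = which(keep),
       keys = residue_keys(model)[keep])
}

#' Map residues common to two structure models
#'
#' Residues are matched by (chain, author number, insertion code); the
#' result is ordered as in `a`.
#'
#' @param a,b `structure_model` objects.
#' @return Object of class `residue_map`: data frame with columns `ia`,
#'   `ib` (row indices into a and b) and `key`.
#' @export
map_common_residues <- function(a, b) {
  ka <- residue_keys(a); kb <- residue_keys(b)
  common <- ka[ka %in% kb]
  if (!length(common)) stop("no residues in common", call. = FALSE)
  out <- data.frame(ia = match(common, ka), ib = match(common, kb),
                    key = common, stringsAsFactors = FALSE)
  class(out) <- c("residue_map", class(out))
  out
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `y %*% R + t` to `x` over paired rows.
#'
#' @param x,y M x 3 coordinate matrices with corresponding rows (M >= 3).
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3), `rmsd` (Angstrom) and `yfit` (transformed y).
#' @export
kabsch_superpose <- function(x, y) {
  assert_coords(x, 3L, "x"); assert_coords(y, 3L, "y")
  stopifnot(nrow(x) == nrow(y))
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  a <- crossprod(yc, xc)
  sv <- svd(a)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2)
    stop("degenerate (collinear or coincident) point sets", call. = FALSE)
  s <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  yfit <- yc %*% rot
  rmsd <- sqrt(mean(rowSums((yfit - xc)^2)))
  yfit <- sweep(yfit, 2, cx, "+")
  list(rotation = rot, translation = cx - as.vector(cy %*% rot),
       rmsd = rmsd, yfit = yfit)
}

#' Residues in heavy-atom contact with a ligand
#'
#' Detects residues with any heavy atom within `cutoff` of any heavy atom
#' of the named heteroatom group(s). Binding-residue sets can instead be
#' supplied explicitly as residue-set files when a curated list is
#' preferred; this function is the geometric route.
#'
#' @param path Structure file path or a `structure_model` from
#'   [read_structure()] (which retains heteroatoms).
#' @param ligands Character vector of heteroatom residue names, e.g.
#'   `c("ATP")`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return Data frame of contact residues (chain, resno).
#' @export
ligand_contact_residues <- function(path, ligands, cutoff = 4.5) {
  model <- if (inherits(path, "structure_model")) path else read_structure(path)
  if (is.null(model$het)) stop("structure has no heteroatoms", call. = FALSE)
  lig <- model$het[model$het$resid %in% ligands, , drop = FALSE]
  lig <- lig[!grepl("^H", lig$elety), , drop = FALSE]
  if (!nrow(lig)) stop("ligand(s) not found: ",
                       paste(ligands, collapse = ", "), call. = FALSE)
  prot <- model$protein_atoms
  if (is.null(prot)) stop("model lacks the protein atom table", call. = FALSE)
  prot <- prot[!grepl("^H", prot$elety), , drop = FALSE]
  pl <- as.matrix(lig[, c("x", "y", "z")])
  pp <- as.matrix(prot[, c("x", "y", "z")])
  ## min distance from each protein atom to any ligand atom
  d2 <- outer(rowSums(pp^2), rowSums(pl^2), "+") - 2 * pp %*% t(pl)
  hit <- apply(d2, 1, min) <= cutoff^2 + 1e-9
  res <- unique(prot[hit, c("chain", "resno")])
  rownames(res) <- NULL
  res[order(res$chain, res$resno), , drop = FALSE]
}

#' Write a C-alpha PDB with per-residue scores in the B-factor column
#'
#' Scores are clipped to the PDB field range (two decimals, max 999.99);
#' missing values are written as 0.
#'
#' @param model A `structure_model`.
#' @param scores Numeric vector, one value per residue (NA allowed).
#' @param path Output PDB path.
#' @export
write_painted_structure <- function(model, scores, path) {
  n <- nrow(model$xyz)
  if (length(scores) != n)
    stop("scores length (", length(scores), ") != residues (", n, ")",
         call. = FALSE)
  b <- ifelse(is.finite(scores), scores, 0)
  b <- pmin(pmax(b, -99.99), 999.99)
  xyz <- as.vector(t(model$xyz))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", n),
                   resno = model$residues$resno,
                   resid = model$residues$resid,
                   chain = model$residues$chain,
                   insert = model$residues$insert,
                   elety = rep("CA", n),
                   b = round(b, 2), o = rep(1, n))
  invisible(path)
}
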