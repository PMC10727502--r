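## Shared fixtures, generated in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

## Standard two-domain toy used across modules.
toy_system <- function() cached("toy", make_two_domain_toy(30, 6, seed = 2))

## Toy with a loosely packed second domain (lower connectivity).
toy_loose <- function(seed = 3)
  cached(paste0("toy_loose_", seed),
         make_two_domain_toy(30, 6, seed = seed, radius_factor = c(1, 1.6)))

## Small heterogeneous system (compact 5-node cluster + 3-node tail)
## with sizable transfer entropies; used by the oracle checks.
cluster_tail_coords <- function() {
  set.seed(3)
  cl <- matrix(stats::rnorm(15, sd = 2.5), 5, 3)
  tail <- rbind(c(6, 0, 0), c(11, 0, 0), c(16, 0, 0))
  rbind(cl, sweep(tail, 2, colMeans(cl), "+"))
}

## Hand-written 3-residue PDB (plus one ATP phosphorus) as text.
tiny_pdb_lines <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
  "ATOM      3  CA  GLY A   2       5.000   1.000   0.000  1.00 20.00           C",
  "ATOM      4  CA  SER A   3       8.000   2.000   1.000  1.00 30.00           C",
  "HETATM    5  P   ATP A 101       9.000   2.500   1.200  1.00  0.00           P",
  "END")

## The same three residues in mmCIF dialect.
tiny_cif_lines <- function() c(
  "data_toy", "#", "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
  "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
  "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
  "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
  "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 10.00 ? 1 ALA A CA 1",
  "ATOM 2 C CA . GLY A 1 2 ? 5.000 1.000 0.000 1.00 20.00 ? 2 GLY A CA 1",
  "ATOM 3 C CA . SER A 1 3 ? 8.000 2.000 1.000 1.00 30.00 ? 3 SER A CA 1",
  "#")

write_tempfile <- function(lines, ext) {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

## Random proper rotation matrix.
random_rotation <- function() {
  qr_q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}
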