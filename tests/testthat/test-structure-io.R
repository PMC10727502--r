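test_that("a hand-written PDB parses to the expected C-alpha model", {
  tf <- write_tempfile(tiny_pdb_lines(), ".pdb")
  m <- read_structure(tf)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$xyz), 3L)
  expect_equal(m$residues$resno, 1:3)
  expect_equal(m$residues$resid, c("ALA", "GLY", "SER"))
  expect_equal(unname(m$xyz[, 1]), c(1.458, 5, 8))
  expect_equal(nrow(m$het), 1L)  # ATP retained separately
})

test_that("the mmCIF dialect yields an identical model", {
  mp <- read_structure(write_tempfile(tiny_pdb_lines(), ".pdb"))
  mc <- read_structure(write_tempfile(tiny_cif_lines(), ".cif"))
  expect_equal(mc$residues$resno, mp$residues$resno)
  expect_equal(mc$residues$chain, mp$residues$chain)
  expect_equal(unname(mc$xyz), unname(mp$xyz), tolerance = 1e-6)
})

test_that("synthetic structures survive a PDB write/read round trip", {
  toy <- toy_system()
  sm <- as_structure_model(toy)
  tf <- tempfile(fileext = ".pdb")
  write_painted_structure(sm, rep(0, nrow(sm$xyz)), tf)
  m2 <- read_structure(tf)
  expect_equal(nrow(m2$xyz), nrow(sm$xyz))
  expect_lt(max(abs(m2$xyz - sm$xyz)), 1e-3)  # PDB precision
  expect_equal(m2$residues$chain, sm$residues$chain)
})

test_that("extract_ca applies author-numbered exclusion ranges", {
  toy <- toy_system()
  sm <- as_structure_model(toy)
  all_rows <- extract_ca(sm)
  expect_equal(nrow(all_rows$xyz), nrow(sm$xyz))
  ## drop residues 5-10 of chain A from a 20-residue slice pattern
  ex <- extract_ca(sm, exclude = "A:5-10")
  expect_equal(nrow(ex$xyz), nrow(sm$xyz) - 6L)
  expect_false(any(sm$residues$resno[ex$index] %in% 5:10 &
                     sm$residues$chain[ex$index] == "A"))
  ## excluding the linker mimics dropping an unmodeled regulatory domain
  rng <- sprintf("A:%d-%d", min(toy$linker), max(toy$linker))
  ex2 <- extract_ca(sm, exclude = rng)
  expect_equal(nrow(ex2$xyz), nrow(sm$xyz) - length(toy$linker))
  expect_error(extract_ca(sm, exclude = sprintf("1-%d", nrow(sm$xyz))),
               "removed all")
})

test_that("residue mapping is the key intersection, in first-model order", {
  toy <- toy_system()
  a <- as_structure_model(toy)
  expect_equal(nrow(map_common_residues(a, a)), nrow(a$xyz))
  ## drop 3 residues from b, with staggered gaps
  keep <- setdiff(seq_len(nrow(a$xyz)), c(4L, 17L, 40L))
  b <- structure_model(a$xyz[keep, ], chain = a$residues$chain[keep],
                       resno = a$residues$resno[keep])
  mab <- map_common_residues(a, b)
  expect_equal(nrow(mab), nrow(a$xyz) - 3L)
  ## brute-force set intersection oracle
  ka <- paste(a$residues$chain, a$residues$resno)
  kb <- paste(b$residues$chain, b$residues$resno)
  expect_equal(mab$ia, which(ka %in% kb))
  ## symmetry: reversing the (b, a) map recovers the same pairing
  mba <- map_common_residues(b, a)
  expect_equal(mab$ia, mba$ib[match(mab$key, mba$key)])
  expect_equal(mab$ib, mba$ia[match(mab$key, mba$key)])
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(7)
  x <- matrix(rnorm(30, sd = 5), 10, 3)
  fit0 <- kabsch_superpose(x, x)
  expect_lt(fit0$rmsd, 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)
  ## 90 degree rotation about z plus translation
  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  y <- sweep(x %*% t(rz), 2, c(3, -2, 5), "+")
  fit <- kabsch_superpose(x, y)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$yfit - x)), 1e-8)
})

test_that("Kabsch RMSD is invariant under proper rigid transforms", {
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(36, sd = 6), 12, 3)
    y <- x + matrix(rnorm(36, sd = 1), 12, 3)
    base <- kabsch_superpose(x, y)$rmsd
    r <- random_rotation()
    y2 <- sweep(y %*% t(r), 2, rnorm(3, sd = 20), "+")
    expect_equal(kabsch_superpose(x, y2)$rmsd, base, tolerance = 1e-8)
    x2 <- sweep(x %*% t(random_rotation()), 2, rnorm(3, sd = 20), "+")
    expect_equal(kabsch_superpose(x2, y)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("kabsch agrees with the bio3d reference superposition", {
  set.seed(5)
  x <- matrix(rnorm(45, sd = 8), 15, 3)
  y <- x + matrix(rnorm(45, sd = 2), 15, 3)
  ours <- kabsch_superpose(x, y)$rmsd
  xf <- bio3d::fit.xyz(fixed = as.vector(t(x)), mobile = as.vector(t(y)))
  ref <- bio3d::rmsd(as.vector(t(x)), xf)
  expect_equal(ours, ref, tolerance = 1e-4)
})

test_that("ligand contacts follow the heavy-atom distance rule", {
  tf <- write_tempfile(tiny_pdb_lines(), ".pdb")
  hits <- ligand_contact_residues(tf, "ATP", cutoff = 4.5)
  expect_setequal(hits$resno, c(2L, 3L))
  expect_equal(ligand_contact_residues(tf, "ATP", cutoff = 2)$resno, 3L)
  expect_equal(nrow(ligand_contact_residues(tf, "ATP", cutoff = 0.5)), 0L)
  expect_error(ligand_contact_residues(tf, "GTP"), "not found")
})

test_that("planted ligand contacts match a brute-force distance oracle", {
  set.seed(9)
  toy <- toy_system()
  sm <- as_structure_model(toy)
  ## plant a fake ligand atom near residue 12
  lig_xyz <- sm$xyz[12, ] + c(3, 0.5, 0)
  tf <- tempfile(fileext = ".pdb")
  write_painted_structure(sm, rep(0, nrow(sm$xyz)), tf)
  lines <- readLines(tf)
  het <- sprintf(
    "HETATM%5d  P   ATP A%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
    9999, 999, lig_xyz[1], lig_xyz[2], lig_xyz[3])
  writeLines(append(lines, het, after = length(lines) - 1L), tf)
  hits <- ligand_contact_residues(tf, "ATP", cutoff = 4.5)
  d <- sqrt(rowSums(sweep(sm$xyz, 2, lig_xyz)^2))
  oracle <- sm$residues$resno[d <= 4.5 + 1e-3]
  expect_setequal(hits$resno, oracle)
})

test_that("painted B-factors round trip to 0.01", {
  toy <- toy_system()
  sm <- as_structure_model(toy)
  scores <- seq_len(nrow(sm$xyz)) / 7
  tf <- tempfile(fileext = ".pdb")
  write_painted_structure(sm, scores, tf)
  m2 <- read_structure(tf)
  expect_lt(max(abs(m2$protein_atoms$b - scores)), 0.01 + 1e-9)
  ## monotone scores stay monotone
  expect_true(all(diff(m2$protein_atoms$b) >= 0))
  expect_error(write_painted_structure(sm, scores[-1], tempfile()),
               "length")
})

test_that("residue-set parsing accepts chain prefixes and files", {
  rs <- parse_residue_set(c("A:551", "563", "B:1370"))
  expect_equal(rs$resno, c(551L, 563L, 1370L))
  expect_equal(rs$chain, c("A", NA, "B"))
  tf <- tempfile()
  writeLines("A:10, A:20\n30", tf)
  rs2 <- parse_residue_set(tf)
  expect_equal(rs2$resno, c(10L, 20L, 30L))
  expect_error(parse_residue_set("A:xx"), "unparsable")
})
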