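test_that("format detection maps extensions case-insensitively", {
  expect_equal(detect_format("poses.pdbqt"), "pdbqt")
  expect_equal(detect_format("ligand.SDF"), "sdf")
  expect_equal(detect_format("x.sd"), "sdf")
  expect_equal(detect_format("structure.ent"), "pdb")
  expect_equal(detect_format("poses.Mol2.gz"), "mol2")
  expect_error(detect_format("notes.txt"), class = "dockpose_format_error")
  expect_error(detect_format("noextension"), class = "dockpose_format_error")
})

test_that("multi-record SDF files split into one graph per record", {
  mols <- lapply(1:10, function(s) generate_molecule(6, seed = s))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_structures(mols, f, "sdf")
  back <- read_structures(f)
  expect_length(back, 10)
  expect_equal(back[[3]]$name, mols[[3]]$name)
})

test_that("SDF write/read round-trips elements, bonds and coordinates", {
  for (s in 1:25) {
    mol <- generate_molecule(3 + s %% 10, seed = 3000 + s)
    f <- tempfile(fileext = ".sdf")
    write_structures(mol, f, "sdf")
    back <- read_structures(f)[[1]]
    unlink(f)
    expect_equal(back$atoms$element, mol$atoms$element, info = paste("seed", s))
    expect_equal(
      as.data.frame(back$bonds[order(back$bonds$i, back$bonds$j), ]),
      as.data.frame(mol$bonds[order(mol$bonds$i, mol$bonds$j), ]),
      ignore_attr = TRUE, info = paste("seed", s))
    expect_lt(max(abs(coords(back) - coords(mol))), 5.1e-4)
  }
})

test_that("the V2000 counts line and record grammar are respected", {
  mol <- propane_mol()
  lines <- write_structures(mol, NULL, "sdf")
  expect_match(lines[4], "^  3  2")
  expect_equal(lines[length(lines)], "$$$$")
  # single carbon at the origin is a valid one-record file
  solo <- molgraph(data.frame(element = "C", x = 0, y = 0, z = 0))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_structures(solo, f, "sdf")
  back <- read_structures(f)[[1]]
  expect_equal(n_atoms(back), 1)
  expect_equal(back$atoms$element, "C")
})

test_that("oversized and malformed SDF records are rejected with the record index", {
  big <- molgraph(data.frame(element = "C",
                             x = 10 * seq_len(1000), y = 0, z = 0))
  expect_error(write_structures(big, NULL, "sdf"),
               class = "dockpose_capacity_error")

  mol <- generate_molecule(5, seed = 1)
  lines <- write_structures(mol, NULL, "sdf")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(lines, lines[1:6], "$$$$"), f)  # record 2 truncated
  expect_error(read_structures(f), regexp = "record 2",
               class = "dockpose_parse_error")

  f2 <- withr::local_tempfile(fileext = ".sdf")
  v3k <- c("name", "", "", "  0  0  0  0  0  0  0  0  0  0999 V3000",
           "M  END", "$$$$")
  writeLines(v3k, f2)
  expect_error(read_structures(f2), regexp = "V3000",
               class = "dockpose_parse_error")
})

test_that("Vina PDBQT models split and carry one score each", {
  base <- generate_molecule(8, ring_prob = 0, double_prob = 0, seed = 11)
  f <- withr::local_tempfile(fileext = ".pdbqt")
  ps <- generate_pose_set(base, k = 2, sizes = c(3, 2), seed = 12, path = f)
  poses <- read_structures(f)
  expect_length(poses, 5)
  sc <- extract_scores(f, "vina")
  expect_equal(sc$pose_index, 1:5)
  expect_equal(sc$score, ps$scores)
  expect_true(all(sc$source_tag == "REMARK VINA RESULT"))
  # pose order in the file equals the score-record pose indices
  expect_equal(order(sc$pose_index), seq_along(poses))
})

test_that("the Vina score grammar takes the first numeric field", {
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL 1",
    "REMARK VINA RESULT:    -7.5      0.000      0.000",
    "ATOM      1  C   LIG A   1       0.000   0.000   0.000  0.00  0.00    +0.000 C ",
    "ATOM      2  OA  LIG A   1       1.400   0.000   0.000  0.00  0.00    -0.300 OA",
    "ENDMDL"), f)
  mols <- read_structures(f)
  expect_equal(mols[[1]]$atoms$element, c("C", "O"))
  expect_equal(extract_scores(f, "vina")$score, -7.5)
})

test_that("AutoDock atom types map to elements", {
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL 1",
    "REMARK VINA RESULT:    -1.0      0.000      0.000",
    "ATOM      1  N1  LIG A   1       0.000   0.000   0.000  0.00  0.00    +0.000 NA",
    "ATOM      2  C1  LIG A   1       1.400   0.000   0.000  0.00  0.00    +0.000 A ",
    "ATOM      3 CL1  LIG A   1       3.400   0.000   0.000  0.00  0.00    +0.000 Cl",
    "ENDMDL"), f)
  mols <- read_structures(f)
  expect_equal(mols[[1]]$atoms$element, c("N", "C", "Cl"))
})

test_that("OpenEye-style SDF score tags are found in order, with fallback warning", {
  mol <- generate_molecule(5, seed = 2)
  mol$properties <- c(Chemgauss4 = "-10.2")
  mol2 <- generate_molecule(5, seed = 3)
  mol2$properties <- c(docking_score = "-8.1")
  f <- withr::local_tempfile(fileext = ".sdf")
  write_structures(list(mol, mol2), f, "sdf")
  sc <- extract_scores(f, "hybrid")
  expect_equal(sc$score, c(-10.2, -8.1))
  expect_equal(sc$source_tag, c("Chemgauss4", "docking_score"))

  mol$properties <- c(unrelated_tag = "1")
  f2 <- withr::local_tempfile(fileext = ".sdf")
  write_structures(mol, f2, "sdf")
  expect_warning(sc2 <- extract_scores(f2, "fred"), regexp = "no score")
  expect_true(is.na(sc2$score))

  # program/format dialect mismatch is a user error
  expect_error(extract_scores(f2, "vina"), class = "dockpose_user_error")
})

test_that("MOL2 records parse with aromatic bonds and multi-record splitting", {
  mol2_text <- c(
    "@<TRIPOS>MOLECULE", "benzene", " 6 6 1", "SMALL", "NO_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("%7d C%d %10.4f %10.4f %10.4f C.ar 1 LIG 0.0000",
            1:6, 1:6, 1.396 * cos(2 * pi * (0:5) / 6),
            1.396 * sin(2 * pi * (0:5) / 6), rep(0, 6)),
    "@<TRIPOS>BOND",
    sprintf("%6d %5d %5d ar", 1:6, 1:6, c(2:6, 1)))
  f <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c(mol2_text, mol2_text), f)
  mols <- read_structures(f)
  expect_length(mols, 2)
  expect_equal(mols[[1]]$atoms$element, rep("C", 6))
  expect_true(all(mols[[1]]$bonds$order == "aromatic"))
})

test_that("PDB models read through with perceived bonds and residue labels", {
  base <- generate_molecule(7, ring_prob = 0, double_prob = 0, seed = 21)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structures(list(base, translate_mol(base, 3)), f, "pdb")
  mols <- read_structures(f)
  expect_length(mols, 2)
  expect_equal(mols[[1]]$atoms$element, base$atoms$element)
  topo <- function(m) m$bonds[order(m$bonds$i, m$bonds$j), c("i", "j")]
  expect_equal(as.data.frame(topo(mols[[1]])), as.data.frame(topo(base)),
               ignore_attr = TRUE)
  expect_true(all(mols[[1]]$atoms$resid == "LIG"))
})

test_that("gzipped input is accepted", {
  mol <- generate_molecule(6, seed = 31)
  f <- paste0(tempfile(), ".sdf.gz")
  con <- gzfile(f, "wt")
  writeLines(write_structures(mol, NULL, "sdf"), con)
  close(con)
  back <- read_structures(f)[[1]]
  unlink(f)
  expect_equal(back$atoms$element, mol$atoms$element)
})

test_that("parsing is deterministic", {
  mols <- lapply(1:3, function(s) generate_molecule(7, seed = 40 + s))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_structures(mols, f, "sdf")
  expect_identical(read_structures(f), read_structures(f))
})
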