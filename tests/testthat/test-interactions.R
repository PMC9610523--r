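# receptor fragments built in code with PDB-style residue labels

rec_fragment <- function(elements, xyz, names, resid = "SER", resno = 152,
                         chain = "A", bonds = NULL) {
  molgraph(tibble::tibble(element = elements,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          atom_name = names, resid = resid, resno = resno,
                          chain = chain),
           bonds)
}

test_that("a donor-acceptor pair at hydrogen-bond geometry is reported", {
  # ligand N-H donor pointing at a receptor hydroxyl O, D...A = 2.9 A,
  # D-H...A angle 160 degrees
  h <- c(1.0 * cos(20 * pi / 180), 1.0 * sin(20 * pi / 180), 0)
  lig <- molgraph(tibble::tibble(element = c("N", "H"),
                                 x = c(0, h[1]), y = c(0, h[2]), z = 0),
                  data.frame(i = 1, j = 2, order = "single"))
  rec <- rec_fragment("O", matrix(c(2.9, 0, 0), 1), "OG")
  res <- detect_interactions(rec, lig, kinds = "hbond")
  expect_equal(nrow(res), 1)
  expect_equal(res$kind, "hbond")
  expect_equal(res$distance, 2.9, tolerance = 1e-9)
  expect_gt(res$angle, 145)  # H sits 20 degrees off the N...O axis
  expect_equal(res$residue, "SER152.A")

  # hydrogen pointing away from the acceptor: D-H...A angle fails.  A
  # thiol sulfur is acceptor-only, so no distance-only reverse record.
  sg <- rec_fragment("S", matrix(c(2.9, 0, 0), 1), "SG", resid = "CYS")
  lig2 <- lig
  lig2$atoms$x[2] <- -1
  lig2$atoms$y[2] <- 0
  expect_gte(nrow(detect_interactions(sg, lig, kinds = "hbond")), 1)
  expect_equal(nrow(detect_interactions(sg, lig2, kinds = "hbond")), 0)
})

test_that("distant molecules produce an empty report", {
  lig <- strip_hydrogens(ethanol_full())
  rec <- rec_fragment("O", matrix(c(15, 0, 0), 1), "OG")
  res <- detect_interactions(rec, lig)
  expect_equal(nrow(res), 0)
  expect_named(res, c("kind", "ligand_atom", "receptor_atom", "residue",
                      "distance", "angle"))
})

test_that("an amidinium nitrogen near a phosphate oxygen is an ionic contact", {
  # ligand amidinium: C bonded to two N, no O
  lig <- molgraph(
    tibble::tibble(element = c("C", "N", "N", "C"),
                   x = c(0, 1.2, -0.6, -0.6), y = c(0, 0.5, 1.1, -1.2), z = 0),
    data.frame(i = c(1, 1, 1), j = c(2, 3, 4),
               order = c("double", "single", "single")))
  # DNA backbone phosphate: P with two terminal O, one 3.4 A from ligand N2
  rec <- rec_fragment(
    c("P", "O", "O"),
    rbind(c(2.2, 2.9, 0), c(1.2, 3.9, 0), c(3.4, 3.3, 0)),
    c("P", "OP1", "OP2"), resid = "DA", resno = 7, chain = "B",
    bonds = data.frame(i = c(1, 1), j = c(2, 3), order = "single"))
  res <- detect_interactions(rec, lig, kinds = "ionic")
  expect_gte(nrow(res), 1)
  expect_true(all(res$kind == "ionic"))
  expect_true(all(res$distance <= 4.0))
  expect_true(any(res$residue == "DA7.B"))
})

test_that("parallel aromatic rings within range are pi-stacking", {
  lig <- benzene_mol()
  rec <- benzene_mol()
  rec$atoms$z <- rec$atoms$z + 3.6  # parallel offset stack
  rec$atoms <- tibble::as_tibble(cbind(rec$atoms,
    atom_name = paste0("C", 1:6), resid = "PHE", resno = 90, chain = "A"))
  res <- detect_interactions(rec, lig, kinds = "pi_stacking")
  expect_equal(nrow(res), 1)
  expect_equal(res$distance, 3.6, tolerance = 1e-6)
  expect_lt(res$angle, 5)
})

test_that("metal coordination and hydrophobic contacts obey their cutoffs", {
  zn <- rec_fragment("Zn", matrix(c(2.1, 0, 0), 1), "ZN", resid = "ZN",
                     resno = 400)
  lig <- molgraph(tibble::tibble(element = "N", x = 0, y = 0, z = 0))
  res <- detect_interactions(zn, lig, kinds = "metal")
  expect_equal(nrow(res), 1)
  expect_equal(res$distance, 2.1, tolerance = 1e-9)
  # beyond 2.8 A no coordination
  far <- rec_fragment("Zn", matrix(c(3.2, 0, 0), 1), "ZN", resid = "ZN")
  expect_equal(nrow(detect_interactions(far, lig, kinds = "metal")), 0)

  leu <- rec_fragment("C", matrix(c(3.8, 0, 0), 1), "CD1", resid = "LEU",
                      resno = 44)
  methane <- molgraph(tibble::tibble(element = "C", x = 0, y = 0, z = 0))
  hyd <- detect_interactions(leu, methane, kinds = "hydrophobic")
  expect_equal(nrow(hyd), 1)
})

test_that("kind restriction yields exactly the matching subset", {
  lig <- molgraph(
    tibble::tibble(element = c("N", "C", "C"),
                   x = c(0, 1.4, 2.9), y = 0, z = 0),
    data.frame(i = 1:2, j = 2:3, order = "single"))
  rec <- rec_fragment(c("O", "C"), rbind(c(0, 3.0, 0), c(2.9, 3.4, 0)),
                      c("OG", "CB"))
  full <- detect_interactions(rec, lig)
  only_hb <- detect_interactions(rec, lig, kinds = "hbond")
  expect_equal(only_hb, full[full$kind == "hbond", ])
  only_ph <- detect_interactions(rec, lig, kinds = "hydrophobic")
  expect_equal(only_ph$kind, full$kind[full$kind == "hydrophobic"])
})

test_that("the report is stable under ligand relabelling", {
  lig <- molgraph(
    tibble::tibble(element = c("N", "C", "O"),
                   x = c(0, 1.4, 2.4), y = c(0, 0.4, 1.4), z = 0),
    data.frame(i = 1:2, j = 2:3, order = "single"))
  rec <- rec_fragment(c("O", "N"), rbind(c(0, 3.1, 0), c(2.5, 4.3, 0)),
                      c("OD1", "ND2"), resid = "ASN", resno = 60)
  a <- detect_interactions(rec, lig)
  b <- detect_interactions(rec, permute_atoms(lig, seed = 8))
  # identical records once identified by geometry, not input order
  cols <- c("kind", "receptor_atom", "residue", "distance")
  expect_equal(a[cols], b[cols])
})

test_that("a receptor without residue labels warns and reports indices", {
  rec <- molgraph(tibble::tibble(element = "O", x = 3.0, y = 0, z = 0))
  lig <- molgraph(tibble::tibble(element = "N", x = 0, y = 0, z = 0))
  expect_warning(res <- detect_interactions(rec, lig, kinds = "hbond"),
                 regexp = "residue labels")
  expect_equal(nrow(res), 1)
  expect_true(is.na(res$residue))
})
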