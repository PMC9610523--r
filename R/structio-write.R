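# Writers for SDF (V2000), PDB and Vina-style PDBQT.  Coordinates are
# written at the V2000/PDB precision of 3-4 decimals, which bounds the
# round-trip fidelity documented in write_structures().

#' Write molecules to a chemical file
#'
#' Serialises a list of [molgraph] objects as a multi-record SDF (V2000), a
#' multi-MODEL PDB, or a Vina-dialect PDBQT.  SDF round-trips elements, bonds
#' and coordinates (to 3 decimals) through [read_structures()]; PDB and PDBQT
#' carry no bond table, so bonds survive a round trip only insofar as distance
#' perception recovers them.  Molecule `properties` become SDF data tags; a
#' `vina_score` property becomes a `REMARK VINA RESULT:` line in PDBQT.
#'
#' @param mols A [molgraph] or list of them.
#' @param path Output file; when `NULL` the text is returned invisibly
#'   without writing.
#' @param format `"sdf"`, `"pdb"` or `"pdbqt"`.
#' @return Invisibly, the character vector of file lines.
#' @export
write_structures <- function(mols, path = NULL,
                             format = c("sdf", "pdb", "pdbqt")) {
  format <- match.arg(format)
  if (inherits(mols, "molgraph")) mols <- list(mols)
  stopifnot(length(mols) > 0, all(vapply(mols, inherits, logical(1), "molgraph")))
  lines <- switch(format,
    sdf = unlist(lapply(mols, format_sdf_record)),
    pdb = format_pdb_models(mols, qt = FALSE),
    pdbqt = format_pdb_models(mols, qt = TRUE))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

format_sdf_record <- function(mol) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  if (n > 999 || nb > 999) {
    abort(paste0("V2000 connection tables are limited to 999 atoms/bonds (",
                 n, " atoms, ", nb, " bonds)"), class = "dockpose_capacity_error")
  }
  header <- c(mol$name, "  dockpose", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        mol$atoms$x, mol$atoms$y, mol$atoms$z, mol$atoms$element)
  order_code <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
  bond_lines <- if (nb == 0) character() else
    sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
            order_code[mol$bonds$order])
  prop_lines <- character()
  if (length(mol$properties) > 0) {
    prop_lines <- unlist(lapply(names(mol$properties), function(tag) {
      c(paste0("> <", tag, ">"), as.character(mol$properties[[tag]]), "")
    }))
  }
  c(header, counts, atom_lines, bond_lines, "M  END", prop_lines, "$$$$")
}

format_pdb_models <- function(mols, qt = FALSE) {
  multi <- length(mols) > 1 || qt
  out <- character()
  for (mi in seq_along(mols)) {
    mol <- mols[[mi]]
    if (multi) out <- c(out, sprintf("MODEL %8d", mi))
    if (qt) {
      sc <- mol$properties[["vina_score"]]
      if (!is.null(sc)) {
        out <- c(out, sprintf("REMARK VINA RESULT:%10.3f%11.3f%11.3f",
                              as.numeric(sc), 0, 0))
      }
    }
    at <- mol$atoms
    name <- mol_col(at, "atom_name"); if (is.null(name)) name <- at$element
    resid <- mol_col(at, "resid"); if (is.null(resid)) resid <- "LIG"
    resno <- mol_col(at, "resno"); if (is.null(resno)) resno <- 1L
    chain <- mol_col(at, "chain"); if (is.null(chain)) chain <- "A"
    resid <- rep_len(resid, nrow(at)); resno <- rep_len(resno, nrow(at))
    chain <- rep_len(chain, nrow(at))
    resid[is.na(resid)] <- "LIG"; resno[is.na(resno)] <- 1L
    chain[is.na(chain) | !nzchar(chain)] <- "A"
    for (k in seq_len(nrow(at))) {
      nm <- name[k]
      nm_field <- if (nchar(nm) >= 4) substr(nm, 1, 4) else
        sprintf(" %-3s", nm)
      # PDB fixed columns: serial 7-11, name 13-16, resName 18-20, chain 22,
      # resSeq 23-26, x/y/z 31-54, occupancy 55-60, B 61-66
      base <- sprintf("HETATM%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                      k, nm_field, substr(resid[k], 1, 3), chain[k],
                      as.integer(resno[k]), at$x[k], at$y[k], at$z[k], 1, 0)
      if (qt) {
        type <- autodock_type(at$element[k])
        base <- paste0(base, sprintf("    %+6.3f %-2s", 0, type))
      } else {
        base <- paste0(base, sprintf("          %2s", toupper(at$element[k])))
      }
      out <- c(out, base)
    }
    out <- c(out, if (multi) "ENDMDL" else "END")
  }
  out
}

# inverse of the AutoDock type table for the elements the writer emits
autodock_type <- function(element) {
  map <- c(C = "C", N = "N", O = "OA", S = "SA", H = "H", P = "P", F = "F",
           Cl = "Cl", Br = "Br", I = "I", Zn = "Zn", Fe = "Fe", Mg = "Mg")
  out <- map[element]
  out[is.na(out)] <- toupper(element[is.na(out)])
  unname(out)
}
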