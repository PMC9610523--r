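#' Molecular graphs
#'
#' A `molgraph` is the light-weight molecule container used throughout the
#' package: atoms are nodes carrying 3D coordinates, bonds are edges carrying
#' an order class.  It is a plain list of two tibbles so that molecules can be
#' inspected and manipulated with ordinary data-frame tools.
#'
#' @param atoms A data frame with at least columns `element` (periodic-table
#'   symbol), `x`, `y`, `z` (coordinates in Angstrom).  An `orig_index` column
#'   (1-based position of each atom in the source record) is added when
#'   absent.  Optional columns such as `atom_name`, `resid`, `resno` and
#'   `chain` are preserved (they are populated when reading PDB-family files).
#' @param bonds A data frame with columns `i`, `j` (atom indices into `atoms`)
#'   and `order` (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`).
#'   May have zero rows.
#' @param name Molecule name.
#' @param properties Named character vector of free-form tag/value pairs
#'   (e.g. SDF data tags).
#'
#' @return An object of class `molgraph`.
#' @examples
#' eth <- molgraph(
#'   atoms = data.frame(element = c("C", "C", "O"),
#'                      x = c(0, 1.5, 2), y = c(0, 0, 1.35), z = 0),
#'   bonds = data.frame(i = c(1, 2), j = c(2, 3), order = "single"),
#'   name = "ethanol-heavy")
#' n_atoms(eth)
#' @export
molgraph <- function(atoms, bonds = NULL, name = "", properties = character()) {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms$element <- as.character(atoms$element)
  if (nrow(atoms) > 0 && any(!nzchar(atoms$element))) {
    abort("every atom needs a non-empty element symbol", class = "dockpose_invalid")
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0 && !all(is.finite(coords))) {
    abort("atom coordinates must be finite", class = "dockpose_invalid")
  }
  if (!"orig_index" %in% names(atoms)) atoms$orig_index <- seq_len(nrow(atoms))
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- tibble(i = integer(), j = integer(), order = character())
  } else {
    bonds <- as_tibble(bonds)
    stopifnot(all(c("i", "j") %in% names(bonds)))
    if (is.null(bonds$order)) bonds$order <- "single"
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.character(bonds$order)
    bad <- bonds$i < 1 | bonds$j < 1 |
      bonds$i > nrow(atoms) | bonds$j > nrow(atoms)
    if (any(bad)) {
      abort("bond endpoints must be valid atom indices", class = "dockpose_invalid")
    }
    if (any(bonds$i == bonds$j)) {
      abort("self-bonds are not allowed", class = "dockpose_invalid")
    }
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (anyDuplicated(bonds[, c("i", "j")])) {
      abort("duplicate bonds are not allowed", class = "dockpose_invalid")
    }
    ok <- bonds$order %in% c("single", "double", "triple", "aromatic")
    if (!all(ok)) {
      abort(paste0("unknown bond order class: ", bonds$order[!ok][1]),
            class = "dockpose_invalid")
    }
  }
  structure(list(atoms = atoms, bonds = bonds, name = name,
                 properties = properties),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", if (nzchar(x$name)) x$name else "(unnamed)",
      ": ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  counts <- table(x$atoms$element)
  cat("  formula: ",
      paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A [molgraph].
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atom coordinates as a matrix
#' @param mol A [molgraph].
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

# optional atom column accessor (tibbles warn on `$` for absent columns)
mol_col <- function(atoms, name) {
  if (name %in% names(atoms)) atoms[[name]] else NULL
}

# adjacency list: for each atom, integer vector of bonded neighbours
adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) if (is.null(v)) integer() else sort(v))
}

# order class of the bond between atoms a and b ("" when absent)
bond_order_lookup <- function(mol) {
  if (nrow(mol$bonds) == 0) return(character())
  setNames(mol$bonds$order, paste0(mol$bonds$i, "_", mol$bonds$j))
}

bond_order_between <- function(lookup, a, b) {
  if (length(lookup) == 0) return("")
  key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
  val <- lookup[key]
  if (is.na(val)) "" else unname(val)
}

#' Remove hydrogen atoms
#'
#' Hydrogens (and deuterium/tritium) never take part in atom matching or RMSD
#' calculation, so they are stripped before any comparison.  Bonds incident to
#' a hydrogen are dropped; the `orig_index` of surviving atoms is preserved so
#' results can be traced back to the source file.  Idempotent.
#'
#' @param mol A [molgraph].
#' @return A [molgraph] containing only the heavy atoms.
#' @export
strip_hydrogens <- function(mol) {
  is_h <- mol$atoms$element %in% c("H", "D", "T")
  if (!any(is_h)) return(mol)
  keep <- which(!is_h)
  new_idx <- rep(NA_integer_, n_atoms(mol))
  new_idx[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  bonds <- mol$bonds[!is_h[mol$bonds$i] & !is_h[mol$bonds$j], , drop = FALSE]
  bonds$i <- new_idx[bonds$i]
  bonds$j <- new_idx[bonds$j]
  molgraph(atoms, bonds, name = mol$name, properties = mol$properties)
}

#' Per-atom local-environment signatures
#'
#' The signature of an atom encodes (i) its element, (ii) the elements of its
#' covalently bound neighbours and (iii) the order class of those bonds, as a
#' canonical string.  Signatures are invariant under any relabelling of the
#' molecule, which is what makes them usable as a matching compatibility test.
#' The relaxed level drops the bond order classes and keeps only the
#' neighbour-element multiset, tolerating bond-order disagreements between
#' file formats.
#'
#' @param mol A [molgraph].
#' @param strict Include bond order classes in the signature (default `TRUE`).
#' @return Character vector of signatures, one per atom.
#' @examples
#' propane <- molgraph(
#'   atoms = data.frame(element = "C", x = c(0, 1.5, 3), y = 0, z = 0),
#'   bonds = data.frame(i = 1:2, j = 2:3, order = "single"))
#' atom_signatures(propane)[2]  # central carbon
#' @export
atom_signatures <- function(mol, strict = TRUE) {
  adj <- adjacency_list(mol)
  lookup <- bond_order_lookup(mol)
  vapply(seq_len(n_atoms(mol)), function(i) {
    nbrs <- adj[[i]]
    if (length(nbrs) == 0) {
      return(paste0(mol$atoms$element[i], "|"))
    }
    parts <- vapply(nbrs, function(j) {
      if (strict) {
        paste0(mol$atoms$element[j], ":", bond_order_between(lookup, i, j))
      } else {
        mol$atoms$element[j]
      }
    }, character(1))
    paste0(mol$atoms$element[i], "|", paste(sort(parts), collapse = ","))
  }, character(1))
}

#' Signature of a single atom
#' @inheritParams atom_signatures
#' @param index Atom index (1-based).
#' @return Signature string.
#' @export
atom_signature <- function(mol, index, strict = TRUE) {
  stopifnot(index >= 1, index <= n_atoms(mol))
  atom_signatures(mol, strict = strict)[index]
}

#' Connected components of a molecular graph
#'
#' Multi-fragment ligands (e.g. salt pairs) are matched fragment by fragment,
#' so the components must be retrievable.  Components are ordered by size
#' (descending) and then by their smallest atom index.
#'
#' @param mol A [molgraph].
#' @return List of integer vectors of atom indices.
#' @export
mol_components <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(list())
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  }
  comp <- igraph::components(g)
  groups <- split(seq_len(n), comp$membership)
  groups <- lapply(groups, as.integer)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, min, integer(1)))
  unname(groups[ord])
}

# All simple rings of size 3..max_size, as ordered atom-index cycles.
# For each edge the shortest cycle through it is recovered by removing the
# edge and finding the shortest remaining path between its endpoints; this
# captures the small rings relevant to aromaticity and pi-stacking.
find_rings <- function(mol, max_size = 6) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(list())
  n <- n_atoms(mol)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  rings <- list()
  seen <- character()
  for (k in seq_len(nb)) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    eid <- igraph::get_edge_ids(g, c(i, j))
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = i, to = j, output = "vpath"))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) >= 2 && length(path) <= max_size) {
      key <- paste(sort(path), collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1]] <- path
      }
    }
  }
  rings
}

#' Normalise aromatic bond encodings
#'
#' Chemical file formats disagree on how aromatic systems are written: MOL2
#' marks bonds `ar` and SDF may either use bond type 4 or a Kekule structure
#' of alternating single/double bonds.  So that the same ligand read from two
#' dialects produces identical signatures, rings (size <= `max_size`) whose
#' bonds alternate single/double are re-classed as aromatic before signature
#' computation.
#'
#' @param mol A [molgraph].
#' @param max_size Largest ring size examined (default 6).
#' @return A [molgraph] with harmonised bond order classes.
#' @export
normalize_aromatic <- function(mol, max_size = 6) {
  if (nrow(mol$bonds) == 0) return(mol)
  rings <- find_rings(mol, max_size = max_size)
  if (length(rings) == 0) return(mol)
  lookup <- bond_order_lookup(mol)
  bonds <- mol$bonds
  key_of <- function(a, b) if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
  for (ring in rings) {
    m <- length(ring)
    ords <- vapply(seq_len(m), function(t) {
      a <- ring[t]; b <- ring[if (t == m) 1L else t + 1L]
      bond_order_between(lookup, a, b)
    }, character(1))
    kekule <- m %% 2 == 0 && all(ords %in% c("single", "double")) &&
      all(ords[seq(1, m, by = 2)] != ords[seq(2, m, by = 2)]) &&
      length(unique(ords[seq(1, m, by = 2)])) == 1
    if (kekule || all(ords == "aromatic")) {
      for (t in seq_len(m)) {
        a <- ring[t]; b <- ring[if (t == m) 1L else t + 1L]
        hit <- (bonds$i == min(a, b)) & (bonds$j == max(a, b))
        bonds$order[hit] <- "aromatic"
      }
    }
  }
  molgraph(mol$atoms, bonds, name = mol$name, properties = mol$properties)
}

# standard valences used by the synthetic generator and sanity checks
element_valence <- function(element) {
  v <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
         B = 3, Si = 4)
  out <- unname(v[element])
  out[is.na(out)] <- 4
  out
}

bond_order_value <- function(order) {
  v <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  unname(v[order])
}

# total bond-order sum per atom
atom_bond_degree <- function(mol) {
  deg <- numeric(n_atoms(mol))
  if (nrow(mol$bonds) > 0) {
    val <- bond_order_value(mol$bonds$order)
    for (k in seq_len(nrow(mol$bonds))) {
      deg[mol$bonds$i[k]] <- deg[mol$bonds$i[k]] + val[k]
      deg[mol$bonds$j[k]] <- deg[mol$bonds$j[k]] + val[k]
    }
  }
  deg
}
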