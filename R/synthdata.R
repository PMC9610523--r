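# Synthetic molecules, peptides and pose sets.  Everything is deterministic
# per seed (the global RNG state is saved and restored), so test fixtures
# are reproducible and nothing binary needs to be shipped.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a random toy molecule
#'
#' Builds a connected, valence-legal random molecular graph: a random tree
#' grown atom by atom, optionally closed into rings, with 3D coordinates from
#' a simple geometric layout (bond lengths around 1.5 Angstrom, random
#' directions, placements clashing with non-bonded atoms rejected).  Not a
#' chemically realistic conformer generator -- the molecules exercise the
#' matching, RMSD and clustering machinery, nothing more.
#'
#' @param n_atoms Number of heavy atoms (>= 1).
#' @param elements Element palette sampled (with replacement) per atom;
#'   repeats bias the composition (default is carbon-rich organic).
#' @param branch_prob Probability that a new atom attaches to a random
#'   earlier atom instead of extending the current chain.
#' @param ring_prob Probability of attempting one ring closure between two
#'   non-adjacent atoms with spare valence.
#' @param double_prob Probability that an eligible new bond is a double bond.
#' @param seed Integer seed; the same spec always yields the same molecule.
#' @return A [molgraph].
#' @export
generate_molecule <- function(n_atoms, elements = c("C", "C", "C", "N", "O"),
                              branch_prob = 0.3, ring_prob = 0.15,
                              double_prob = 0.15, seed = 1) {
  stopifnot(n_atoms >= 1, branch_prob >= 0, branch_prob <= 1,
            ring_prob >= 0, ring_prob <= 1)
  with_local_seed(seed, {
    el <- sample(elements, n_atoms, replace = TRUE)
    pos <- matrix(0, n_atoms, 3)
    bonds <- data.frame(i = integer(), j = integer(), order = character())
    used_val <- numeric(n_atoms)
    cap <- element_valence(el)
    if (n_atoms > 1) {
      for (k in 2:n_atoms) {
        open <- which(used_val[seq_len(k - 1)] < cap[seq_len(k - 1)])
        if (length(open) == 0) open <- seq_len(k - 1)  # give up on valence
        parent <- if (length(open) > 1 && runif(1) < branch_prob) {
          sample(open, 1)
        } else {
          max(open)  # extend the most recent open atom: chain growth
        }
        dbl <- runif(1) < double_prob &&
          cap[parent] - used_val[parent] >= 2 && cap[k] >= 2
        ord <- if (dbl) "double" else "single"
        bonds <- rbind(bonds, data.frame(i = parent, j = k, order = ord))
        used_val[parent] <- used_val[parent] + if (dbl) 2 else 1
        used_val[k] <- used_val[k] + if (dbl) 2 else 1
        pos[k, ] <- place_atom(pos, k, parent)
      }
      if (runif(1) < ring_prob && n_atoms >= 4) {
        adj <- lapply(seq_len(n_atoms), function(i)
          c(bonds$j[bonds$i == i], bonds$i[bonds$j == i]))
        spare <- which(used_val < cap)
        pairs <- expand.grid(a = spare, b = spare)
        pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
        ok <- vapply(seq_len(nrow(pairs)), function(r)
          !(pairs$b[r] %in% adj[[pairs$a[r]]]), logical(1))
        pairs <- pairs[ok, , drop = FALSE]
        if (nrow(pairs) > 0) {
          pick <- pairs[sample(nrow(pairs), 1), ]
          bonds <- rbind(bonds, data.frame(i = pick$a, j = pick$b,
                                           order = "single"))
        }
      }
    }
    molgraph(tibble(element = el, x = pos[, 1], y = pos[, 2], z = pos[, 3]),
             bonds, name = paste0("synthetic-", seed))
  })
}

# place atom k bonded to `parent`: 1.5 A away in a random direction,
# rejecting directions that bring it within 2.1 A of any other placed atom
place_atom <- function(pos, k, parent, bond_length = 1.5, clash = 2.1,
                       tries = 200) {
  placed <- seq_len(k - 1)
  others <- setdiff(placed, parent)
  best <- NULL; best_min <- -Inf
  for (t in seq_len(tries)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    cand <- pos[parent, ] + bond_length * u
    dmin <- if (length(others) == 0) Inf else
      min(sqrt(rowSums((pos[others, , drop = FALSE] -
                          matrix(cand, length(others), 3, byrow = TRUE))^2)))
    if (dmin >= clash) return(cand)
    if (dmin > best_min) { best_min <- dmin; best <- cand }
  }
  best  # crowded molecule: accept the least-clashing candidate
}

#' Randomly relabel the atoms of a molecule
#'
#' Applies a seeded random permutation to the atom order, re-indexing the
#' bonds accordingly.  Coordinates travel with their atoms, so the molecule
#' is geometrically unchanged -- this emulates a docking program writing the
#' same ligand with a different atom order.
#'
#' @param mol A [molgraph].
#' @param seed Integer seed.
#' @return A [molgraph]; the permutation applied is attached as attribute
#'   `"permutation"` (`new_order[old] = new position of old atom`).
#' @export
permute_atoms <- function(mol, seed = 1) {
  n <- n_atoms(mol)
  with_local_seed(seed, {
    perm <- sample(n)  # perm[new_position] = old index
    inv <- order(perm)
    atoms <- mol$atoms[perm, , drop = FALSE]
    atoms$orig_index <- seq_len(n)
    bonds <- mol$bonds
    if (nrow(bonds) > 0) {
      bonds$i <- inv[bonds$i]
      bonds$j <- inv[bonds$j]
    }
    out <- molgraph(atoms, bonds, name = mol$name, properties = mol$properties)
    attr(out, "permutation") <- inv
    out
  })
}

#' Add Gaussian coordinate noise
#'
#' Adds i.i.d. Gaussian noise of standard deviation `sigma` to every
#' coordinate.  For a molecule of N atoms the expected RMSD against the
#' unperturbed copy approaches `sigma * sqrt(3)` as N grows.
#'
#' @param mol A [molgraph].
#' @param sigma Noise scale in Angstrom (0 = identity).
#' @param seed Integer seed.
#' @return A [molgraph].
#' @export
perturb_coordinates <- function(mol, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(mol)
  n <- n_atoms(mol)
  with_local_seed(seed, {
    atoms <- mol$atoms
    noise <- matrix(rnorm(3 * n, sd = sigma), n, 3)
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
    molgraph(atoms, mol$bonds, name = mol$name, properties = mol$properties)
  })
}

#' Generate a pose set with planted cluster structure
#'
#' Emulates the output of a docking run whose poses fall into `k` distinct
#' binding modes: `k` cluster centres are rigid translations of the base
#' molecule (pairwise centre distances >= `separation`), each populated with
#' perturbed copies (coordinate noise `intra_spread`).  Synthetic scores are
#' drawn so that the largest cluster has the best (most negative) mean
#' score.  The set can be written as a multi-record SDF (scores in a data
#' tag) or a Vina-dialect PDBQT (scores in `REMARK VINA RESULT:` lines).
#'
#' @param base A [molgraph] used as the pose template.
#' @param k Number of planted clusters.
#' @param sizes Integer vector (length `k`) of poses per cluster.
#' @param intra_spread Within-cluster coordinate noise, Angstrom.
#' @param separation Minimum distance between cluster centres, Angstrom;
#'   must exceed `2 * intra_spread`.
#' @param seed Integer seed.
#' @param path Optional output file; written via [write_structures()].
#' @param format `"pdbqt"` (default) or `"sdf"`.
#' @return A list: `poses` (list of [molgraph], centre-grouped in pose
#'   order), `assignment` (true cluster of each pose), `scores`, `path`
#'   (`NULL` when not written).
#' @export
generate_pose_set <- function(base, k = 3, sizes = rep(5, k),
                              intra_spread = 0.2, separation = 3,
                              seed = 1, path = NULL,
                              format = c("pdbqt", "sdf")) {
  format <- match.arg(format)
  stopifnot(k >= 1, length(sizes) == k, all(sizes >= 1),
            separation > 2 * intra_spread)
  with_local_seed(seed, {
    centres <- place_centres(k, separation)
    # score means: most populated cluster most favourable
    rank_by_size <- rank(-sizes, ties.method = "first")
    means <- -9 + 0.6 * (rank_by_size - 1)
    poses <- list(); assignment <- integer(); scores <- numeric()
    base_topo <- bond_topology(base)
    for (ci in seq_len(k)) {
      for (s in seq_len(sizes[ci])) {
        shifted <- base
        shifted$atoms$x <- shifted$atoms$x + centres[ci, 1]
        shifted$atoms$y <- shifted$atoms$y + centres[ci, 2]
        shifted$atoms$z <- shifted$atoms$z + centres[ci, 3]
        # redraw the noise until distance-based bond perception still
        # recovers the base topology, so poses stay self-consistent when
        # written to dialects that carry no bond table
        for (try in 1:50) {
          m <- shifted
          noise <- matrix(rnorm(3 * n_atoms(m), sd = intra_spread),
                          n_atoms(m), 3)
          m$atoms$x <- m$atoms$x + noise[, 1]
          m$atoms$y <- m$atoms$y + noise[, 2]
          m$atoms$z <- m$atoms$z + noise[, 3]
          if (identical(bond_topology(perceive_bonds(m)), base_topo)) break
        }
        sc <- round(means[ci] + rnorm(1, sd = 0.05), 3)
        tag <- if (format == "pdbqt") "vina_score" else "Chemgauss4"
        m$properties <- setNames(as.character(sc), tag)
        m$name <- sprintf("pose_c%d_%d", ci, s)
        poses[[length(poses) + 1]] <- m
        assignment <- c(assignment, ci)
        scores <- c(scores, sc)
      }
    }
    if (!is.null(path)) write_structures(poses, path, format = format)
    list(poses = poses, assignment = assignment, scores = scores,
         path = path)
  })
}

bond_topology <- function(mol) {
  b <- mol$bonds[order(mol$bonds$i, mol$bonds$j), c("i", "j")]
  paste(b$i, b$j, sep = "-", collapse = ";")
}

# k centres with pairwise distance >= separation (origin-anchored)
place_centres <- function(k, separation) {
  centres <- matrix(0, 1, 3)
  box <- separation * max(2, ceiling(k^(1 / 3)) + 1)
  while (nrow(centres) < k) {
    cand <- runif(3, -box, box)
    dmin <- min(sqrt(rowSums(sweep(centres, 2, cand)^2)))
    if (dmin >= separation) centres <- rbind(centres, cand)
  }
  centres
}

#' Generate a synthetic peptide
#'
#' Builds a glycine/alanine chain with the explicit backbone motif
#' N-CA-C'(=O) per residue, a C-terminal hydroxyl oxygen, and zigzag
#' extended-chain coordinates with bond lengths around 1.4-1.5 Angstrom.
#' Used to exercise the backbone RMSD mode without any external structure.
#'
#' @param n_residues Number of residues (>= 1).
#' @param sequence Character vector of `"G"`/`"A"` per residue; default
#'   alternates.
#' @param with_names Attach PDB-style atom names (`N`, `CA`, `C`, `O`,
#'   `CB`, `OXT`); when `FALSE` (default) backbone detection must rely on
#'   the graph motif.
#' @param seed Seed for the small random pucker added to the coordinates.
#' @return A [molgraph].
#' @export
generate_peptide <- function(n_residues, sequence = NULL, with_names = FALSE,
                             seed = 1) {
  stopifnot(n_residues >= 1)
  if (is.null(sequence)) {
    sequence <- rep(c("G", "A"), length.out = n_residues)
  }
  stopifnot(length(sequence) == n_residues, all(sequence %in% c("G", "A")))
  with_local_seed(seed, {
    atoms <- list(); bonds <- list(); names_v <- character()
    elements <- character()
    idx <- 0L
    add <- function(element, xyz, nm) {
      idx <<- idx + 1L
      atoms[[idx]] <<- c(xyz)
      names_v[idx] <<- nm
      elements[idx] <<- element
      idx
    }
    prev_c <- NA_integer_
    for (r in seq_len(n_residues)) {
      x0 <- (r - 1) * 3.6
      zig <- if (r %% 2 == 0) 0.5 else -0.5
      jit <- function() rnorm(3, sd = 0.03)
      iN <- add("N", c(x0, zig, 0) + jit(), "N")
      iCA <- add("C", c(x0 + 1.2, -zig, 0.4) + jit(), "CA")
      iC <- add("C", c(x0 + 2.4, zig, -0.4) + jit(), "C")
      iO <- add("O", c(x0 + 2.6, zig + 1.2, -0.7) + jit(), "O")
      bonds[[length(bonds) + 1]] <- data.frame(i = iN, j = iCA, order = "single")
      bonds[[length(bonds) + 1]] <- data.frame(i = iCA, j = iC, order = "single")
      bonds[[length(bonds) + 1]] <- data.frame(i = iC, j = iO, order = "double")
      if (!is.na(prev_c)) {
        bonds[[length(bonds) + 1]] <- data.frame(i = prev_c, j = iN,
                                                 order = "single")
      }
      if (sequence[r] == "A") {
        iCB <- add("C", c(x0 + 1.2, -zig - 1.4, 1.2) + jit(), "CB")
        bonds[[length(bonds) + 1]] <- data.frame(i = iCA, j = iCB,
                                                 order = "single")
      }
      prev_c <- iC
    }
    iOXT <- add("O", c((n_residues - 1) * 3.6 + 3.4, -0.8, 0.2) +
                  rnorm(3, sd = 0.03), "OXT")
    bonds[[length(bonds) + 1]] <- data.frame(i = prev_c, j = iOXT,
                                             order = "single")
    pos <- do.call(rbind, atoms)
    at <- tibble(element = elements, x = pos[, 1], y = pos[, 2], z = pos[, 3])
    if (with_names) at$atom_name <- names_v
    molgraph(at, do.call(rbind, bonds),
             name = paste0("peptide-", paste(sequence, collapse = "")))
  })
}
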