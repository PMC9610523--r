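# Positional RMSD between mapped structures.
#
# Docked poses and the reference share the receptor's coordinate frame, so
# the RMSD is computed in place -- no superposition is performed.  A rigid
# displacement therefore contributes fully, which is exactly what a
# re-docking evaluation needs.  This differs from alignment RMSD; see the
# methods vignette.

#' RMSD between two mapped molecules
#'
#' Computes `sqrt(mean(delta_i^2))` over the mapped heavy-atom pairs, where
#' `delta_i` is the Euclidean distance between the i-th pair of corresponding
#' atoms, in the shared coordinate frame (positional RMSD, no superposition).
#'
#' @param ref,probe [molgraph] objects, hydrogens stripped internally.
#' @param mapping An `atom_mapping` from [match_atoms()] or
#'   [brute_force_match()]; must be complete.  When `NULL`, matching is run
#'   here.
#' @return A one-row tibble with columns `rmsd` (Angstrom), `n_atoms`,
#'   `mode`, and a `mapping` list-column.
#' @export
compute_rmsd <- function(ref, probe, mapping = NULL) {
  ref_h <- strip_hydrogens(ref)
  probe_h <- strip_hydrogens(probe)
  if (is.null(mapping)) mapping <- match_atoms(ref_h, probe_h)
  stopifnot(inherits(mapping, "atom_mapping"))
  if (!mapping$complete) {
    abort("mapping is incomplete; RMSD requires every heavy atom mapped",
          class = "dockpose_user_error")
  }
  d <- coords(ref_h)[mapping$pairs$ref_atom, , drop = FALSE] -
       coords(probe_h)[mapping$pairs$probe_atom, , drop = FALSE]
  tibble(rmsd = sqrt(mean(rowSums(d^2))), n_atoms = nrow(mapping$pairs),
         mode = "all_heavy", mapping = list(mapping))
}

#' RMSD of many poses against one reference
#'
#' Confronts a reference structure with every pose of a docking run in one
#' call.  Atom matching is re-run per pose, so poses may be labelled in any
#' order.  In `"backbone"` mode the calculation is restricted to the peptide
#' backbone atoms (N, C-alpha, C', O) of the reference, excluding side
#' chains; see [backbone_filter()].
#'
#' @param ref Reference [molgraph].
#' @param poses List of [molgraph] poses (e.g. from [read_structures()]).
#' @param mode `"all_heavy"` (default) or `"backbone"`.
#' @param backbone_oxygen Include the carbonyl oxygen in the backbone set
#'   (default `TRUE`).
#' @return A tibble with one row per pose: `pose_index`, `rmsd`, `n_atoms`,
#'   `mode`, `mapping` (list-column), `error` (`NA` or the per-pose failure
#'   message; failures never abort the batch).
#' @examples
#' m <- generate_molecule(9, seed = 4)
#' poses <- lapply(1:3, function(s) permute_atoms(m, seed = s))
#' rmsd_all(m, poses)$rmsd  # all zero: identical coordinates
#' @export
rmsd_all <- function(ref, poses, mode = c("all_heavy", "backbone"),
                     backbone_oxygen = TRUE) {
  mode <- match.arg(mode)
  if (inherits(poses, "molgraph")) poses <- list(poses)
  ref_h <- strip_hydrogens(ref)
  bb <- NULL
  if (mode == "backbone") {
    bb <- backbone_filter(ref_h, include_oxygen = backbone_oxygen)
  }
  rows <- lapply(seq_along(poses), function(k) {
    out <- tryCatch({
      pose_h <- strip_hydrogens(poses[[k]])
      mapping <- match_atoms(ref_h, pose_h)
      pairs <- mapping$pairs
      if (!is.null(bb)) pairs <- pairs[pairs$ref_atom %in% bb, , drop = FALSE]
      d <- coords(ref_h)[pairs$ref_atom, , drop = FALSE] -
           coords(pose_h)[pairs$probe_atom, , drop = FALSE]
      tibble(pose_index = k, rmsd = sqrt(mean(rowSums(d^2))),
             n_atoms = nrow(pairs), mode = mode, mapping = list(mapping),
             error = NA_character_)
    }, error = function(e) {
      tibble(pose_index = k, rmsd = NA_real_, n_atoms = NA_integer_,
             mode = mode, mapping = list(NULL),
             error = conditionMessage(e))
    })
    out
  })
  bind_rows(rows)
}

#' Peptide backbone atom selection
#'
#' Returns the indices of the backbone atoms (amide N, C-alpha, carbonyl C',
#' and optionally the carbonyl O) of every residue of a peptide ligand.  When
#' the molecule carries PDB atom names they are used directly; otherwise the
#' repeating N-C-C(=O) motif is found by graph search: each candidate
#' C-alpha is a carbon bonded both to a nitrogen and to a carbon that bears a
#' terminal oxygen.  Exactly one oxygen is selected per carbonyl carbon
#' (double-bonded preferred, then lowest index), so a C-terminal carboxylate
#' contributes a single backbone oxygen.
#'
#' @param mol A [molgraph]; hydrogens stripped internally.
#' @param include_oxygen Include the carbonyl oxygen (default `TRUE`,
#'   the conventional N/CA/C/O backbone; `FALSE` gives N/CA/C).
#' @return Sorted integer vector of backbone atom indices into the
#'   heavy-atom graph.
#' @export
backbone_filter <- function(mol, include_oxygen = TRUE) {
  mol <- strip_hydrogens(mol)
  at <- mol$atoms
  anames <- mol_col(at, "atom_name")
  if (!is.null(anames) && !anyNA(anames) &&
      any(toupper(trimws(anames)) %in% c("CA"))) {
    names_up <- toupper(trimws(anames))
    wanted <- c("N", "CA", "C", if (include_oxygen) "O")
    idx <- which(names_up %in% wanted)
    if (length(idx) >= 3) return(sort(idx))
  }
  adj <- adjacency_list(mol)
  lookup <- bond_order_lookup(mol)
  deg <- lengths(adj)
  el <- at$element
  backbone <- integer()
  n_motifs <- 0L
  for (ca in which(el == "C")) {
    nbrs <- adj[[ca]]
    n_nbrs <- nbrs[el[nbrs] == "N"]
    c_nbrs <- nbrs[el[nbrs] == "C"]
    if (length(n_nbrs) == 0 || length(c_nbrs) == 0) next
    for (cp in c_nbrs) {
      term_o <- adj[[cp]][el[adj[[cp]]] == "O" & deg[adj[[cp]]] == 1]
      if (length(term_o) == 0) next
      # prefer the double-bonded oxygen, then the lowest index
      dbl <- term_o[vapply(term_o, function(o)
        bond_order_between(lookup, cp, o) == "double", logical(1))]
      o_pick <- if (length(dbl) > 0) min(dbl) else min(term_o)
      n_motifs <- n_motifs + 1L
      backbone <- c(backbone, n_nbrs[1], ca, cp,
                    if (include_oxygen) o_pick)
      break  # one carbonyl per C-alpha
    }
  }
  if (n_motifs == 0L) {
    abort(paste0("no peptide backbone motif (N-CA-C'=O) found; ",
                 "this molecule is not a linear peptide -- use mode = ",
                 "'all_heavy' instead"), class = "dockpose_not_peptide")
  }
  sort(unique(backbone))
}
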