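# Geometric detection of receptor-ligand interactions.  Replaces visual
# inspection with a machine-readable report: each record is one atom pair
# (or ring pair, for pi-stacking) satisfying a literature-standard geometric
# criterion.  All thresholds are configurable.

METAL_ELEMENTS <- c("Na", "K", "Mg", "Ca", "Zn", "Fe", "Mn", "Cu", "Ni",
                    "Co", "Cd")

#' Default geometric criteria for interaction detection
#'
#' @return Named list of thresholds: `hbond_dist` (donor-acceptor <= 3.5 A),
#'   `hbond_angle` (D-H...A >= 120 degrees, applied when an explicit
#'   hydrogen is present), `ionic_dist` (4.0 A), `hydrophobic_dist` (4.0 A),
#'   `pi_dist` (ring-centroid distance <= 5.5 A), `pi_parallel_max` (30
#'   degrees), `pi_tshape_min`/`pi_tshape_max` (60-90 degrees), `metal_dist`
#'   (2.8 A).
#' @export
interaction_criteria <- function() {
  list(hbond_dist = 3.5, hbond_angle = 120, ionic_dist = 4.0,
       hydrophobic_dist = 4.0, pi_dist = 5.5, pi_parallel_max = 30,
       pi_tshape_min = 60, pi_tshape_max = 90, metal_dist = 2.8)
}

#' Detect receptor-ligand interactions
#'
#' Scans all receptor/ligand atom pairs for geometric signatures of five
#' interaction types: hydrogen bonds (N/O donors to N/O/S acceptors, with a
#' D-H...A angle check when explicit hydrogens are present), ionic contacts
#' between oppositely charged groups (carboxylate, phosphate, sulfate,
#' guanidinium, amidinium, protonated amine; residue-name patterns are used
#' for the receptor when available), hydrophobic contacts between apolar
#' carbons, pi-stacking between 5-/6-membered aromatic rings (parallel or
#' T-shaped), and metal coordination.  Records are sorted by type and
#' distance and identified by residue labels, so the report is stable under
#' relabelling of the ligand atoms.
#'
#' @param receptor A [molgraph], typically read from a PDB file so that
#'   residue labels are present; a warning is emitted when they are not.
#' @param ligand A [molgraph] sharing the receptor's coordinate frame.
#' @param kinds Interaction types to report; any subset of `"hbond"`,
#'   `"ionic"`, `"hydrophobic"`, `"pi_stacking"`, `"metal"`.
#' @param criteria Thresholds, see [interaction_criteria()].
#' @return A tibble with columns `kind`, `ligand_atom`, `receptor_atom`,
#'   `residue` (e.g. `"SER152.A"`, `NA` without labels), `distance` (A) and
#'   `angle` (degrees, `NA` where not applicable).
#' @export
detect_interactions <- function(receptor, ligand,
                                kinds = c("hbond", "ionic", "hydrophobic",
                                          "pi_stacking", "metal"),
                                criteria = interaction_criteria()) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (is.null(mol_col(receptor$atoms, "resid"))) {
    warn("receptor carries no residue labels; records are reported with atom indices only")
  }
  out <- list()
  if ("hbond" %in% kinds) out$hb <- detect_hbonds(receptor, ligand, criteria)
  if ("ionic" %in% kinds) out$io <- detect_ionic(receptor, ligand, criteria)
  if ("hydrophobic" %in% kinds) {
    out$ph <- detect_hydrophobic(receptor, ligand, criteria)
  }
  if ("pi_stacking" %in% kinds) out$pi <- detect_pi(receptor, ligand, criteria)
  if ("metal" %in% kinds) out$me <- detect_metal(receptor, ligand, criteria)
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(kind = character(), ligand_atom = integer(),
                  receptor_atom = integer(), residue = character(),
                  distance = numeric(), angle = numeric()))
  }
  res <- res[order(res$kind, res$distance, res$receptor_atom), , drop = FALSE]
  res
}

residue_label <- function(mol, idx) {
  at <- mol$atoms
  resid <- mol_col(at, "resid")
  if (is.null(resid)) return(rep(NA_character_, length(idx)))
  ch <- mol_col(at, "chain")
  chain <- if (is.null(ch)) "" else
    ifelse(is.na(ch[idx]) | !nzchar(ch[idx]), "", paste0(".", ch[idx]))
  paste0(resid[idx], mol_col(at, "resno")[idx], chain)
}

cross_distances <- function(receptor, ligand) {
  rc <- coords(receptor); lc <- coords(ligand)
  # n_lig x n_rec matrix of Euclidean distances
  outer_d <- sqrt(outer(rowSums(lc^2), rowSums(rc^2), "+") -
                    2 * lc %*% t(rc))
  outer_d[outer_d < 0 | is.nan(outer_d)] <- 0
  outer_d
}

make_records <- function(kind, receptor, lig_idx, rec_idx, distance, angle) {
  tibble(kind = kind, ligand_atom = as.integer(lig_idx),
         receptor_atom = as.integer(rec_idx),
         residue = residue_label(receptor, rec_idx),
         distance = distance, angle = angle)
}

# donors: N/O with at least one explicit H (any N/O when the molecule has no
# hydrogens at all); acceptors: N/O/S
hbond_roles <- function(mol) {
  el <- mol$atoms$element
  adj <- adjacency_list(mol)
  has_h <- any(el == "H")
  donor <- el %in% c("N", "O") &
    (!has_h | vapply(adj, function(nb) any(el[nb] == "H"), logical(1)))
  list(donor = which(donor), acceptor = which(el %in% c("N", "O", "S")),
       adj = adj, has_h = has_h)
}

angle_deg <- function(a, b, c) {  # angle at b, degrees
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

hb_angle_ok <- function(dmol, amol, d_idx, a_idx, roles, criteria) {
  # max D-H...A angle over the donor's hydrogens; NA when no explicit H
  hs <- roles$adj[[d_idx]][dmol$atoms$element[roles$adj[[d_idx]]] == "H"]
  if (length(hs) == 0) return(NA_real_)
  dpos <- coords(dmol)[d_idx, ]; apos <- coords(amol)[a_idx, ]
  max(vapply(hs, function(h) angle_deg(dpos, coords(dmol)[h, ], apos),
             numeric(1)))
}

detect_hbonds <- function(receptor, ligand, criteria) {
  lr <- hbond_roles(ligand); rr <- hbond_roles(receptor)
  d <- cross_distances(receptor, ligand)
  rows <- list()
  scan <- function(d_side, donors, acceptors) {
    for (di in donors) for (ai in acceptors) {
      dist <- if (d_side == "ligand") d[di, ai] else d[ai, di]
      if (dist > criteria$hbond_dist || dist < 1e-6) next
      ang <- if (d_side == "ligand") {
        hb_angle_ok(ligand, receptor, di, ai, lr, criteria)
      } else {
        hb_angle_ok(receptor, ligand, di, ai, rr, criteria)
      }
      if (!is.na(ang) && ang < criteria$hbond_angle) next
      lig_idx <- if (d_side == "ligand") di else ai
      rec_idx <- if (d_side == "ligand") ai else di
      rows[[length(rows) + 1]] <<- make_records("hbond", receptor, lig_idx,
                                                rec_idx, dist, ang)
    }
  }
  scan("ligand", lr$donor, rr$acceptor)
  scan("receptor", rr$donor, lr$acceptor)
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    out <- out[!duplicated(out[, c("ligand_atom", "receptor_atom")]), ,
               drop = FALSE]
  }
  out
}

#' Formal-charge group detection by substructure pattern
#'
#' Identifies atoms belonging to the standard charged groups at
#' physiological pH: terminal oxygens of carboxylate/phosphate/sulfate
#' (negative), guanidinium/amidinium nitrogens and sp3 amine nitrogens with
#' only carbon/hydrogen neighbours (positive).  When residue labels are
#' present the canonical charged protein/nucleic-acid atoms (ASP/GLU side
#' chain O, LYS NZ, ARG NE/NH, HIS ring N, phosphate O of nucleotides) are
#' used instead.
#'
#' @param mol A [molgraph].
#' @return Tibble with columns `atom` and `sign` (+1/-1).
#' @export
charged_atoms <- function(mol) {
  at <- mol$atoms
  el <- at$element
  resid_col <- mol_col(at, "resid"); name_col <- mol_col(at, "atom_name")
  if (!is.null(resid_col) && !all(is.na(resid_col)) && !is.null(name_col)) {
    nm <- toupper(trimws(name_col)); res <- toupper(trimws(resid_col))
    neg <- (res == "ASP" & nm %in% c("OD1", "OD2")) |
           (res == "GLU" & nm %in% c("OE1", "OE2")) |
           nm %in% c("OP1", "OP2", "O1P", "O2P") |
           (nm == "OXT")
    pos <- (res == "LYS" & nm == "NZ") |
           (res == "ARG" & nm %in% c("NE", "NH1", "NH2")) |
           (res == "HIS" & nm %in% c("ND1", "NE2"))
    return(bind_rows(tibble(atom = which(neg), sign = -1),
                     tibble(atom = which(pos), sign = 1)))
  }
  adj <- adjacency_list(mol)
  deg_heavy <- vapply(adj, function(nb) sum(!el[nb] %in% c("H", "D", "T")),
                      integer(1))
  neg <- logical(length(el)); pos <- logical(length(el))
  for (i in seq_along(el)) {
    nb <- adj[[i]]
    if (el[i] == "O" && deg_heavy[i] == 1 && length(nb) >= 1) {
      centre <- nb[el[nb] %in% c("C", "P", "S")][1]
      if (!is.na(centre)) {
        term_o <- sum(el[adj[[centre]]] == "O" &
                        deg_heavy[adj[[centre]]] == 1)
        if (term_o >= 2) neg[i] <- TRUE
      }
    }
    if (el[i] == "N") {
      c_nb <- nb[el[nb] == "C"]
      for (cc in c_nb) {
        n_on_c <- sum(el[adj[[cc]]] == "N")
        o_on_c <- sum(el[adj[[cc]]] == "O")
        if (n_on_c >= 2 && o_on_c == 0) pos[i] <- TRUE  # guanidinium/amidinium
      }
      only_ch <- all(el[nb] %in% c("C", "H"))
      sp3 <- all(vapply(nb, function(j)
        bond_order_between(bond_order_lookup(mol), i, j) == "single",
        logical(1)))
      if (length(nb) > 0 && only_ch && sp3 && deg_heavy[i] <= 2 && !pos[i]) {
        pos[i] <- TRUE  # protonated primary/secondary amine (approximation)
      }
    }
  }
  bind_rows(tibble(atom = which(neg), sign = -1),
            tibble(atom = which(pos), sign = 1))
}

detect_ionic <- function(receptor, ligand, criteria) {
  lq <- charged_atoms(ligand); rq <- charged_atoms(receptor)
  if (nrow(lq) == 0 || nrow(rq) == 0) return(tibble())
  d <- cross_distances(receptor, ligand)
  rows <- list()
  for (a in seq_len(nrow(lq))) for (b in seq_len(nrow(rq))) {
    if (lq$sign[a] * rq$sign[b] >= 0) next
    dist <- d[lq$atom[a], rq$atom[b]]
    if (dist <= criteria$ionic_dist && dist > 1e-6) {
      rows[[length(rows) + 1]] <- make_records("ionic", receptor, lq$atom[a],
                                               rq$atom[b], dist, NA_real_)
    }
  }
  bind_rows(rows)
}

apolar_carbons <- function(mol) {
  el <- mol$atoms$element
  adj <- adjacency_list(mol)
  which(el == "C" & vapply(adj, function(nb)
    !any(el[nb] %in% c("N", "O", "S", "P")), logical(1)))
}

detect_hydrophobic <- function(receptor, ligand, criteria) {
  lc <- apolar_carbons(ligand); rc <- apolar_carbons(receptor)
  if (length(lc) == 0 || length(rc) == 0) return(tibble())
  d <- cross_distances(receptor, ligand)
  hit <- which(d[lc, rc, drop = FALSE] <= criteria$hydrophobic_dist &
                 d[lc, rc, drop = FALSE] > 1e-6, arr.ind = TRUE)
  if (nrow(hit) == 0) return(tibble())
  make_records("hydrophobic", receptor, lc[hit[, 1]], rc[hit[, 2]],
               d[cbind(lc[hit[, 1]], rc[hit[, 2]])], NA_real_)
}

# aromatic 5-/6-rings (C/N only) with centroid and unit normal
aromatic_rings <- function(mol) {
  m <- normalize_aromatic(strip_hydrogens(mol))
  rings <- find_rings(m, max_size = 6)
  lookup <- bond_order_lookup(m)
  keep <- list()
  for (ring in rings) {
    k <- length(ring)
    if (k < 5) next
    if (!all(m$atoms$element[ring] %in% c("C", "N"))) next
    arom <- all(vapply(seq_len(k), function(t) {
      a <- ring[t]; b <- ring[if (t == k) 1L else t + 1L]
      bond_order_between(lookup, a, b) == "aromatic"
    }, logical(1)))
    if (!arom) next
    pts <- coords(m)[ring, , drop = FALSE]
    centroid <- colMeans(pts)
    sv <- svd(sweep(pts, 2, centroid))
    keep[[length(keep) + 1]] <- list(atoms = sort(m$atoms$orig_index[ring]),
                                     centroid = centroid,
                                     normal = sv$v[, 3])
  }
  keep
}

detect_pi <- function(receptor, ligand, criteria) {
  lr <- aromatic_rings(ligand); rr <- aromatic_rings(receptor)
  if (length(lr) == 0 || length(rr) == 0) return(tibble())
  rows <- list()
  for (a in lr) for (b in rr) {
    dist <- sqrt(sum((a$centroid - b$centroid)^2))
    if (dist > criteria$pi_dist || dist < 1e-6) next
    ang <- acos(pmin(abs(sum(a$normal * b$normal)), 1)) * 180 / pi
    parallel <- ang <= criteria$pi_parallel_max
    tshape <- ang >= criteria$pi_tshape_min & ang <= criteria$pi_tshape_max
    if (!parallel && !tshape) next
    rows[[length(rows) + 1]] <- make_records("pi_stacking", receptor,
                                             a$atoms[1], b$atoms[1], dist, ang)
  }
  bind_rows(rows)
}

detect_metal <- function(receptor, ligand, criteria) {
  d <- cross_distances(receptor, ligand)
  rows <- list()
  lmet <- which(ligand$atoms$element %in% METAL_ELEMENTS)
  rmet <- which(receptor$atoms$element %in% METAL_ELEMENTS)
  lda <- which(ligand$atoms$element %in% c("N", "O", "S"))
  rda <- which(receptor$atoms$element %in% c("N", "O", "S"))
  for (m in rmet) for (a in lda) {
    if (d[a, m] <= criteria$metal_dist && d[a, m] > 1e-6) {
      rows[[length(rows) + 1]] <- make_records("metal", receptor, a, m,
                                               d[a, m], NA_real_)
    }
  }
  for (m in lmet) for (a in rda) {
    if (d[m, a] <= criteria$metal_dist && d[m, a] > 1e-6) {
      rows[[length(rows) + 1]] <- make_records("metal", receptor, m, a,
                                               d[m, a], NA_real_)
    }
  }
  bind_rows(rows)
}
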