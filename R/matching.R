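# Atom matching between identically composed molecules whose atoms are
# labelled in different orders.
#
# The greedy matcher walks both molecular graphs depth-first from a root
# pair: at every branching step the signature-compatible assignments of the
# unvisited reference neighbours to the unvisited probe neighbours are ranked
# by the RMSD of all atoms assigned so far (including the candidates), and
# the minimising branch is followed.  Dead ends trigger backtracking to the
# most recent branch, up to a bounded budget.  Every accepted pair must also
# be adjacency-consistent with the pairs already placed, so a completed
# mapping is a genuine graph isomorphism and its RMSD can never undercut the
# exhaustive optimum.

#' Match atoms between a reference and a probe molecule
#'
#' Finds a bijection between the heavy atoms of two identically composed
#' molecules by greedy depth-first traversal of their molecular graphs,
#' choosing at each branching step the neighbour assignment that minimises
#' the partial RMSD.  Roots are chosen from the rarest atom signature in the
#' reference; every probe atom sharing that signature is tried as a probe
#' root and the mapping with the lowest full-molecule RMSD wins.  Signatures
#' are first compared strictly (element, neighbour elements, bond order
#' classes); if no complete mapping is found the comparison is relaxed to
#' element plus neighbour-element multiset, which tolerates bond-order
#' disagreements between file dialects.  Multi-fragment molecules are matched
#' fragment by fragment.
#'
#' @param ref,probe [molgraph] objects with equal heavy-atom element
#'   multisets.  Hydrogens are stripped internally.
#' @param max_backtracks Alternative-branch budget per root pair (default
#'   1000); exceeded budgets make that root pair fail.
#' @return An object of class `atom_mapping`: a list with `pairs` (tibble of
#'   `ref_atom`, `probe_atom`, 1-based indices into the heavy-atom graphs),
#'   `complete`, `rmsd` and `strictness` (`"strict"` or `"relaxed"`).
#' @examples
#' m <- generate_molecule(8, seed = 1)
#' p <- permute_atoms(m, seed = 2)
#' match_atoms(m, p)$rmsd  # 0: same coordinates, relabelled
#' @seealso [brute_force_match()] for the exhaustive oracle.
#' @export
match_atoms <- function(ref, probe, max_backtracks = 1000) {
  ref <- normalize_aromatic(strip_hydrogens(ref))
  probe <- normalize_aromatic(strip_hydrogens(probe))
  check_matchable(ref, probe)
  for (strict in c(TRUE, FALSE)) {
    res <- match_components(ref, probe, strict = strict,
                            max_backtracks = max_backtracks,
                            engine = greedy_match_component)
    if (!is.null(res)) {
      return(new_atom_mapping(res, ref, probe,
                              strictness = if (strict) "strict" else "relaxed"))
    }
  }
  abort(paste0("no complete atom mapping found within the backtrack budget; ",
               "for small molecules brute_force_match() gives the exact answer"),
        class = "dockpose_matching_failure")
}

#' Exhaustive minimum-RMSD atom matching
#'
#' Enumerates every signature-consistent graph isomorphism between the two
#' heavy-atom graphs by backtracking and returns the mapping with globally
#' minimal RMSD (ties broken by the lexicographically smallest pair list).
#' Exact but exponential in the worst case, hence the size guard; used as
#' the oracle against which the greedy matcher is validated.
#'
#' @inheritParams match_atoms
#' @param max_atoms Refuse molecules with more heavy atoms than this
#'   (default 14).
#' @return An `atom_mapping` (see [match_atoms()]).
#' @export
brute_force_match <- function(ref, probe, max_atoms = 14) {
  ref <- normalize_aromatic(strip_hydrogens(ref))
  probe <- normalize_aromatic(strip_hydrogens(probe))
  if (n_atoms(ref) > max_atoms) {
    abort(paste0("molecule too large for exhaustive matching (", n_atoms(ref),
                 " > ", max_atoms, " heavy atoms)"), class = "dockpose_user_error")
  }
  check_matchable(ref, probe)
  for (strict in c(TRUE, FALSE)) {
    res <- match_components(ref, probe, strict = strict, max_backtracks = Inf,
                            engine = exhaustive_match_component)
    if (!is.null(res)) {
      return(new_atom_mapping(res, ref, probe,
                              strictness = if (strict) "strict" else "relaxed"))
    }
  }
  abort("molecules are not isomorphic under any signature level",
        class = "dockpose_matching_failure")
}

check_matchable <- function(ref, probe) {
  if (n_atoms(ref) == 0 || n_atoms(probe) == 0) {
    abort("cannot match an empty (all-hydrogen) molecule",
          class = "dockpose_incompatible")
  }
  if (n_atoms(ref) != n_atoms(probe)) {
    abort(paste0("heavy-atom counts differ (", n_atoms(ref), " vs ",
                 n_atoms(probe), ")"), class = "dockpose_incompatible")
  }
  e1 <- sort(ref$atoms$element); e2 <- sort(probe$atoms$element)
  if (!identical(e1, e2)) {
    abort("element multisets differ; molecules are not the same compound",
          class = "dockpose_incompatible")
  }
}

new_atom_mapping <- function(pairs, ref, probe, strictness) {
  pairs <- pairs[order(pairs$ref_atom), , drop = FALSE]
  d <- coords(ref)[pairs$ref_atom, , drop = FALSE] -
       coords(probe)[pairs$probe_atom, , drop = FALSE]
  structure(list(pairs = as_tibble(pairs),
                 complete = nrow(pairs) == n_atoms(ref),
                 rmsd = sqrt(mean(rowSums(d^2))),
                 strictness = strictness),
            class = "atom_mapping")
}

#' @export
print.atom_mapping <- function(x, ...) {
  cat("<atom_mapping> ", nrow(x$pairs), " pairs, ",
      if (x$complete) "complete" else "incomplete",
      ", rmsd ", format(round(x$rmsd, 3), nsmall = 3), " A (",
      x$strictness, " signatures)\n", sep = "")
  invisible(x)
}

# Split into connected components, pair components between the molecules by
# (size, element multiset), and run the per-component engine on each pair.
# Returns a data.frame of (ref_atom, probe_atom) or NULL on failure.
match_components <- function(ref, probe, strict, max_backtracks, engine) {
  rcomp <- mol_components(ref)
  pcomp <- mol_components(probe)
  if (length(rcomp) != length(pcomp)) return(NULL)
  key <- function(mol, idx) paste0(length(idx), "|",
                                   paste(sort(mol$atoms$element[idx]), collapse = ","))
  rkey <- vapply(rcomp, function(i) key(ref, i), character(1))
  pkey <- vapply(pcomp, function(i) key(probe, i), character(1))
  if (!identical(sort(rkey), sort(pkey))) return(NULL)
  used <- rep(FALSE, length(pcomp))
  all_pairs <- list()
  for (ci in seq_along(rcomp)) {
    cand <- which(pkey == rkey[ci] & !used)
    # among probe components of identical composition, greedily take the one
    # whose matching gives the lowest component RMSD
    best <- NULL; best_rmsd <- Inf; best_j <- NA_integer_
    for (j in cand) {
      sub <- engine(subgraph_of(ref, rcomp[[ci]]), subgraph_of(probe, pcomp[[j]]),
                    strict = strict, max_backtracks = max_backtracks)
      if (!is.null(sub) && sub$rmsd < best_rmsd) {
        best <- sub; best_rmsd <- sub$rmsd; best_j <- j
      }
    }
    if (is.null(best)) return(NULL)
    used[best_j] <- TRUE
    all_pairs[[ci]] <- data.frame(
      ref_atom = rcomp[[ci]][best$pairs$ref_atom],
      probe_atom = pcomp[[best_j]][best$pairs$probe_atom])
  }
  do.call(rbind, all_pairs)
}

subgraph_of <- function(mol, idx) {
  new_idx <- rep(NA_integer_, n_atoms(mol))
  new_idx[idx] <- seq_along(idx)
  keep <- !is.na(new_idx[mol$bonds$i]) & !is.na(new_idx[mol$bonds$j])
  bonds <- mol$bonds[keep, , drop = FALSE]
  bonds$i <- new_idx[bonds$i]; bonds$j <- new_idx[bonds$j]
  molgraph(mol$atoms[idx, , drop = FALSE], bonds, mol$name)
}

# ---- greedy engine --------------------------------------------------------

# Match one connected component pair greedily.  Returns list(pairs, rmsd)
# or NULL when no complete mapping is found within the budget.
greedy_match_component <- function(ref, probe, strict, max_backtracks) {
  n <- n_atoms(ref)
  rsig <- atom_signatures(ref, strict = strict)
  psig <- atom_signatures(probe, strict = strict)
  if (!identical(sort(rsig), sort(psig))) return(NULL)
  if (n == 1) return(list(pairs = data.frame(ref_atom = 1L, probe_atom = 1L),
                          rmsd = sqrt(sum((coords(ref) - coords(probe))^2))))
  # root: rarest reference signature, lowest index on ties
  counts <- table(rsig)
  rarity <- as.vector(counts[rsig])
  ref_root <- which(rarity == min(rarity))[1]
  probe_roots <- which(psig == rsig[ref_root])
  st <- list(radj = adjacency_list(ref), padj = adjacency_list(probe),
             rlook = bond_order_lookup(ref), plook = bond_order_lookup(probe),
             rc = coords(ref), pc = coords(probe),
             rsig = rsig, psig = psig, strict = strict, n = n)
  best <- NULL
  for (pr in probe_roots) {
    env <- new.env(parent = emptyenv())
    env$budget <- max_backtracks
    map0 <- rep(NA_integer_, n); map0[ref_root] <- pr
    used0 <- rep(FALSE, n); used0[pr] <- TRUE
    d0 <- sum((st$rc[ref_root, ] - st$pc[pr, ])^2)
    res <- greedy_descend(st, env, map0, used0, stack = ref_root, ssd = d0)
    if (!is.null(res)) {
      rmsd <- sqrt(res$ssd / n)
      if (is.null(best) || rmsd < best$rmsd - 1e-12) {
        best <- list(pairs = data.frame(ref_atom = seq_len(n),
                                        probe_atom = res$map),
                     rmsd = rmsd)
      }
    }
  }
  best
}

# Recursive descent.  `stack` holds mapped ref atoms whose neighbourhoods
# may still contain unmapped atoms (LIFO = depth-first).  Returns
# list(map, ssd) for the first (greedy) completion, or NULL.
greedy_descend <- function(st, env, map, used, stack, ssd) {
  # find the deepest stacked atom with unmapped neighbours
  while (length(stack) > 0) {
    r <- stack[length(stack)]
    rn <- st$radj[[r]][is.na(map[st$radj[[r]]])]
    if (length(rn) > 0) break
    stack <- stack[-length(stack)]
  }
  if (length(stack) == 0) {
    if (!anyNA(map)) return(list(map = map, ssd = ssd))
    return(NULL)  # disconnected remainder: cannot happen within a component
  }
  p <- map[r]
  pn <- st$padj[[p]][!used[st$padj[[p]]]]
  if (length(pn) != length(rn)) return(NULL)
  cands <- enumerate_assignments(st, map, r, p, rn, pn)
  if (length(cands) == 0) return(NULL)
  ord <- order(vapply(cands, `[[`, numeric(1), "dssd"))
  for (k in seq_along(ord)) {
    if (k > 1) {
      if (env$budget <= 0) return(NULL)
      env$budget <- env$budget - 1
    }
    cand <- cands[[ord[k]]]
    map2 <- map; used2 <- used
    map2[rn] <- cand$assign
    used2[cand$assign] <- TRUE
    res <- greedy_descend(st, env, map2, used2,
                          stack = c(stack, rn), ssd = ssd + cand$dssd)
    if (!is.null(res)) return(res)
  }
  NULL
}

# All signature- and adjacency-consistent bijections rn -> pn, each with the
# squared-distance increment it contributes.
enumerate_assignments <- function(st, map, r, p, rn, pn) {
  k <- length(rn)
  # pairwise feasibility: signature equality, matching edge order to the
  # current atom, and adjacency consistency with all previously mapped atoms
  feas <- matrix(FALSE, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      feas[a, b] <- pair_feasible(st, map, rn[a], pn[b], r, p)
    }
  }
  perms <- permutations_of(k)
  out <- list()
  for (pi in seq_len(nrow(perms))) {
    perm <- perms[pi, ]
    ok <- all(feas[cbind(seq_len(k), perm)])
    if (!ok) next
    assign <- pn[perm]
    # candidates must also be mutually consistent (edges among rn themselves)
    if (k > 1 && !candidates_consistent(st, rn, assign)) next
    d <- st$rc[rn, , drop = FALSE] - st$pc[assign, , drop = FALSE]
    out[[length(out) + 1]] <- list(assign = assign, dssd = sum(d^2))
  }
  out
}

pair_feasible <- function(st, map, nr, np, r, p) {
  if (st$rsig[nr] != st$psig[np]) return(FALSE)
  if (st$strict) {
    if (bond_order_between(st$rlook, r, nr) !=
        bond_order_between(st$plook, p, np)) return(FALSE)
  }
  # adjacency consistency with every already-mapped atom
  for (m in st$radj[[nr]]) {
    pm <- map[m]
    if (is.na(pm)) next
    if (!pm %in% st$padj[[np]]) return(FALSE)
    if (st$strict && bond_order_between(st$rlook, nr, m) !=
        bond_order_between(st$plook, np, pm)) return(FALSE)
  }
  # degree of mapped neighbours must agree in both directions
  n_mapped_r <- sum(!is.na(map[st$radj[[nr]]]))
  pmapped <- st$padj[[np]][st$padj[[np]] %in% map[!is.na(map)]]
  n_mapped_p <- length(pmapped)
  n_mapped_r == n_mapped_p
}

candidates_consistent <- function(st, rn, assign) {
  k <- length(rn)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      re <- bond_order_between(st$rlook, rn[a], rn[b])
      pe <- bond_order_between(st$plook, assign[a], assign[b])
      if (st$strict) {
        if (re != pe) return(FALSE)
      } else {
        if (nzchar(re) != nzchar(pe)) return(FALSE)
      }
    }
  }
  TRUE
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

# ---- exhaustive engine ----------------------------------------------------

# Enumerate every signature-consistent isomorphism of one component pair and
# keep the minimum-SSD mapping (ties: lexicographically smallest probe list,
# guaranteed by visiting candidates in ascending index order and replacing
# only on strict improvement).
exhaustive_match_component <- function(ref, probe, strict, max_backtracks) {
  n <- n_atoms(ref)
  rsig <- atom_signatures(ref, strict = strict)
  psig <- atom_signatures(probe, strict = strict)
  if (!identical(sort(rsig), sort(psig))) return(NULL)
  radj <- adjacency_list(ref); padj <- adjacency_list(probe)
  rlook <- bond_order_lookup(ref); plook <- bond_order_lookup(probe)
  rc <- coords(ref); pc <- coords(probe)
  # visit ref atoms in a BFS order so each new atom (after the first) has a
  # previously visited neighbour; keeps the search tree narrow
  order_bfs <- integer(0); seen <- rep(FALSE, n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order_bfs <- c(order_bfs, v)
    nxt <- radj[[v]][!seen[radj[[v]]]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  if (length(order_bfs) < n) return(NULL)  # disconnected (cannot happen)
  best <- new.env(parent = emptyenv())
  best$ssd <- Inf; best$map <- NULL
  edge_ok <- function(a, b, pa, pb) {
    re <- bond_order_between(rlook, a, b)
    pe <- bond_order_between(plook, pa, pb)
    if (strict) identical(re, pe) else nzchar(re) == nzchar(pe)
  }
  recurse <- function(step, map, used, ssd) {
    if (ssd >= best$ssd) return(invisible())  # bound: ssd only grows
    if (step > n) {
      best$ssd <- ssd; best$map <- map
      return(invisible())
    }
    r <- order_bfs[step]
    for (p in seq_len(n)) {
      if (used[p] || psig[p] != rsig[r]) next
      ok <- TRUE
      for (m in radj[[r]]) {
        pm <- map[m]
        if (is.na(pm)) next
        if (!pm %in% padj[[p]] || !edge_ok(r, m, p, pm)) { ok <- FALSE; break }
      }
      if (!ok) next
      # reverse direction: mapped probe neighbours of p must be images of
      # mapped ref neighbours of r
      pmapped <- padj[[p]][used[padj[[p]]]]
      if (length(pmapped) != sum(!is.na(map[radj[[r]]]))) next
      map[r] <- p; used[p] <- TRUE
      recurse(step + 1, map, used, ssd + sum((rc[r, ] - pc[p, ])^2))
      map[r] <- NA_integer_; used[p] <- FALSE
    }
    invisible()
  }
  recurse(1L, rep(NA_integer_, n), rep(FALSE, n), 0)
  if (is.null(best$map)) return(NULL)
  list(pairs = data.frame(ref_atom = seq_len(n), probe_atom = best$map),
       rmsd = sqrt(best$ssd / n))
}
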