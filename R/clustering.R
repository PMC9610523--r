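# Pose clustering on the pairwise RMSD matrix: the gromos neighbour-count
# algorithm plus agglomerative single- and complete-linkage, all driven by a
# distance cutoff and a minimum cluster size.

#' Pairwise pose-RMSD matrix
#'
#' Builds the symmetric N x N matrix whose (i, j) entry is the heavy-atom
#' RMSD between pose i and pose j.  When every pose carries the same element
#' sequence (the usual case for the output of a single docking run) the
#' identity mapping is used directly; otherwise per-pair atom matching is
#' invoked.
#'
#' @param poses List of [molgraph] objects, length >= 2.
#' @return Symmetric numeric matrix with a zero diagonal.
#' @export
rmsd_matrix <- function(poses) {
  stopifnot(is.list(poses), length(poses) >= 2)
  heavy <- lapply(poses, strip_hydrogens)
  n <- length(heavy)
  seqs <- vapply(heavy, function(m) paste(m$atoms$element, collapse = ","),
                 character(1))
  same_order <- all(seqs == seqs[1])
  mat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      val <- if (same_order) {
        d <- coords(heavy[[i]]) - coords(heavy[[j]])
        sqrt(mean(rowSums(d^2)))
      } else {
        tryCatch(match_atoms(heavy[[i]], heavy[[j]])$rmsd,
                 error = function(e) {
          abort(paste0("poses ", i, " and ", j, " are incompatible: ",
                       conditionMessage(e)), class = "dockpose_incompatible")
        })
      }
      mat[i, j] <- val
      mat[j, i] <- val
    }
  }
  mat
}

#' Cluster docked poses on a pairwise RMSD matrix
#'
#' Groups poses whose mutual RMSD is small, with one of three algorithms:
#'
#' * **gromos**: the pose with the most neighbours (RMSD <= `cutoff`) seeds
#'   a cluster together with those neighbours; all of them leave the pool and
#'   the count is repeated until the pool is empty.  The representative is
#'   the cluster centre.  Ties in neighbour count go to the lowest pose
#'   index.
#' * **single** / **complete** linkage: agglomerative merging of the pair of
#'   clusters at the lowest linkage distance (minimum respectively maximum
#'   member-pair RMSD), as long as that distance is strictly below `cutoff`.
#'   Equal merge distances are resolved by the lexicographically smallest
#'   index pair.  The representative is the member with the best (lowest)
#'   score, or the lowest index when scores are absent.
#'
#' Groups smaller than `min_size` are reported as unclustered.  Clusters are
#' ordered by size (descending), then by formation order.
#'
#' @param x A symmetric RMSD matrix from [rmsd_matrix()], or a list of
#'   [molgraph] poses (the matrix is then computed here).
#' @param algorithm `"gromos"` (default), `"single"` or `"complete"`.
#' @param cutoff RMSD cutoff in Angstrom (default 1.0).
#' @param min_size Minimum cluster size (default 4).
#' @param scores Optional numeric vector of per-pose docking scores (lower =
#'   better), e.g. `extract_scores()$score`.
#' @return A `pose_clustering` object; see [tidy.pose_clustering()],
#'   [glance.pose_clustering()], [autoplot.pose_clustering()] and
#'   [cluster_report()].
#' @examples
#' set.seed(NULL)
#' ps <- generate_pose_set(generate_molecule(8, seed = 1), k = 2,
#'                         sizes = c(4, 3), seed = 9)
#' cl <- cluster_poses(ps$poses, cutoff = 1, min_size = 1,
#'                     scores = ps$scores)
#' glance(cl)
#' @export
cluster_poses <- function(x, algorithm = c("gromos", "single", "complete"),
                          cutoff = 1.0, min_size = 4, scores = NULL) {
  algorithm <- match.arg(algorithm)
  if (cutoff <= 0) {
    abort("cutoff must be positive (Angstrom)", class = "dockpose_user_error")
  }
  if (min_size < 1) {
    abort("min_size must be >= 1", class = "dockpose_user_error")
  }
  mat <- if (is.matrix(x)) x else rmsd_matrix(x)
  check_distance_matrix(mat)
  n <- nrow(mat)
  if (!is.null(scores)) stopifnot(length(scores) == n)
  groups <- if (algorithm == "gromos") {
    gromos_groups(mat, cutoff)
  } else {
    linkage_groups(mat, cutoff, method = algorithm)
  }
  # representative per group
  reps <- vapply(seq_along(groups), function(g) {
    members <- groups[[g]]
    if (algorithm == "gromos") {
      members[1]  # the centre, recorded first at formation
    } else if (!is.null(scores) && !all(is.na(scores[members]))) {
      members[which.min(scores[members])]
    } else {
      min(members)
    }
  }, integer(1))
  sizes <- lengths(groups)
  keep <- sizes >= min_size
  ord <- order(-sizes[keep])
  kept <- which(keep)[ord]
  clusters <- tibble(
    cluster = seq_along(kept),
    size = sizes[kept],
    representative = reps[kept],
    score = if (is.null(scores)) NA_real_ else scores[reps[kept]],
    members = lapply(kept, function(g) {
      m <- groups[[g]]
      c(reps[g], sort(setdiff(m, reps[g])))  # representative first
    }))
  unclustered <- sort(unlist(groups[!keep]))
  if (is.null(unclustered)) unclustered <- integer()
  structure(list(clusters = clusters, unclustered = as.integer(unclustered),
                 n = n, algorithm = algorithm, cutoff = cutoff,
                 min_size = min_size,
                 scores = if (is.null(scores)) rep(NA_real_, n) else scores),
            class = "pose_clustering")
}

check_distance_matrix <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    abort("distance matrix must be square", class = "dockpose_user_error")
  }
  if (any(!is.finite(mat)) || any(mat < 0) ||
      any(abs(diag(mat)) > 1e-9) || any(abs(mat - t(mat)) > 1e-9)) {
    abort("distance matrix must be finite, non-negative, symmetric with a zero diagonal",
          class = "dockpose_user_error")
  }
}

# gromos: returns groups in formation order, centre first within each group
gromos_groups <- function(mat, cutoff) {
  n <- nrow(mat)
  pool <- seq_len(n)
  groups <- list()
  while (length(pool) > 0) {
    sub <- mat[pool, pool, drop = FALSE]
    nb_counts <- rowSums(sub <= cutoff) - 1L  # exclude self
    centre_pos <- which.max(nb_counts)        # ties -> lowest pose index
    centre <- pool[centre_pos]
    members <- pool[sub[centre_pos, ] <= cutoff]
    groups[[length(groups) + 1]] <- c(centre, sort(setdiff(members, centre)))
    pool <- setdiff(pool, members)
  }
  groups
}

# agglomerative linkage: merge while the lowest linkage distance < cutoff
linkage_groups <- function(mat, cutoff, method) {
  n <- nrow(mat)
  groups <- as.list(seq_len(n))
  link <- function(a, b) {
    d <- mat[groups[[a]], groups[[b]], drop = FALSE]
    if (method == "single") min(d) else max(d)
  }
  repeat {
    k <- length(groups)
    if (k == 1) break
    best <- NULL
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        d <- link(a, b)
        if (is.null(best) || d < best$d - 1e-12) best <- list(a = a, b = b, d = d)
        # ties: keep the first (lexicographically smallest) pair, i.e. do
        # not replace on equality -- groups are ordered by smallest member
      }
    }
    if (best$d >= cutoff) break
    merged <- sort(c(groups[[best$a]], groups[[best$b]]))
    groups <- groups[-c(best$a, best$b)]
    groups[[length(groups) + 1]] <- merged
    # keep groups ordered by their smallest member for deterministic ties
    groups <- groups[order(vapply(groups, min, integer(1)))]
  }
  groups
}

#' @export
print.pose_clustering <- function(x, ...) {
  cat("<pose_clustering> ", x$algorithm, " on ", x$n, " poses (cutoff ",
      x$cutoff, " A, min size ", x$min_size, "): ", nrow(x$clusters),
      " cluster(s), ", length(x$unclustered), " unclustered\n", sep = "")
  print(select(x$clusters, -"members"))
  invisible(x)
}

#' Per-pose cluster assignments
#'
#' @param x A `pose_clustering`.
#' @param ... Unused.
#' @return A tibble with one row per pose: `pose_index`, `cluster` (`NA` for
#'   unclustered poses), `is_representative`, `score`.
#' @method tidy pose_clustering
#' @export
tidy.pose_clustering <- function(x, ...) {
  assign <- rep(NA_integer_, x$n)
  is_rep <- rep(FALSE, x$n)
  for (k in seq_len(nrow(x$clusters))) {
    assign[x$clusters$members[[k]]] <- x$clusters$cluster[k]
    is_rep[x$clusters$representative[k]] <- TRUE
  }
  tibble(pose_index = seq_len(x$n), cluster = assign,
         is_representative = is_rep, score = x$scores)
}

#' One-row clustering summary
#'
#' @param x A `pose_clustering`.
#' @param ... Unused.
#' @return A one-row tibble: `n_poses`, `n_clusters`, `n_unclustered`,
#'   `largest_size`, `algorithm`, `cutoff`, `min_size`.
#' @method glance pose_clustering
#' @export
glance.pose_clustering <- function(x, ...) {
  tibble(n_poses = x$n, n_clusters = nrow(x$clusters),
         n_unclustered = length(x$unclustered),
         largest_size = if (nrow(x$clusters)) max(x$clusters$size) else 0L,
         algorithm = x$algorithm, cutoff = x$cutoff, min_size = x$min_size)
}

#' Cluster table and bar-plot series
#'
#' The standard two outputs of a pose-clustering run: a table with one row
#' per cluster (members listed representative-first) and the series behind
#' the cluster bar plot -- one bar per cluster at x = representative score,
#' height = cluster population.
#'
#' @param clustering A `pose_clustering`.
#' @param scores Optional per-pose scores overriding those stored in the
#'   clustering.
#' @return A list with `table` (tibble: `cluster`, `size`, `representative`,
#'   `representative_score`, `members` as a comma-separated string) and
#'   `bars` (tibble: `cluster`, `score`, `size`).
#' @export
cluster_report <- function(clustering, scores = NULL) {
  stopifnot(inherits(clustering, "pose_clustering"))
  cl <- clustering$clusters
  sc <- if (is.null(scores)) clustering$scores else scores
  rep_score <- if (all(is.na(sc))) rep(NA_real_, nrow(cl)) else
    sc[cl$representative]
  table <- tibble(cluster = cl$cluster, size = cl$size,
                  representative = cl$representative,
                  representative_score = rep_score,
                  members = vapply(cl$members, paste, character(1),
                                   collapse = ","))
  list(table = table,
       bars = tibble(cluster = cl$cluster, score = rep_score, size = cl$size))
}

#' Bar plot of cluster populations against representative scores
#'
#' @param object A `pose_clustering`.
#' @param ... Unused.
#' @return A ggplot: one bar per cluster, x = representative score (docking
#'   program units), y = number of conformations.
#' @method autoplot pose_clustering
#' @export
autoplot.pose_clustering <- function(object, ...) {
  bars <- cluster_report(object)$bars
  if (all(is.na(bars$score))) bars$score <- bars$cluster
  ggplot2::ggplot(bars, ggplot2::aes(x = .data$score, y = .data$size)) +
    ggplot2::geom_col(width = diff(range(bars$score, finite = TRUE)) / 25 +
                        1e-3, fill = "steelblue") +
    ggplot2::labs(x = "representative score", y = "conformations in cluster",
                  title = paste0(object$algorithm, " clustering (cutoff ",
                                 object$cutoff, " Å)")) +
    ggplot2::theme_minimal()
}
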