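dist_from_pairs <- function(n, pairs, default = 5) {
  m <- matrix(default, n, n)
  diag(m) <- 0
  for (p in pairs) {
    m[p[1], p[2]] <- p[3]
    m[p[2], p[1]] <- p[3]
  }
  m
}

test_that("the pairwise matrix is symmetric with the expected entries", {
  mol <- generate_molecule(8, seed = 501)
  poses <- list(mol, mol, mol)
  m <- rmsd_matrix(poses)
  expect_equal(m, matrix(0, 3, 3))

  poses2 <- list(mol, translate_mol(mol, 2))
  m2 <- rmsd_matrix(poses2)
  expect_equal(m2[1, 2], 2, tolerance = 1e-12)
  expect_equal(m2, t(m2))

  # permuted poses trigger per-pair matching and still give exact distances
  poses3 <- list(mol, permute_atoms(translate_mol(mol, 2), seed = 5))
  expect_equal(rmsd_matrix(poses3)[1, 2], 2, tolerance = 1e-9)

  expect_error(rmsd_matrix(list(mol, generate_molecule(5, seed = 2))),
               class = "dockpose_incompatible")
})

test_that("gromos clustering follows the neighbour-count rule", {
  # 5 identical structures: one cluster of five, centre = pose 1
  m0 <- matrix(0, 5, 5)
  cl0 <- cluster_poses(m0, "gromos", cutoff = 1, min_size = 1)
  expect_equal(nrow(cl0$clusters), 1)
  expect_equal(cl0$clusters$representative, 1)
  expect_equal(cl0$clusters$members[[1]], 1:5)

  # hand-enumerated: d(A,B)=0.3, d(A,C)=0.4, d(B,C)=0.6, D far away
  m <- dist_from_pairs(4, list(c(1, 2, 0.3), c(1, 3, 0.4), c(2, 3, 0.6)))
  cl <- cluster_poses(m, "gromos", cutoff = 0.5, min_size = 1)
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$clusters$members[[1]], c(1, 2, 3))  # centre A first
  expect_equal(cl$clusters$representative[1], 1)      # A has 2 neighbours
  expect_equal(cl$clusters$members[[2]], 4)

  # min-size filtering pushes the singleton to unclustered
  cl2 <- cluster_poses(m, "gromos", cutoff = 0.5, min_size = 2)
  expect_equal(nrow(cl2$clusters), 1)
  expect_equal(cl2$unclustered, 4L)
})

test_that("gromos members lie within the cutoff of their centre", {
  for (s in 1:30) {
    withr::local_seed(6000 + s)
    m <- random_distance_matrix(12)
    cl <- cluster_poses(m, "gromos", cutoff = 0.8, min_size = 1)
    for (k in seq_len(nrow(cl$clusters))) {
      centre <- cl$clusters$representative[k]
      expect_true(all(m[centre, cl$clusters$members[[k]]] <= 0.8))
    }
    # partition property
    all_poses <- sort(c(unlist(cl$clusters$members), cl$unclustered))
    expect_equal(all_poses, 1:12)
  }
})

test_that("single- and complete-linkage differ exactly as the chain example shows", {
  # d(A,B)=0.4, d(B,C)=0.4, d(A,C)=0.8, cutoff 0.5
  m <- dist_from_pairs(3, list(c(1, 2, 0.4), c(2, 3, 0.4), c(1, 3, 0.8)))
  single <- cluster_poses(m, "single", cutoff = 0.5, min_size = 1)
  expect_equal(nrow(single$clusters), 1)
  expect_equal(single$clusters$members[[1]], 1:3)
  complete <- cluster_poses(m, "complete", cutoff = 0.5, min_size = 1)
  expect_equal(nrow(complete$clusters), 2)
  # first merge is the lexicographically smallest tied pair: {A,B}
  expect_equal(complete$clusters$members[[1]], c(1, 2))
  expect_equal(complete$clusters$members[[2]], 3)
})

test_that("when all distances exceed the cutoff, linkage returns singletons", {
  m <- dist_from_pairs(4, list(), default = 3)
  cl <- cluster_poses(m, "single", cutoff = 1, min_size = 1)
  expect_equal(nrow(cl$clusters), 4)
  expect_true(all(cl$clusters$size == 1))
  cl2 <- cluster_poses(m, "complete", cutoff = 1, min_size = 2)
  expect_equal(nrow(cl2$clusters), 0)
  expect_equal(cl2$unclustered, 1:4)
})

test_that("single linkage equals connected components of the threshold graph", {
  for (s in 1:60) {
    withr::local_seed(7000 + s)
    n <- sample(4:15, 1)
    m <- random_distance_matrix(n)
    cutoff <- runif(1, 0.3, 1.5)
    cl <- cluster_poses(m, "single", cutoff = cutoff, min_size = 1)
    got <- tidy(cl)$cluster
    want <- threshold_components(m, cutoff)
    # same partition up to label names
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("complete-linkage clusters have diameter at most the cutoff", {
  for (s in 1:40) {
    withr::local_seed(8000 + s)
    m <- random_distance_matrix(12)
    cutoff <- runif(1, 0.3, 1.5)
    cl <- cluster_poses(m, "complete", cutoff = cutoff, min_size = 1)
    for (mem in cl$clusters$members) {
      if (length(mem) > 1) expect_lte(max(m[mem, mem]), cutoff)
    }
  }
})

test_that("linkage representatives take the best score, gromos the centre", {
  m <- dist_from_pairs(3, list(c(1, 2, 0.2), c(2, 3, 0.2), c(1, 3, 0.3)))
  scores <- c(-5, -9, -7)
  single <- cluster_poses(m, "single", cutoff = 0.5, min_size = 1,
                          scores = scores)
  expect_equal(single$clusters$representative, 2)  # lowest score
  expect_equal(single$clusters$score, -9)
  expect_equal(single$clusters$members[[1]], c(2, 1, 3))  # rep listed first
  # no scores: lowest index
  single2 <- cluster_poses(m, "single", cutoff = 0.5, min_size = 1)
  expect_equal(single2$clusters$representative, 1)
  # gromos keeps its centre even when another member scores better: with
  # cutoff 0.25 only pose 2 has two neighbours, so it is the centre
  grom <- cluster_poses(m, "gromos", cutoff = 0.25, min_size = 1,
                        scores = c(-9, -5, -7))
  expect_equal(grom$clusters$representative[1], 2)
})

test_that("report, tidy, glance and autoplot expose the clustering", {
  m <- dist_from_pairs(5, list(c(1, 2, 0.2), c(1, 3, 0.2), c(2, 3, 0.2)))
  scores <- c(-7.5, -7.1, -6.9, -5, -4.8)
  cl <- cluster_poses(m, "gromos", cutoff = 0.5, min_size = 1,
                      scores = scores)
  rep <- cluster_report(cl)
  expect_equal(rep$table$size[1], 3)
  expect_equal(rep$table$members[1], "1,2,3")
  expect_equal(rep$bars$score[1], -7.5)
  expect_equal(rep$bars$size, rep$table$size)

  td <- tidy(cl)
  expect_equal(nrow(td), 5)
  expect_equal(td$cluster[1:3], rep(1L, 3))
  expect_true(td$is_representative[1])

  gl <- glance(cl)
  expect_equal(gl$n_clusters, 3)
  expect_equal(gl$largest_size, 3)

  p <- autoplot(cl)
  expect_s3_class(p, "ggplot")

  # empty clustering: empty table and series
  m2 <- dist_from_pairs(2, list(), default = 4)
  cl2 <- cluster_poses(m2, "gromos", cutoff = 1, min_size = 2)
  rep2 <- cluster_report(cl2)
  expect_equal(nrow(rep2$table), 0)
  expect_equal(nrow(rep2$bars), 0)
})

test_that("degenerate and invalid matrices are rejected", {
  expect_error(cluster_poses(matrix(c(0, 1, 2, 0), 2, 2), cutoff = 1,
                             min_size = 1),
               class = "dockpose_user_error")  # asymmetric
  m <- matrix(0, 3, 3)
  expect_error(cluster_poses(m, cutoff = -1, min_size = 1),
               class = "dockpose_user_error")
  expect_error(cluster_poses(m, cutoff = 1, min_size = 0),
               class = "dockpose_user_error")
})
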