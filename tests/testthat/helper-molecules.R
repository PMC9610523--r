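# Small hand-built molecules used across the suite.  Everything is built in
# code; no binary fixtures.

# ethanol with explicit hydrogens: C-C-O heavy skeleton, 6 H
ethanol_full <- function() {
  molgraph(
    atoms = data.frame(
      element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
      x = c(0, 1.5, 2.0, -0.36, -0.36, -0.36, 1.86, 1.86, 2.96),
      y = c(0, 0, 1.35, 1.02, -0.51, -0.51, -0.51, -0.51, 1.35),
      z = c(0, 0, 0, 0, 0.88, -0.88, 0.88, -0.88, 0)),
    bonds = data.frame(i = c(1, 2, 1, 1, 1, 2, 2, 3),
                       j = c(2, 3, 4, 5, 6, 7, 8, 9),
                       order = "single"),
    name = "ethanol")
}

water_mol <- function() {
  molgraph(
    atoms = data.frame(element = c("O", "H", "H"),
                       x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0),
    bonds = data.frame(i = c(1, 1), j = c(2, 3), order = "single"),
    name = "water")
}

# hydrogen-free benzene, regular hexagon of radius 1.396 A, aromatic bonds
benzene_mol <- function(order = "aromatic") {
  ang <- 2 * pi * (0:5) / 6
  ords <- if (length(order) == 1) rep(order, 6) else order
  molgraph(
    atoms = data.frame(element = "C", x = round(1.396 * cos(ang), 4),
                       y = round(1.396 * sin(ang), 4), z = 0),
    bonds = data.frame(i = 1:6, j = c(2:6, 1), order = ords),
    name = "benzene")
}

propane_mol <- function() {
  molgraph(
    atoms = data.frame(element = "C", x = c(0, 1.5, 3), y = c(0, 0.8, 0), z = 0),
    bonds = data.frame(i = 1:2, j = 2:3, order = "single"),
    name = "propane-heavy")
}

acetone_mol <- function() {
  molgraph(
    atoms = data.frame(element = c("C", "C", "C", "O"),
                       x = c(-1.3, 0, 1.3, 0), y = c(-0.8, 0, -0.8, 1.22),
                       z = 0),
    bonds = data.frame(i = c(1, 2, 2), j = c(2, 3, 4),
                       order = c("single", "single", "double")),
    name = "acetone-heavy")
}

# translate every atom by (dx, dy, dz)
translate_mol <- function(mol, dx = 0, dy = 0, dz = 0) {
  mol$atoms$x <- mol$atoms$x + dx
  mol$atoms$y <- mol$atoms$y + dy
  mol$atoms$z <- mol$atoms$z + dz
  mol
}

# connected components of the thresholded graph: independent oracle for
# single-linkage clustering (pure BFS, no igraph)
threshold_components <- function(mat, cutoff) {
  n <- nrow(mat)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(mat[v, ] <= cutoff & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# random symmetric distance matrix with zero diagonal
random_distance_matrix <- function(n, scale = 2) {
  m <- matrix(runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
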