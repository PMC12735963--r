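# Independent oracles and small fixture builders shared across tests.

# --- fixtures -----------------------------------------------------------

# minimal ensemble from a list of N x 3 frames
frames_to_ensemble <- function(frames, ...) {
  arr <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
  ensemble(arr, ...)
}

# Calpha-only topology with n residues
ca_topology <- function(n) {
  topology(data.frame(name = "CA", element = "C", resno = seq_len(n),
                      resname = "GLY", hetatm = FALSE,
                      stringsAsFactors = FALSE))
}

# write a small PDB with given residues; one CA per residue plus optional
# HETATM ligand residue
write_fixture_pdb <- function(path, n_res = 3, ligand = FALSE) {
  lines <- character(0)
  for (i in seq_len(n_res))
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, i, i * 3.8, 0, 0))
  if (ligand) {
    lines <- c(lines,
      sprintf("HETATM%5d  N   LIG A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
              n_res + 1L, n_res + 1L, 1.0, 2.0, 0),
      sprintf("HETATM%5d  C1  LIG A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              n_res + 2L, n_res + 1L, 2.0, 2.0, 0))
  }
  writeLines(c(lines, "END"), path)
  path
}

rigid_rotate <- function(xyz, angles = c(0.3, -0.5, 0.9), shift = c(1, -2, 3)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  xyz %*% t(Rz %*% Ry %*% Rx) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
}

# --- naive-summation oracles -------------------------------------------

oracle_rmsd <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a)))
    s <- s + sum((a[i, ] - b[i, ])^2)
  sqrt(s / nrow(a))
}

oracle_rg <- function(xyz, w = rep(1, nrow(xyz))) {
  com <- c(sum(w * xyz[, 1]), sum(w * xyz[, 2]), sum(w * xyz[, 3])) / sum(w)
  s <- 0
  for (i in seq_len(nrow(xyz)))
    s <- s + w[i] * sum((xyz[i, ] - com)^2)
  sqrt(s / sum(w))
}

oracle_rmsf <- function(frames_list) {
  # frames assumed already aligned; per-atom RMSF by explicit loops
  f <- length(frames_list); n <- nrow(frames_list[[1]])
  out <- numeric(n)
  for (i in seq_len(n)) {
    mu <- c(0, 0, 0)
    for (k in seq_len(f)) mu <- mu + frames_list[[k]][i, ]
    mu <- mu / f
    s <- 0
    for (k in seq_len(f)) s <- s + sum((frames_list[[k]][i, ] - mu)^2)
    out[i] <- sqrt(s / f)
  }
  out
}

oracle_dccm <- function(frames_list) {
  f <- length(frames_list); n <- nrow(frames_list[[1]])
  mu <- matrix(0, n, 3)
  for (k in seq_len(f)) mu <- mu + frames_list[[k]]
  mu <- mu / f
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; di <- 0; dj <- 0
    for (k in seq_len(f)) {
      a <- frames_list[[k]][i, ] - mu[i, ]
      b <- frames_list[[k]][j, ] - mu[j, ]
      num <- num + sum(a * b)
      di <- di + sum(a * a)
      dj <- dj + sum(b * b)
    }
    C[i, j] <- num / sqrt(di * dj)
  }
  C
}

# brute-force rotation-grid + refinement oracle for minimal pairwise RMSD
oracle_min_rmsd <- function(mobile, reference, n_grid = 14) {
  ca <- colMeans(mobile); cb <- colMeans(reference)
  A <- sweep(mobile, 2, ca); B <- sweep(reference, 2, cb)
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  f <- function(ang) sqrt(mean(rowSums((A %*% t(rot(ang)) - B)^2)))
  best <- NULL; bestv <- Inf
  gr <- seq(0, 2 * pi, length.out = n_grid)
  for (a1 in gr) for (a2 in gr[seq_len(n_grid %/% 2)]) for (a3 in gr) {
    v <- f(c(a1, a2, a3))
    if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# brute-force DBSCAN oracle: core points by counting, clusters as connected
# components of the core-core eps-graph (igraph), borders attached to any
# reachable cluster. Returns list(core, noise, partition of core points).
oracle_dbscan <- function(points, eps, min_samples) {
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  nbr <- D <= eps + 1e-12
  core <- which(rowSums(nbr) >= min_samples)
  if (length(core) == 0)
    return(list(core = integer(0), noise = seq_len(n), components = list()))
  sub <- nbr[core, core, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  reached <- rep(FALSE, n)
  for (ci in seq_len(max(comp))) {
    members <- core[comp == ci]
    reach <- which(colSums(nbr[members, , drop = FALSE]) > 0)
    reached[reach] <- TRUE
  }
  noise <- setdiff(which(!reached), core)
  components <- lapply(seq_len(max(comp)), function(ci) sort(core[comp == ci]))
  list(core = core, noise = sort(noise), components = components)
}

# canonical form of a partition (set of sorted index vectors, sorted)
canonical_partition <- function(parts) {
  parts <- unname(lapply(parts, function(p) as.integer(sort(unname(p)))))
  parts[order(vapply(parts, function(p) p[1], numeric(1)))]
}
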