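# Essential-dynamics PCA, k-distance-calibrated DBSCAN state census,
# and Gibbs free-energy landscapes. This is the package's core
# quantification of conformational locking.

#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872

#' Principal-component projection of Calpha coordinates
#'
#' Frames are aligned with the iterative-mean procedure, flattened to
#' 3N-dimensional coordinate vectors, and the covariance eigendecomposition
#' is taken (via singular value decomposition of the centered frame matrix).
#' Frames are projected onto the leading eigenvectors; the first two scores
#' (PC1, PC2) define the landscape plane. Sign convention: each eigenvector's
#' largest-magnitude component is positive.
#'
#' @param x an [ensemble()] with >= 3 frames.
#' @param mask Calpha atom indices; default every atom.
#' @param n_components number of score columns to keep (default 2).
#' @param align if FALSE the frames are assumed pre-aligned.
#' @return Object of class `pc_model`: `mean` (3N), `loadings`
#'   (3N x n_components, orthonormal), `eigenvalues` (all, non-increasing),
#'   `explained` (variance fractions), `scores` (F x n_components).
#' @export
pca_project <- function(x, mask = seq_len(n_atoms(x)), n_components = 2,
                        align = TRUE) {
  stopifnot(inherits(x, "ensemble"))
  if (n_frames(x) < 3)
    stop("insufficient data: PCA needs at least 3 frames", call. = FALSE)
  if (align) x <- align_frames(x, fit_mask = mask, reference = "mean")
  sub <- x$coords[, mask, , drop = FALSE]
  f <- dim(sub)[1]
  X <- matrix(sub, nrow = f)  # 3N columns: all x, then all y, then all z
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(n_components, min(dim(Xc))))
  eig <- sv$d^2 / (f - 1)
  expl <- eig / sum(eig)
  V <- sv$v
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(mean = mu, loadings = V, eigenvalues = eig,
                 explained = expl, scores = scores,
                 n_atoms = length(mask)),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("PC model: %d frames x %d atoms; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), x$n_atoms, 100 * x$explained[1],
              100 * x$explained[2]))
  invisible(x)
}

#' @export
plot.pc_model <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) "#00000055"
         else ifelse(labels < 0, "grey70",
                     grDevices::hcl.colors(max(labels) + 1, "Dark 3")[labels + 1])
  graphics::plot(x$scores[, 1], x$scores[, 2], pch = 20, col = col,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
}

.knn_distance <- function(points, k, chunk = 512L) {
  n <- nrow(points)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(points^2), "+") -
      2 * tcrossprod(block, points)
    d2[d2 < 0] <- 0
    out[s:e] <- apply(d2, 1, function(r) sqrt(sort(r, partial = k + 1)[k + 1]))
  }
  out
}

#' Calibrate DBSCAN eps from the k-distance elbow
#'
#' Computes each point's distance to its k-th nearest neighbor (self
#' excluded), sorts the values ascending, and returns the value at the elbow:
#' the index with maximum perpendicular distance to the chord joining the
#' curve's endpoints (Kneedle criterion, both axes normalized to [0, 1], so
#' the choice is scale-equivariant: scaling the scores by c scales eps by c).
#' A near-linear curve (no clear elbow) raises a warning and returns the
#' chord-maximum anyway.
#'
#' @param projection F x 2 score matrix (or a `pc_model`).
#' @param k neighbor rank (default 4, matching `min_samples`).
#' @return eps (numeric), with attributes `k` and `kdist` (sorted curve).
#' @export
kdistance_eps <- function(projection, k = 4) {
  if (inherits(projection, "pc_model")) projection <- projection$scores[, 1:2]
  projection <- as.matrix(projection)
  n <- nrow(projection)
  if (n <= k)
    stop("insufficient data: need more than k points for a k-distance graph",
         call. = FALSE)
  kd <- sort(.knn_distance(projection, k))
  rng <- kd[n] - kd[1]
  if (rng <= 0) {
    warning("no clear elbow: k-distance curve is flat", call. = FALSE)
    eps <- max(kd[n], .Machine$double.eps)
    return(structure(eps, k = k, kdist = kd))
  }
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (kd - kd[1]) / rng
  # perpendicular distance to the chord from (0,0) to (1,1)
  perp <- abs(ys - xs) / sqrt(2)
  i <- which.max(perp)
  if (perp[i] < 0.05)
    warning("no clear elbow in the k-distance graph; eps may be unreliable",
            call. = FALSE)
  # the chord criterion presumes a separated noise scale above the elbow; a
  # single-scale (unimodal) curve has none, and the max-deviation point then
  # sits mid-curve and shreds the one dense state.  Detect that case -- the
  # curve never rises well clear of the candidate elbow -- and fall back to
  # the upper end of the curve (excluding the extreme tail).
  hi <- kd[ceiling(0.98 * n)]
  if (hi < 3 * kd[i]) {
    warning("no separated noise scale in the k-distance graph; using its upper end as eps",
            call. = FALSE)
    i <- ceiling(0.995 * n)
  }
  structure(kd[i], k = k, kdist = kd, elbow_index = i)
}

#' Density-based clustering with noise (DBSCAN)
#'
#' Own implementation of the classic algorithm on Euclidean distances in raw
#' score units. A point is core iff its eps-neighborhood (including itself)
#' holds at least `min_samples` points; clusters are the connected components
#' of density-reachability, grown by index-ordered expansion so border points
#' join the first cluster that reaches them; remaining points are noise.
#'
#' @param projection F x 2 score matrix (or a `pc_model`).
#' @param eps neighborhood radius (> 0), in score units.
#' @param min_samples minimum neighborhood size for a core point (>= 1; with
#'   1 every point is core and noise is impossible).
#' @return Integer labels: 0, 1, ... for clusters, -1 for noise.
#' @export
dbscan_cluster <- function(projection, eps, min_samples = 4) {
  if (inherits(projection, "pc_model")) projection <- projection$scores[, 1:2]
  projection <- as.matrix(projection)
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0)
    stop("parameter error: eps must be a single positive number", call. = FALSE)
  if (min_samples < 1)
    stop("parameter error: min_samples must be >= 1", call. = FALSE)
  n <- nrow(projection)
  eps2 <- eps^2
  # neighbor lists via chunked distance computation
  nbrs <- vector("list", n)
  chunk <- 512L
  ss <- rowSums(projection^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- projection[s:e, , drop = FALSE]
    d2 <- outer(ss[s:e], ss, "+") - 2 * tcrossprod(block, projection)
    for (i in seq_len(e - s + 1L))
      nbrs[[s + i - 1L]] <- which(d2[i, ] <= eps2 + 1e-12)
  }
  core <- lengths(nbrs) >= min_samples
  labels <- rep.int(-2L, n)   # -2 = unvisited
  cl <- -1L
  for (p in seq_len(n)) {
    if (labels[p] != -2L) next
    if (!core[p]) { labels[p] <- -1L; next }
    cl <- cl + 1L
    labels[p] <- cl
    queue <- nbrs[[p]]
    qi <- 1L
    while (qi <= length(queue)) {
      q <- queue[qi]; qi <- qi + 1L
      if (labels[q] == -1L) labels[q] <- cl       # border, previously noise
      if (labels[q] != -2L) next
      labels[q] <- cl
      if (core[q]) queue <- c(queue, nbrs[[q]])
    }
  }
  labels[labels == -2L] <- -1L
  labels
}

#' Conformational state census from cluster labels
#'
#' @param labels integer labels (clusters >= 0, noise -1), e.g. from
#'   [dbscan_cluster()].
#' @return Object of class `state_census`: `n_states`, `noise_fraction`,
#'   `populations` (descending fractions of all frames),
#'   `largest_state_fraction`, and the labels.
#' @export
census <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("labels must be non-empty", call. = FALSE)
  f <- length(labels)
  states <- sort(unique(labels[labels >= 0L]))
  pops <- sort(vapply(states, function(s) sum(labels == s), numeric(1)),
               decreasing = TRUE) / f
  structure(list(labels = labels,
                 n_states = length(states),
                 noise_fraction = mean(labels == -1L),
                 populations = unname(pops),
                 largest_state_fraction = if (length(pops)) pops[1] else 0),
            class = "state_census")
}

#' @export
print.state_census <- function(x, ...) {
  cat(sprintf("State census: %d stable states; %.1f%% noise (transitions); %.1f%% in largest state\n",
              x$n_states, 100 * x$noise_fraction,
              100 * x$largest_state_fraction))
  invisible(x)
}

#' Macrostate population table
#'
#' Top `n_top` states (S1, S2, ...) by population plus an aggregated "Other"
#' row holding the remaining states and the noise fraction; the fractions
#' sum to 1.
#'
#' @param x a `state_census`.
#' @param n_top number of named macrostates (default 6).
#' @return data.frame with `state` and `fraction`.
#' @export
population_table <- function(x, n_top = 6) {
  stopifnot(inherits(x, "state_census"))
  k <- min(n_top, length(x$populations))
  top <- if (k > 0) x$populations[seq_len(k)] else numeric(0)
  other <- 1 - sum(top)
  data.frame(state = c(if (k > 0) paste0("S", seq_len(k)), "Other"),
             fraction = c(top, max(other, 0)),
             stringsAsFactors = FALSE)
}

#' Gibbs free-energy landscape over the PC1/PC2 plane
#'
#' Bins the scores on an equal-width 2D grid spanning the data range,
#' converts bin probabilities to free energies
#' dG = -kB T ln(P / P_max) with kB = 0.0019872 kcal/(mol K), so the modal
#' bin sits at exactly 0 and all energies are >= 0. Empty bins are capped at
#' the maximum finite dG plus one contour-level spacing (dG_max / n_levels)
#' to keep the grid renderable.
#'
#' @param projection F x 2 score matrix (or `pc_model`).
#' @param temperature simulation temperature in K (default 310).
#' @param n_bins bins per axis (>= 2; default 32).
#' @param n_levels contour levels used for rendering and for the empty-bin
#'   cap (default 100).
#' @return Object of class `free_energy_landscape`: bin `edges`,
#'   probability grid `P` (sums to 1), `dG` grid (kcal/mol), `temperature`.
#' @export
fel <- function(projection, temperature = 310, n_bins = 32, n_levels = 100) {
  if (inherits(projection, "pc_model")) projection <- projection$scores[, 1:2]
  projection <- as.matrix(projection)
  if (n_bins < 2) stop("n_bins must be >= 2 per axis", call. = FALSE)
  f <- nrow(projection)
  rng1 <- range(projection[, 1]); rng2 <- range(projection[, 2])
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  rng1 <- pad(rng1); rng2 <- pad(rng2)
  e1 <- seq(rng1[1], rng1[2], length.out = n_bins + 1)
  e2 <- seq(rng2[1], rng2[2], length.out = n_bins + 1)
  i1 <- pmin(pmax(findInterval(projection[, 1], e1, rightmost.closed = TRUE), 1), n_bins)
  i2 <- pmin(pmax(findInterval(projection[, 2], e2, rightmost.closed = TRUE), 1), n_bins)
  P <- matrix(0, n_bins, n_bins)
  for (k in seq_len(f)) P[i1[k], i2[k]] <- P[i1[k], i2[k]] + 1
  P <- P / f
  kbt <- KB_KCAL * temperature
  dG <- matrix(NA_real_, n_bins, n_bins)
  occ <- P > 0
  pmax_ <- max(P)
  dG[occ] <- -kbt * log(P[occ] / pmax_)
  gmax <- max(dG[occ])
  spacing <- if (gmax > 0) gmax / n_levels else kbt * log(2)
  dG[!occ] <- gmax + spacing
  structure(list(edges = list(pc1 = e1, pc2 = e2), P = P, dG = dG,
                 temperature = temperature, kB = KB_KCAL,
                 n_levels = n_levels, cap = gmax + spacing),
            class = "free_energy_landscape")
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf("Free-energy landscape: %d x %d bins at T = %g K; dG range 0 - %.3f kcal/mol (cap %.3f)\n",
              nrow(x$P), ncol(x$P), x$temperature,
              max(x$dG[x$P > 0]), x$cap))
  invisible(x)
}

#' @export
plot.free_energy_landscape <- function(x, ...) {
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  graphics::filled.contour(
    mid(x$edges$pc1), mid(x$edges$pc2), x$dG,
    nlevels = min(x$n_levels, 25),
    color.palette = function(n) grDevices::hcl.colors(n, "viridis"),
    xlab = "PC1", ylab = "PC2",
    key.title = graphics::title(main = "dG\n(kcal/mol)", cex.main = 0.8), ...)
}

#' Fit the conformational landscape of an ensemble
#'
#' The package's central analysis: aligns the ensemble, projects the Calpha
#' coordinates onto PC1/PC2, calibrates eps from the k-distance elbow (unless
#' a fixed eps is supplied, e.g. one frozen from the apo system for
#' cross-system comparability), clusters the projection with DBSCAN, and
#' derives the state census and the Gibbs free-energy landscape.
#'
#' @param x an [ensemble()].
#' @param mask Calpha atom indices; default every atom.
#' @param eps DBSCAN radius in score units; `NULL` (default) calibrates it
#'   with [kdistance_eps()].
#' @param min_samples DBSCAN core threshold (default 4).
#' @param k neighbor rank for the k-distance calibration (default 4).
#' @param temperature temperature in K for the free-energy map (default 310).
#' @param n_bins free-energy grid bins per axis (default 32).
#' @return Object of class `conf_landscape` with components `pca`
#'   (`pc_model`), `eps`, `min_samples`, `labels`, `census`
#'   (`state_census`), `fel` (`free_energy_landscape`) and `system_label`;
#'   methods: `print`, `summary`, `plot`.
#' @export
conformational_landscape <- function(x, mask = seq_len(n_atoms(x)),
                                     eps = NULL, min_samples = 4, k = 4,
                                     temperature = 310, n_bins = 32) {
  stopifnot(inherits(x, "ensemble"))
  pca <- pca_project(x, mask)
  if (is.null(eps)) eps <- kdistance_eps(pca$scores, k = k)
  labels <- dbscan_cluster(pca$scores, eps = as.numeric(eps),
                           min_samples = min_samples)
  cen <- census(labels)
  structure(list(pca = pca, eps = as.numeric(eps), min_samples = min_samples,
                 k = k, labels = labels, census = cen,
                 fel = fel(pca$scores, temperature = temperature,
                           n_bins = n_bins),
                 system_label = x$system_label),
            class = "conf_landscape")
}

#' @export
print.conf_landscape <- function(x, ...) {
  cat(sprintf("Conformational landscape of '%s'\n", x$system_label))
  cat(sprintf("  PCA: PC1+PC2 capture %.1f%% of variance\n",
              100 * sum(x$pca$explained[1:2])))
  cat(sprintf("  DBSCAN: eps = %.4g, min_samples = %d\n", x$eps, x$min_samples))
  print(x$census)
  invisible(x)
}

#' @export
summary.conf_landscape <- function(object, n_top = 6, ...) {
  pt <- population_table(object$census, n_top)
  cat(sprintf("System: %s\n", object$system_label))
  print(object$census)
  cat("Macrostate populations:\n")
  print(transform(pt, percent = sprintf("%.1f%%", 100 * fraction)),
        row.names = FALSE)
  invisible(list(census = object$census, populations = pt))
}

#' @export
plot.conf_landscape <- function(x, which = c("states", "fel"), ...) {
  which <- match.arg(which)
  if (which == "states") plot(x$pca, labels = x$labels, ...)
  else plot(x$fel, ...)
}
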