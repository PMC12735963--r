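# Dynamic cross-correlation matrices and domain-level networks.

#' Dynamic cross-correlation matrix over Calpha atoms
#'
#' After iterative-mean alignment on the mask, computes
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>) where dr is each atom's
#' Cartesian deviation from its time-mean position. Values near +1 indicate
#' residues moving together, near -1 in opposition. Correlations are computed
#' over the concatenated frames with a single global mean (the convention for
#' replicate-concatenated trajectories); no mass weighting.
#'
#' @param x an [ensemble()] (>= 2 frames).
#' @param mask Calpha atom indices; default every atom.
#' @param topology optional [topology()] used to label rows by residue.
#' @param align if FALSE the frames are assumed pre-aligned.
#' @return A `dccm_matrix`: symmetric matrix with unit diagonal, entries in
#'   [-1, 1], attribute `resno` carrying residue numbers.
#' @export
dccm <- function(x, mask = seq_len(n_atoms(x)), topology = NULL,
                 align = TRUE) {
  stopifnot(inherits(x, "ensemble"))
  if (n_frames(x) < 2)
    stop("insufficient data: DCCM needs at least 2 frames", call. = FALSE)
  if (align) x <- align_frames(x, fit_mask = mask, reference = "mean")
  sub <- x$coords[, mask, , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  dev <- sweep(sub, c(2, 3), mu)
  f <- dim(dev)[1]
  # numerator_ij = sum_t sum_d dev[t,i,d] dev[t,j,d] / f
  num <- (crossprod(dev[, , 1]) + crossprod(dev[, , 2]) +
            crossprod(dev[, , 3])) / f
  v <- diag(num)
  if (any(v <= 1e-300)) {
    bad <- which(v <= 1e-300)[1]
    stop(sprintf("undefined correlation: atom %d (mask position) has zero variance",
                 bad), call. = FALSE)
  }
  C <- num / sqrt(outer(v, v))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  resno <- if (!is.null(topology)) topology$resno[mask] else seq_along(mask)
  dimnames(C) <- list(resno, resno)
  structure(C, resno = resno, class = c("dccm_matrix", "matrix", "array"))
}

#' @export
print.dccm_matrix <- function(x, ...) {
  n <- nrow(x)
  off <- x[upper.tri(x)]
  cat(sprintf("DCCM: %d x %d residues; off-diagonal mean %.3f, range [%.3f, %.3f]\n",
              n, n, mean(off), min(off), max(off)))
  invisible(x)
}

#' @export
plot.dccm_matrix <- function(x, ...) {
  n <- nrow(x)
  pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(101)
  graphics::image(seq_len(n), seq_len(n), unclass(x)[, n:1],
                  zlim = c(-1, 1), col = pal,
                  xlab = "residue", ylab = "residue", ...)
}

#' Named residue-set map of functional domains
#'
#' The default map carries the C-terminal domain (residues 339-480, which
#' encloses the leucine-binding site of Sestrin2) and the redox-sensitive
#' Cys125; further domains (NTD, GATOR2 docking domain, Leu lid/latch) have
#' no published residue ranges and must be supplied by the caller.
#'
#' @param ... named residue-number vectors, e.g. `CTD = 339:480`.
#' @param topology optional [topology()]; if given, membership is validated.
#' @return Object of class `domain_map` (named list).
#' @export
domain_map <- function(..., topology = NULL) {
  domains <- list(...)
  if (length(domains) == 1L && is.list(domains[[1]]) &&
      !is.null(names(domains[[1]])))
    domains <- domains[[1]]
  if (length(domains) == 0L)
    domains <- list(CTD = 339:480, Cys125 = 125L)
  if (is.null(names(domains)) || any(names(domains) == "") ||
      anyDuplicated(names(domains)))
    stop("domains must have unique non-empty names", call. = FALSE)
  if (any(vapply(domains, length, integer(1)) == 0L))
    stop("domains must be non-empty", call. = FALSE)
  if (!is.null(topology)) {
    for (nm in names(domains)) {
      missing <- setdiff(domains[[nm]], topology$resno)
      if (length(missing))
        stop(sprintf("mapping error: domain '%s' residues not in topology: %s",
                     nm, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  structure(lapply(domains, as.integer), class = "domain_map")
}

#' Reduce a DCCM to a domain-level network
#'
#' Edge weight between two domains is the signed mean of C_ij over i in one
#' domain and j in the other; the self-weight of a domain is the mean over
#' its unordered intra-domain pairs (i < j). Sign is retained so positively
#' and negatively coupled domain pairs are distinguished.
#'
#' @param C a `dccm_matrix` from [dccm()].
#' @param map a [domain_map()].
#' @return Object of class `domain_network`: list with `nodes`, symmetric
#'   `weights` matrix in [-1, 1] and the map.
#' @export
domain_network <- function(C, map) {
  stopifnot(inherits(C, "dccm_matrix"), inherits(map, "domain_map"))
  resno <- attr(C, "resno")
  idx <- lapply(map, function(rs) {
    i <- which(resno %in% rs)
    if (length(i) == 0L)
      stop("mapping error: domain residues not present in the correlation matrix",
           call. = FALSE)
    missing <- setdiff(rs, resno)
    if (length(missing))
      stop(sprintf("mapping error: residues %s not present in the correlation matrix",
                   paste(missing, collapse = ", ")), call. = FALSE)
    i
  })
  nd <- length(idx)
  W <- matrix(NA_real_, nd, nd, dimnames = list(names(map), names(map)))
  Cm <- unclass(C)
  for (a in seq_len(nd)) {
    for (b in seq_len(nd)) {
      if (a == b) {
        ia <- idx[[a]]
        W[a, a] <- if (length(ia) < 2) 1
                   else mean(Cm[ia, ia][upper.tri(matrix(0, length(ia), length(ia)))])
      } else {
        W[a, b] <- mean(Cm[idx[[a]], idx[[b]]])
      }
    }
  }
  structure(list(nodes = names(map), weights = W, map = map),
            class = "domain_network")
}

#' @export
print.domain_network <- function(x, ...) {
  cat(sprintf("Domain network: %d nodes\n", length(x$nodes)))
  print(round(x$weights, 3))
  invisible(x)
}

#' Threshold a domain network into an edge table
#'
#' Edges with |weight| below `threshold` are suppressed. The companion plot
#' method draws nodes on a circle (deterministic layout) with edge width
#' proportional to |weight|, blue for positive and red for negative coupling.
#'
#' @param network a [domain_network()].
#' @param threshold display threshold in [0, 1] (default 0.25).
#' @return data.frame with columns `domain_a`, `domain_b`, `weight`, classed
#'   `network_report`.
#' @export
network_report <- function(network, threshold = 0.25) {
  stopifnot(inherits(network, "domain_network"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    stop("invalid threshold: must be a single value in [0, 1]", call. = FALSE)
  W <- network$weights
  nd <- nrow(W)
  rows <- list()
  for (a in seq_len(nd - 1)) for (b in (a + 1):nd) {
    if (abs(W[a, b]) >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        domain_a = network$nodes[a], domain_b = network$nodes[b],
        weight = W[a, b], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(domain_a = character(), domain_b = character(),
                         weight = numeric(), stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "nodes") <- network$nodes
  class(out) <- c("network_report", "data.frame")
  out
}

#' @export
plot.network_report <- function(x, ...) {
  nodes <- attr(x, "nodes")
  n <- length(nodes)
  ang <- 2 * pi * (seq_len(n) - 1) / n + pi / 2
  px <- cos(ang); py <- sin(ang)
  graphics::plot(px, py, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4),
                 axes = FALSE, xlab = "", ylab = "", pch = 19, cex = 2, ...)
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      a <- match(x$domain_a[i], nodes); b <- match(x$domain_b[i], nodes)
      graphics::segments(px[a], py[a], px[b], py[b],
                         lwd = 1 + 6 * abs(x$weight[i]),
                         col = if (x$weight[i] >= 0) "#2166ac" else "#b2182b")
    }
  }
  graphics::text(1.18 * px, 1.18 * py, nodes)
}
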