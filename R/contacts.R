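# Frame-by-frame protein-ligand interaction detection and occupancy
# fractions. Geometric criteria are standard-practice defaults; every cutoff
# is a named, overridable parameter because published interaction diagnostics
# rarely state theirs.

#' Geometric contact criteria
#'
#' Defaults: hydrogen bond iff donor-heavy-atom to acceptor distance <=
#' 3.5 Angstrom and, when an explicit hydrogen is attached to the donor
#' (within 1.2 Angstrom), donor-H...acceptor angle >= 120 degrees (with no
#' hydrogens present the distance rule alone applies); hydrophobic iff any
#' apolar carbon pair <= 4.5 Angstrom; ionic iff centroids of
#' opposite formal-charge groups <= 4.0 Angstrom; a water bridge requires one
#' water satisfying the hydrogen-bond rule to both the protein residue and
#' the ligand in the same frame.
#'
#' @param hbond_dist donor-acceptor heavy-atom cutoff, Angstrom.
#' @param hbond_angle minimum donor-H...acceptor angle, degrees.
#' @param hydrophobic_dist apolar carbon pair cutoff, Angstrom.
#' @param ionic_dist charged-group centroid cutoff, Angstrom.
#' @return list of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_dist = 3.5, hbond_angle = 120,
                             hydrophobic_dist = 4.5, ionic_dist = 4.0) {
  vals <- c(hbond_dist, hydrophobic_dist, ionic_dist)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("parameter error: distance cutoffs must be positive", call. = FALSE)
  structure(list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 hydrophobic_dist = hydrophobic_dist,
                 ionic_dist = ionic_dist),
            class = "contact_criteria")
}

.pair_dist <- function(a, b) {
  # rows of a x rows of b Euclidean distances
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0))
}

.hbond_pairs <- function(xyz, don_idx, acc_idx, h_idx, crit) {
  # returns logical matrix |don| x |acc|
  if (!length(don_idx) || !length(acc_idx))
    return(matrix(FALSE, length(don_idx), length(acc_idx)))
  D <- .pair_dist(xyz[don_idx, , drop = FALSE], xyz[acc_idx, , drop = FALSE])
  ok <- D <= crit$hbond_dist & D > 1e-6
  if (length(h_idx) && any(ok)) {
    for (i in seq_along(don_idx)) {
      if (!any(ok[i, ])) next
      dh <- .pair_dist(xyz[don_idx[i], , drop = FALSE],
                       xyz[h_idx, , drop = FALSE])
      hs <- h_idx[dh[1, ] <= 1.2]
      if (!length(hs)) next  # no attached hydrogen: heavy-atom rule stands
      for (j in which(ok[i, ])) {
        angles <- vapply(hs, function(h) {
          v1 <- xyz[don_idx[i], ] - xyz[h, ]
          v2 <- xyz[acc_idx[j], ] - xyz[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        }, numeric(1))
        if (max(angles) < crit$hbond_angle) ok[i, j] <- FALSE
      }
    }
  }
  ok
}

#' Detect protein-ligand contacts in one frame
#'
#' @param xyz N x 3 coordinate matrix for one frame.
#' @param topology the matching [topology()] (must contain ligand atoms).
#' @param criteria a [contact_criteria()].
#' @return data.frame with `resno`, `resname`, `type` for every protein
#'   residue in contact with the ligand this frame (types: hbond,
#'   hydrophobic, ionic, water_bridge).
#' @export
detect_contacts <- function(xyz, topology, criteria = contact_criteria()) {
  stopifnot(inherits(topology, "topology"), inherits(criteria, "contact_criteria"),
            nrow(xyz) == nrow(topology))
  lig <- which(topology$ligand)
  if (!length(lig)) stop("topology contains no ligand atoms", call. = FALSE)
  prot <- which(!topology$ligand & !topology$water)
  wat <- which(topology$water)
  h_all <- which(toupper(topology$element) == "H")
  res_of <- topology$resno
  hits <- list()
  add <- function(resnos, type) {
    for (rn in unique(resnos))
      hits[[length(hits) + 1L]] <<- data.frame(
        resno = rn,
        resname = topology$resname[match(rn, topology$resno)],
        type = type, stringsAsFactors = FALSE)
  }

  # hydrogen bonds (either partner can donate)
  pd <- intersect(prot, which(topology$donor))
  pa <- intersect(prot, which(topology$acceptor))
  ld <- intersect(lig, which(topology$donor))
  la <- intersect(lig, which(topology$acceptor))
  m1 <- .hbond_pairs(xyz, pd, la, h_all, criteria)
  if (any(m1)) add(res_of[pd[rowSums(m1) > 0]], "hbond")
  m2 <- .hbond_pairs(xyz, ld, pa, h_all, criteria)
  if (any(m2)) add(res_of[pa[colSums(m2) > 0]], "hbond")

  # hydrophobic contacts between apolar carbons
  pc <- intersect(prot, which(topology$apolar))
  lc <- intersect(lig, which(topology$apolar))
  if (length(pc) && length(lc)) {
    D <- .pair_dist(xyz[pc, , drop = FALSE], xyz[lc, , drop = FALSE])
    close <- rowSums(D <= criteria$hydrophobic_dist) > 0
    if (any(close)) add(res_of[pc[close]], "hydrophobic")
  }

  # ionic: opposite formal-charge group centroids
  .centroids <- function(idx) {
    if (!length(idx)) return(NULL)
    grp <- split(idx, res_of[idx])
    t(vapply(grp, function(ii) colMeans(xyz[ii, , drop = FALSE]), numeric(3)))
  }
  for (signs in list(c("pos_charged", "neg_charged"),
                     c("neg_charged", "pos_charged"))) {
    pi_ <- intersect(prot, which(topology[[signs[1]]]))
    li_ <- intersect(lig, which(topology[[signs[2]]]))
    cp <- .centroids(pi_); clg <- .centroids(li_)
    if (!is.null(cp) && !is.null(clg)) {
      D <- .pair_dist(cp, clg)
      close <- rowSums(D <= criteria$ionic_dist) > 0
      if (any(close)) add(as.integer(rownames(cp)[close]), "ionic")
    }
  }

  # water bridges: one water hbonded to both the residue and the ligand
  if (length(wat)) {
    wo <- intersect(wat, which(toupper(topology$element) == "O"))
    lig_po <- intersect(lig, which(topology$donor | topology$acceptor))
    prot_po <- intersect(prot, which(topology$donor | topology$acceptor))
    if (length(wo) && length(lig_po) && length(prot_po)) {
      dw_l <- .pair_dist(xyz[wo, , drop = FALSE], xyz[lig_po, , drop = FALSE])
      dw_p <- .pair_dist(xyz[wo, , drop = FALSE], xyz[prot_po, , drop = FALSE])
      to_lig <- rowSums(dw_l <= criteria$hbond_dist) > 0
      for (wi in which(to_lig)) {
        pr <- prot_po[dw_p[wi, ] <= criteria$hbond_dist]
        if (length(pr)) add(res_of[pr], "water_bridge")
      }
    }
  }

  out <- if (length(hits)) unique(do.call(rbind, hits))
         else data.frame(resno = integer(), resname = character(),
                         type = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Contact occupancy timeline over an ensemble
#'
#' Runs [detect_contacts()] on every frame; presence is capped at one per
#' (residue, type) per frame.
#'
#' @param x an [ensemble()].
#' @param topology the matching [topology()].
#' @param criteria a [contact_criteria()].
#' @return Object of class `contact_timeline`: logical occupancy matrix
#'   `occ` (frames x contact pairs), `pairs` (data.frame resno/resname/type),
#'   `n_frames`.
#' @export
contact_timeline <- function(x, topology, criteria = contact_criteria()) {
  stopifnot(inherits(x, "ensemble"), n_atoms(x) == nrow(topology))
  f <- n_frames(x)
  per_frame <- lapply(seq_len(f), function(k)
    detect_contacts(frame_coords(x, k), topology, criteria))
  all_pairs <- unique(do.call(rbind, c(per_frame, list(
    data.frame(resno = integer(), resname = character(), type = character(),
               stringsAsFactors = FALSE)))))
  all_pairs <- all_pairs[order(all_pairs$resno, all_pairs$type), , drop = FALSE]
  rownames(all_pairs) <- NULL
  key <- function(d) paste(d$resno, d$type)
  occ <- matrix(FALSE, f, nrow(all_pairs),
                dimnames = list(NULL, key(all_pairs)))
  for (k in seq_len(f)) {
    hk <- key(per_frame[[k]])
    if (length(hk)) occ[k, match(hk, key(all_pairs))] <- TRUE
  }
  structure(list(occ = occ, pairs = all_pairs, n_frames = f,
                 criteria = criteria),
            class = "contact_timeline")
}

#' @export
print.contact_timeline <- function(x, ...) {
  cat(sprintf("Contact timeline: %d frames x %d (residue, type) pairs\n",
              x$n_frames, nrow(x$pairs)))
  invisible(x)
}

#' Interaction fractions per residue and type
#'
#' The fraction of analyzed frames in which each (residue, interaction type)
#' contact is present -- the quantity shown in interaction-fraction bar
#' charts. Fractions are frame-order invariant and lie in [0, 1].
#'
#' @param timeline a [contact_timeline()].
#' @return data.frame with `resno`, `resname`, `type`, `fraction`, classed
#'   `interaction_fractions`.
#' @export
interaction_fractions <- function(timeline) {
  stopifnot(inherits(timeline, "contact_timeline"))
  out <- timeline$pairs
  out$fraction <- if (nrow(out)) unname(colMeans(timeline$occ)) else numeric(0)
  class(out) <- c("interaction_fractions", "data.frame")
  out
}

#' @export
plot.interaction_fractions <- function(x, ...) {
  if (!nrow(x)) { graphics::plot.new(); return(invisible(x)) }
  cols <- c(hbond = "#4daf4a", hydrophobic = "#984ea3", ionic = "#e41a1c",
            water_bridge = "#377eb8")
  lab <- sprintf("%s%d", x$resname, x$resno)
  graphics::barplot(x$fraction, names.arg = lab, las = 2,
                    col = cols[x$type], ylab = "interaction fraction",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", legend = names(cols), fill = cols, cex = 0.8)
}
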