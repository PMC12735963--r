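# Superposition and stability metrics.

#' Kabsch least-squares superposition
#'
#' Finds the proper rigid transform (rotation + translation) minimizing the
#' RMSD between `mobile` and `reference` over the atoms in `mask`, and applies
#' it to all atoms of `mobile`. Reflections are corrected so the rotation has
#' determinant +1.
#'
#' @param mobile N x 3 coordinate matrix to move.
#' @param reference N x 3 coordinate matrix (same atom count).
#' @param mask integer atom indices used for the fit (>= 3 non-collinear).
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `aligned = mobile %*% R + t`), `aligned` (N x 3) and `rmsd`
#'   over the mask after fitting.
#' @export
kabsch_superpose <- function(mobile, reference, mask = seq_len(nrow(mobile))) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  mask <- as.integer(mask)
  if (length(mask) < 3) stop("fit mask must contain at least 3 atoms", call. = FALSE)
  A <- mobile[mask, , drop = FALSE]
  B <- reference[mask, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv_a <- svd(A0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1e-12))
    stop("degenerate fit mask: atoms are collinear or coincident", call. = FALSE)
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)   # aligned = (mobile - ca) %*% R + cb
  tr <- as.numeric(cb - ca %*% R)
  aligned <- mobile %*% R + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((aligned[mask, , drop = FALSE] - B)^2)))
  list(rotation = R, translation = tr, aligned = aligned, rmsd = rmsd)
}

.rmsd_pair <- function(a, b, mask) {
  sqrt(mean(rowSums((a[mask, , drop = FALSE] - b[mask, , drop = FALSE])^2)))
}

#' Align every frame of an ensemble
#'
#' `reference = "first"` fits each frame on the first frame. `reference =
#' "mean"` uses the iterative mean procedure: fit all frames to a running mean
#' structure, recompute the mean, and repeat until the mean moves by less than
#' `tol` (RMSD over the fit mask) or `max_iter` iterations; this removes
#' global drift without privileging any single frame and is the alignment
#' used by RMSF, DCCM and PCA.
#'
#' @param x an [ensemble()].
#' @param fit_mask atom indices used for fitting.
#' @param reference `"first"`, `"mean"`, or an N x 3 matrix.
#' @param tol convergence threshold in Angstrom (default 1e-6).
#' @param max_iter maximum mean-refinement iterations (default 10).
#' @return An `ensemble` with aligned coordinates (attribute
#'   `mean_structure` holds the final N x 3 mean when `reference = "mean"`).
#' @export
align_frames <- function(x, fit_mask = seq_len(n_atoms(x)),
                         reference = c("first", "mean"),
                         tol = 1e-6, max_iter = 10) {
  stopifnot(inherits(x, "ensemble"))
  external <- is.matrix(reference)
  if (!external) reference <- match.arg(reference)
  f <- n_frames(x)
  n <- n_atoms(x)
  coords <- x$coords
  ref <- if (external) reference else frame_coords(x, 1)
  # degeneracy checked once on the reference; the per-frame loop then uses a
  # lean Kabsch (3x3 SVD only) for speed on long trajectories
  kabsch_superpose(ref, ref, fit_mask)
  m_idx <- as.integer(fit_mask)
  nm <- length(m_idx)
  align_all <- function(coords, ref) {
    B <- ref[m_idx, , drop = FALSE]
    cb <- colMeans(B)
    B0 <- B - rep(cb, each = nm)
    for (k in seq_len(f)) {
      A <- coords[k, m_idx, ]
      dim(A) <- c(nm, 3)
      ca_ <- colMeans(A)
      H <- crossprod(A - rep(ca_, each = nm), B0)
      s <- svd(H)
      d <- sign(det(s$v %*% t(s$u)))
      R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
      fr <- coords[k, , ]
      dim(fr) <- c(n, 3)
      coords[k, , ] <- (fr - rep(ca_, each = n)) %*% R + rep(cb, each = n)
    }
    coords
  }
  coords <- align_all(coords, ref)
  mean_struct <- NULL
  if (!external && identical(reference, "mean") && f > 1) {
    for (it in seq_len(max_iter)) {
      m <- apply(coords, c(2, 3), mean)
      if (.rmsd_pair(m, ref, fit_mask) < tol) { ref <- m; break }
      ref <- m
      coords <- align_all(coords, ref)
    }
    mean_struct <- apply(coords, c(2, 3), mean)
  }
  out <- ensemble(coords, x$frame_interval, x$replicate_starts, x$system_label)
  attr(out, "mean_structure") <- mean_struct
  out
}

.metric_series <- function(values, name, fit_mask = NULL, measure_mask = NULL,
                           frame_interval = NA_real_) {
  stopifnot(all(is.finite(values)), all(values >= -1e-12))
  structure(list(values = pmax(values, 0), units = "Angstrom",
                 metric_name = name, fit_mask = fit_mask,
                 measure_mask = measure_mask,
                 frame_interval = frame_interval),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("%s series: %d frames, mean %.3f A (range %.3f-%.3f)\n",
              x$metric_name, length(x$values), mean(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.metric_series <- function(x, ...) {
  t_ps <- (seq_along(x$values) - 1) * (if (is.finite(x$frame_interval))
    x$frame_interval else 1)
  xlab <- if (is.finite(x$frame_interval)) "time (ps)" else "frame"
  graphics::plot(t_ps, x$values, type = "l", xlab = xlab,
                 ylab = sprintf("%s (A)", x$metric_name), ...)
}

#' RMSD time series
#'
#' For each frame, superposes the frame on the reference using `fit_mask`
#' (Kabsch) and reports the RMSD over `measure_mask`. With the default
#' reference (frame 1) the series starts at 0.
#'
#' @param x an [ensemble()].
#' @param fit_mask atoms used to fit (typically Calpha).
#' @param measure_mask atoms over which RMSD is computed; default = fit mask.
#' @param reference `1` for the first frame or an external N x 3 matrix (for
#'   deviation from a crystallographic model).
#' @return A `metric_series`.
#' @export
rmsd_series <- function(x, fit_mask, measure_mask = fit_mask, reference = 1L) {
  stopifnot(inherits(x, "ensemble"))
  if (length(fit_mask) == 0L || length(measure_mask) == 0L)
    stop("empty selection mask", call. = FALSE)
  ref <- if (is.matrix(reference)) reference else frame_coords(x, reference)
  vals <- vapply(seq_len(n_frames(x)), function(k) {
    fit <- kabsch_superpose(frame_coords(x, k), ref, fit_mask)
    .rmsd_pair(fit$aligned, ref, measure_mask)
  }, numeric(1))
  .metric_series(vals, "RMSD", fit_mask, measure_mask, x$frame_interval)
}

#' Radius of gyration time series
#'
#' Rg_t = sqrt( sum_i w_i |r_i - r_com|^2 / sum_i w_i ), with w = atomic mass
#' when `mass_weighted` (the standard convention) or 1 otherwise.
#'
#' @param x an [ensemble()].
#' @param mask atom indices to include.
#' @param masses per-atom masses for the full topology (amu); required when
#'   `mass_weighted = TRUE` unless `topology` is given.
#' @param topology optional [topology()] supplying masses.
#' @param mass_weighted logical, default TRUE.
#' @return A `metric_series`.
#' @export
radius_of_gyration <- function(x, mask, topology = NULL, masses = NULL,
                               mass_weighted = TRUE) {
  stopifnot(inherits(x, "ensemble"))
  if (length(mask) == 0L) stop("empty selection mask", call. = FALSE)
  w <- if (!mass_weighted) rep(1, length(mask))
       else if (!is.null(masses)) masses[mask]
       else if (!is.null(topology)) topology$mass[mask]
       else stop("mass-weighted Rg needs masses or a topology", call. = FALSE)
  w <- w / sum(w)
  vals <- vapply(seq_len(n_frames(x)), function(k) {
    fr <- frame_coords(x, k)[mask, , drop = FALSE]
    com <- colSums(fr * w)
    sqrt(sum(w * rowSums(sweep(fr, 2, com)^2)))
  }, numeric(1))
  .metric_series(vals, "Rg", measure_mask = mask,
                 frame_interval = x$frame_interval)
}

#' Per-residue or per-atom RMSF profile
#'
#' Frames are aligned with the iterative-mean procedure (see
#' [align_frames()]), then RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2). With
#' `grouping = "by_residue"` the profile reports the Calpha atom of each
#' residue in the mask; `"by_atom"` reports every mask atom (used for
#' per-atom ligand flexibility).
#'
#' @param x an [ensemble()] with at least 2 frames.
#' @param topology the matching [topology()].
#' @param mask atoms to profile (and to fit on).
#' @param grouping `"by_residue"` or `"by_atom"`.
#' @return A `profile_series` (fields `values`, `labels`, `units`).
#' @export
rmsf_profile <- function(x, topology, mask = which(topology$calpha),
                         grouping = c("by_residue", "by_atom")) {
  stopifnot(inherits(x, "ensemble"), inherits(topology, "topology"))
  grouping <- match.arg(grouping)
  if (n_frames(x) < 2)
    stop("insufficient data: RMSF needs at least 2 frames", call. = FALSE)
  if (length(mask) == 0L) stop("empty selection mask", call. = FALSE)
  aligned <- align_frames(x, fit_mask = mask, reference = "mean")
  sub <- aligned$coords[, mask, , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), mu)^2
  msf <- apply(dev2, 2, sum) / n_frames(x)   # sums over frames and x,y,z
  rmsf <- sqrt(msf)
  if (grouping == "by_residue") {
    is_ca <- topology$calpha[mask]
    keep <- which(is_ca)
    if (length(keep) == 0L)
      stop("by_residue grouping needs Calpha atoms in the mask", call. = FALSE)
    vals <- rmsf[keep]
    labels <- sprintf("%s%d", topology$resname[mask][keep],
                      topology$resno[mask][keep])
  } else {
    vals <- rmsf
    labels <- sprintf("%s:%d", topology$name[mask], topology$index[mask])
  }
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "_")
  structure(list(values = vals, labels = labels, units = "Angstrom",
                 metric_name = sprintf("RMSF (%s)", grouping)),
            class = "profile_series")
}

#' @export
print.profile_series <- function(x, ...) {
  cat(sprintf("%s profile: %d entries, mean %.3f A, max %.3f A (%s)\n",
              x$metric_name, length(x$values), mean(x$values),
              max(x$values), x$labels[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.profile_series <- function(x, ...) {
  graphics::plot(seq_along(x$values), x$values, type = "h",
                 xlab = "entity", ylab = sprintf("%s (A)", x$metric_name), ...)
}
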