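# Seeded synthetic trajectory ensembles with known ground truth.
#
# The generator is a statistical emulator (no force field): frames hop
# between K metastable basins with geometric dwell times, transitions are
# linearly interpolated low-density frames, residue blocks can carry planted
# rank-1 correlations, and an optional pseudo-ligand maintains contacts with
# designated pocket residues in a Bernoulli subset of frames.

#' Specification for a synthetic ensemble
#'
#' @param n_residues number of residues (one Calpha pseudo-atom each).
#' @param n_basins K, number of metastable basins.
#' @param basin_separation Delta: per-residue displacement magnitude between
#'   basin centers, Angstrom.
#' @param intra_basin_sigma sigma: isotropic Gaussian noise per coordinate
#'   within a basin, Angstrom.
#' @param basin_occupancies stationary occupancy of each basin (sums to 1);
#'   default equal.
#' @param mean_dwell mean dwell time in frames before a basin switch.
#' @param transition_length m: interpolated transition frames inserted per
#'   switch; default derived from `target_noise_fraction`.
#' @param target_noise_fraction intended fraction of frames spent in
#'   transitions (ground truth records the realized fraction).
#' @param correlation_blocks list of planted blocks, each
#'   `list(block_a =, block_b =, rho =, sign = +1/-1)` with residue index
#'   vectors; realized as a shared scalar latent factor times a fixed unit
#'   direction added to every residue of the block.
#' @param ligand optional list of contacts, each
#'   `list(type = "hbond"|"hydrophobic", resno =, bound_fraction =)`; every
#'   contact adds one pseudo-ligand atom.
#' @param mobile_residues residues displaced between basins; default all.
#' @param n_replicates number of independent replicates.
#' @param n_frames frames per replicate.
#' @param frame_interval saving interval in ps (default 100).
#' @param seed integer; replicate r uses `seed + r`.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 40, n_basins = 3,
                           basin_separation = 4, intra_basin_sigma = 0.5,
                           basin_occupancies = NULL, mean_dwell = 18,
                           transition_length = NULL,
                           target_noise_fraction = 0.1,
                           correlation_blocks = list(), ligand = NULL,
                           mobile_residues = NULL,
                           n_replicates = 3, n_frames = 400,
                           frame_interval = 100, seed = 1) {
  K <- as.integer(n_basins)
  if (is.null(basin_occupancies)) basin_occupancies <- rep(1 / K, K)
  if (K < 1L) stop("parameter error: n_basins must be >= 1", call. = FALSE)
  if (length(basin_occupancies) != K ||
      abs(sum(basin_occupancies) - 1) > 1e-9 || any(basin_occupancies <= 0))
    stop("parameter error: basin_occupancies must be positive and sum to 1 (+/- 1e-9)",
         call. = FALSE)
  if (intra_basin_sigma < 0) stop("parameter error: sigma must be >= 0", call. = FALSE)
  if (basin_separation < 0) stop("parameter error: basin_separation must be >= 0", call. = FALSE)
  if (target_noise_fraction < 0 || target_noise_fraction >= 1)
    stop("parameter error: target_noise_fraction must be in [0, 1)", call. = FALSE)
  for (b in correlation_blocks) {
    if (abs(b$rho) > 1)
      stop("parameter error: |rho| of a correlation block must be <= 1", call. = FALSE)
    if (any(c(b$block_a, b$block_b) > n_residues))
      stop("parameter error: correlation block residues outside chain", call. = FALSE)
  }
  if (is.null(mobile_residues)) mobile_residues <- seq_len(n_residues)
  if (is.null(transition_length)) {
    transition_length <- if (target_noise_fraction > 0 && K > 1)
      max(1L, as.integer(round(target_noise_fraction * mean_dwell /
                                 (1 - target_noise_fraction))))
    else 0L
  }
  structure(list(n_residues = as.integer(n_residues), n_basins = K,
                 basin_separation = basin_separation,
                 intra_basin_sigma = intra_basin_sigma,
                 basin_occupancies = basin_occupancies,
                 mean_dwell = mean_dwell,
                 transition_length = as.integer(transition_length),
                 target_noise_fraction = target_noise_fraction,
                 correlation_blocks = correlation_blocks, ligand = ligand,
                 mobile_residues = as.integer(mobile_residues),
                 n_replicates = as.integer(n_replicates),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic spec: %d residues, K=%d basins (Delta=%g A, sigma=%g A), %d x %d frames, seed %d\n",
    x$n_residues, x$n_basins, x$basin_separation, x$intra_basin_sigma,
    x$n_replicates, x$n_frames, x$seed))
  invisible(x)
}

#' Self-avoiding reference Calpha chain
#'
#' Random 3D walk with a fixed 3.8 Angstrom consecutive-Calpha distance and a
#' minimum 3.4 Angstrom clearance between non-consecutive beads.
#' Deterministic under `seed`.
#'
#' @param n_residues chain length (>= 2).
#' @param seed integer seed.
#' @return n x 3 coordinate matrix.
#' @export
make_reference_chain <- function(n_residues, seed = 1) {
  n_residues <- as.integer(n_residues)
  if (n_residues < 2L)
    stop("parameter error: n_residues must be >= 2", call. = FALSE)
  set.seed(seed)
  bond <- 3.8; clearance <- 3.4
  xyz <- matrix(0, n_residues, 3)
  for (i in 2:n_residues) {
    for (try in 1:200) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- xyz[i - 1, ] + bond * u
      prev <- xyz[seq_len(max(i - 2, 1)), , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, cand)^2)
      if (i == 2 || min(d2) >= clearance^2) break
      if (try == 200) stop("failed to grow a self-avoiding chain", call. = FALSE)
    }
    xyz[i, ] <- cand
  }
  xyz
}

# Basin center k = reference + Delta * d_ik on mobile residues, where the
# per-residue directions d_ik live (mostly) in a fixed 2-plane: basin k sits
# at ring angle theta_k, so the K centers are well spread in the top-2 PC
# plane that the census pipeline clusters on.
.make_basin_directions <- function(n_res, K, seed) {
  set.seed(seed + 104729L)
  U <- matrix(stats::rnorm(n_res * 3), n_res, 3)
  V <- matrix(stats::rnorm(n_res * 3), n_res, 3)
  W <- matrix(stats::rnorm(n_res * 3), n_res, 3)
  U <- U / sqrt(rowSums(U^2))
  V <- V - U * rowSums(V * U); V <- V / sqrt(rowSums(V^2))
  W <- W - U * rowSums(W * U) - V * rowSums(W * V)
  W <- W / sqrt(rowSums(W^2))
  theta <- 2 * pi * (seq_len(K) - 1) / K + stats::runif(K, -0.05, 0.05)
  eta <- 0.15  # small out-of-plane component
  dirs <- lapply(seq_len(K), function(k) {
    D <- cos(theta[k]) * U + sin(theta[k]) * V +
      eta * stats::rnorm(1) * W
    D / sqrt(rowSums(D^2))
  })
  list(dirs = dirs, U = U, V = V)
}

#' Basin center conformations for a synthetic spec
#'
#' Basin k is the reference chain plus a per-residue displacement of
#' magnitude `basin_separation` in a basin-specific direction applied to the
#' mobile residues. With K = 1 the single basin equals the reference chain.
#' A warning is raised if `basin_separation` is 0 (degenerate basins) or if
#' any pairwise Calpha RMSD falls below `basin_separation / 2`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `reference` (n x 3) and `centers` (list of K n x 3
#'   matrices).
#' @export
make_basins <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ref <- make_reference_chain(spec$n_residues, spec$seed)
  K <- spec$n_basins
  if (K == 1L)
    return(list(reference = ref, centers = list(ref), plane = NULL))
  if (spec$basin_separation == 0)
    warning("degenerate basins: basin_separation is 0", call. = FALSE)
  bd <- .make_basin_directions(spec$n_residues, K, spec$seed)
  dirs <- bd$dirs
  centers <- lapply(seq_len(K), function(k) {
    ck <- ref
    m <- spec$mobile_residues
    ck[m, ] <- ck[m, ] + spec$basin_separation * dirs[[k]][m, , drop = FALSE]
    ck
  })
  if (K >= 2 && spec$basin_separation > 0) {
    rmin <- Inf
    for (a in 1:(K - 1)) for (b in (a + 1):K)
      rmin <- min(rmin, sqrt(mean(rowSums((centers[[a]] - centers[[b]])^2))))
    if (rmin < spec$basin_separation / 2)
      warning(sprintf("minimum pairwise basin RMSD %.2f A is below Delta/2", rmin),
              call. = FALSE)
    attr(centers, "min_pairwise_rmsd") <- rmin
  }
  list(reference = ref, centers = centers,
       plane = list(U = bd$U, V = bd$V))
}

.synthetic_topology <- function(spec) {
  n <- spec$n_residues
  hb_res <- integer(0)
  if (!is.null(spec$ligand))
    hb_res <- sort(unique(vapply(
      Filter(function(cc) cc$type == "hbond", spec$ligand),
      function(cc) as.integer(cc$resno), integer(1))))
  rows <- list()
  for (i in seq_len(n)) {
    has_og <- i %in% hb_res
    rows[[length(rows) + 1L]] <- data.frame(
      name = "CA", element = "C", resno = i,
      resname = if (has_og) "SER" else "GLY", hetatm = FALSE,
      stringsAsFactors = FALSE)
    if (has_og)
      rows[[length(rows) + 1L]] <- data.frame(
        name = "OG", element = "O", resno = i, resname = "SER",
        hetatm = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.null(spec$ligand)) {
    for (j in seq_along(spec$ligand)) {
      cc <- spec$ligand[[j]]
      el <- if (cc$type == "hbond") "O" else "C"
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s%d", el, j), element = el, resno = n + 1L,
        resname = "LIG", hetatm = TRUE, stringsAsFactors = FALSE)
    }
  }
  topology(do.call(rbind, rows))
}

#' Simulate a synthetic replicate ensemble with ground truth
#'
#' Basin visits form a jump chain with uniform targets and state-dependent
#' geometric dwell means `K * occupancy_k * mean_dwell`, which realizes the
#' requested stationary occupancies exactly in expectation. Each basin switch
#' inserts `transition_length` linearly interpolated frames (plus the same
#' Gaussian noise) labelled -1 in the ground truth. Planted correlation
#' blocks add a shared standard-normal latent factor times a fixed unit
#' direction, with amplitude chosen so the expected inter-block correlation
#' equals the requested rho. Replicate r is seeded with `seed + r`, so a
#' given spec is bit-reproducible.
#'
#' @param spec a [synthetic_spec()].
#' @return Object of class `conflock_sim`: list with `topology`, `replicates`
#'   (list of [ensemble()]), `ensemble` (replicates concatenated),
#'   `ground_truth` (per-frame basin labels with -1 transitions, realized
#'   noise fraction, expected block correlations, planted contact fractions)
#'   and the `spec`.
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bas <- make_basins(spec)
  K <- spec$n_basins
  top <- .synthetic_topology(spec)
  ca_idx <- which(top$calpha)
  og_idx <- which(top$name == "OG")
  lig_idx <- which(top$ligand)
  n_at <- nrow(top)

  set.seed(spec$seed + 202481L)
  og_dirs <- matrix(stats::rnorm(3 * length(og_idx)), ncol = 3)
  if (length(og_idx))
    og_dirs <- 1.5 * og_dirs / sqrt(rowSums(og_dirs^2))
  lig_dirs <- matrix(stats::rnorm(3 * length(lig_idx)), ncol = 3)
  if (length(lig_idx))
    lig_dirs <- lig_dirs / sqrt(rowSums(lig_dirs^2))
  block_dirs <- lapply(spec$correlation_blocks, function(b) {
    u <- stats::rnorm(3); u / sqrt(sum(u^2))
  })

  sigma <- spec$intra_basin_sigma
  m_tr <- spec$transition_length
  dwell_means <- pmax(1, K * spec$basin_occupancies * spec$mean_dwell)

  replicates <- vector("list", spec$n_replicates)
  labels_all <- integer(0)
  for (r in seq_len(spec$n_replicates)) {
    set.seed(spec$seed + r)
    nf <- spec$n_frames
    # basin label sequence with -1 transitions
    if (K == 1L) {
      lab <- rep.int(1L, nf)
      seq_centers <- rep(list(bas$centers[[1]]), nf)
    } else {
      lab <- integer(0)
      seq_centers <- list()
    }
    state <- sample.int(K, 1, prob = spec$basin_occupancies)
    while (length(lab) < nf) {
      dwell <- 1L + stats::rgeom(1, prob = 1 / dwell_means[state])
      lab <- c(lab, rep.int(state, dwell))
      seq_centers <- c(seq_centers, rep(list(bas$centers[[state]]), dwell))
      if (length(lab) >= nf) break
      nxt <- if (K == 2L) 3L - state
             else sample(setdiff(seq_len(K), state), 1)
      if (m_tr > 0) {
        # transition paths: interpolation fractions drawn uniformly along the
        # corridor (fixed grid positions would pile frames from repeated
        # switches onto a few dense spots and fake extra states), and each
        # switch bows along its own random in-plane arc so repeated passages
        # trace distinct low-density paths rather than one shared line
        ws <- sort(stats::runif(m_tr))
        bow_amp <- stats::rnorm(1, sd = spec$basin_separation / 3)
        bow_phi <- stats::runif(1, 0, 2 * pi)
        bow_dir <- if (is.null(bas$plane)) 0 else
          cos(bow_phi) * bas$plane$U + sin(bow_phi) * bas$plane$V
        for (t in seq_len(m_tr)) {
          w <- ws[t]
          lab <- c(lab, -1L)
          pt <- (1 - w) * bas$centers[[state]] + w * bas$centers[[nxt]]
          if (!is.null(bas$plane)) {
            mm <- spec$mobile_residues
            pt[mm, ] <- pt[mm, ] + (bow_amp * 4 * w * (1 - w)) *
              bow_dir[mm, , drop = FALSE]
          }
          seq_centers <- c(seq_centers, list(pt))
        }
      }
      state <- nxt
    }
    lab <- lab[seq_len(nf)]
    seq_centers <- seq_centers[seq_len(nf)]

    coords <- array(0, dim = c(nf, n_at, 3))
    noise <- array(stats::rnorm(nf * spec$n_residues * 3, sd = sigma),
                   dim = c(nf, spec$n_residues, 3))
    latents <- matrix(stats::rnorm(nf * max(1, length(spec$correlation_blocks))),
                      nrow = nf)
    for (k in seq_len(nf)) {
      ca <- seq_centers[[k]] + noise[k, , ] * (sigma > 0)
      dim(ca) <- c(spec$n_residues, 3)
      for (bi in seq_along(spec$correlation_blocks)) {
        b <- spec$correlation_blocks[[bi]]
        a_amp <- if (abs(b$rho) >= 1) 1e3 * max(sigma, 1e-3)
                 else sqrt(3 * sigma^2 * abs(b$rho) / (1 - abs(b$rho)))
        sgn <- if (is.null(b$sign)) sign(b$rho) else b$sign
        u <- block_dirs[[bi]]
        ca[b$block_a, ] <- ca[b$block_a, ] +
          a_amp * latents[k, bi] * matrix(u, length(b$block_a), 3, byrow = TRUE)
        ca[b$block_b, ] <- ca[b$block_b, ] +
          sgn * a_amp * latents[k, bi] *
            matrix(u, length(b$block_b), 3, byrow = TRUE)
      }
      coords[k, ca_idx, ] <- ca
      if (length(og_idx))
        coords[k, og_idx, ] <- ca[top$resno[og_idx], , drop = FALSE] + og_dirs
    }
    # pseudo-ligand contacts
    if (length(lig_idx)) {
      for (j in seq_along(spec$ligand)) {
        cc <- spec$ligand[[j]]
        bound <- stats::runif(nf) < cc$bound_fraction
        anchor_idx <- if (cc$type == "hbond")
          og_idx[match(cc$resno, top$resno[og_idx])]
        else ca_idx[cc$resno]
        if (is.na(anchor_idx))
          stop("selection error: pocket residue ", cc$resno,
               " not in topology", call. = FALSE)
        d0 <- if (cc$type == "hbond") 2.9 else 4.0
        dist <- ifelse(bound, d0, 10.0)
        for (k in seq_len(nf))
          coords[k, lig_idx[j], ] <- coords[k, anchor_idx, ] +
            dist[k] * lig_dirs[j, ]
        attr(coords, sprintf("bound_%d", j)) <- bound
      }
    }
    e <- ensemble(coords, spec$frame_interval,
                  system_label = sprintf("synthetic_rep%d", r))
    attr(e, "bound_masks") <- lapply(seq_along(spec$ligand), function(j)
      attr(coords, sprintf("bound_%d", j)))
    replicates[[r]] <- e
    labels_all <- c(labels_all, lab)
  }

  contact_truth <- NULL
  if (!is.null(spec$ligand)) {
    contact_truth <- do.call(rbind, lapply(seq_along(spec$ligand), function(j) {
      cc <- spec$ligand[[j]]
      realized <- mean(unlist(lapply(replicates, function(e)
        attr(e, "bound_masks")[[j]])))
      data.frame(resno = cc$resno, type = cc$type,
                 bound_fraction = cc$bound_fraction,
                 realized_fraction = realized, stringsAsFactors = FALSE)
    }))
  }
  blocks <- spec$correlation_blocks
  expected_corr <- if (length(blocks))
    vapply(blocks, function(b) {
      sgn <- if (is.null(b$sign)) sign(b$rho) else b$sign
      sgn * abs(b$rho)
    }, numeric(1))
  else numeric(0)

  structure(list(
    spec = spec, topology = top, replicates = replicates,
    ensemble = concatenate_ensembles(replicates,
                                     system_label = "synthetic_concat"),
    basins = bas,
    ground_truth = list(
      labels = labels_all,
      noise_fraction = mean(labels_all == -1L),
      n_basins = K,
      occupancies = spec$basin_occupancies,
      expected_block_correlation = expected_corr,
      contact_fractions = contact_truth)),
    class = "conflock_sim")
}

#' @export
print.conflock_sim <- function(x, ...) {
  cat(sprintf("Synthetic ensemble: %d replicates x %d frames, K=%d basins, noise fraction %.3f\n",
              x$spec$n_replicates, x$spec$n_frames, x$spec$n_basins,
              x$ground_truth$noise_fraction))
  invisible(x)
}

#' Write a simulated system to disk
#'
#' Writes the topology as PDB, one trajectory per replicate (DCD by default)
#' and the ground truth as JSON.
#'
#' @param sim a `conflock_sim` from [simulate_ensemble()].
#' @param dir output directory (created if needed).
#' @param format trajectory format, `"dcd"` or `"pdb"`.
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir, format = c("dcd", "pdb")) {
  stopifnot(inherits(sim, "conflock_sim"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pdb_topology(sim$topology, frame_coords(sim$replicates[[1]], 1),
                     file.path(dir, "topology.pdb"))
  for (r in seq_along(sim$replicates))
    write_trajectory(sim$replicates[[r]], sim$topology,
                     file.path(dir, sprintf("rep%d.%s", r, format)), format)
  jsonlite::write_json(sim$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
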