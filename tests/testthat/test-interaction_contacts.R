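# constructed micro-complexes with exact geometry
micro_topology <- function(water = FALSE, hydrogens = FALSE) {
  rows <- list(
    data.frame(name = "CA", element = "C", resno = 1, resname = "SER",
               hetatm = FALSE),
    data.frame(name = "OG", element = "O", resno = 1, resname = "SER",
               hetatm = FALSE),
    data.frame(name = "CA", element = "C", resno = 2, resname = "LEU",
               hetatm = FALSE),
    data.frame(name = "CD1", element = "C", resno = 2, resname = "LEU",
               hetatm = FALSE),
    data.frame(name = "NZ", element = "N", resno = 3, resname = "LYS",
               hetatm = FALSE),
    data.frame(name = "CA", element = "C", resno = 3, resname = "LYS",
               hetatm = FALSE))
  if (hydrogens)
    rows <- c(rows, list(
      data.frame(name = "HG", element = "H", resno = 1, resname = "SER",
                 hetatm = FALSE),
      data.frame(name = "H1", element = "H", resno = 99, resname = "LIG",
                 hetatm = TRUE)))
  if (water)
    rows <- c(rows, list(data.frame(name = "OW", element = "O", resno = 90,
                                    resname = "HOH", hetatm = TRUE)))
  rows <- c(rows, list(
    data.frame(name = "N", element = "N", resno = 99, resname = "LIG",
               hetatm = TRUE),
    data.frame(name = "O1", element = "O", resno = 99, resname = "LIG",
               hetatm = TRUE),
    data.frame(name = "C1", element = "C", resno = 99, resname = "LIG",
               hetatm = TRUE),
    data.frame(name = "OXT", element = "O", resno = 99, resname = "LIG",
               hetatm = TRUE)))
  topology(do.call(rbind, rows))
}

far <- function(n) matrix(rep(c(50, 50, 50), n), n, 3, byrow = TRUE) +
  10 * seq_len(n)

test_that("hydrogen bonds obey the distance rule with the heavy-atom fallback", {
  top <- micro_topology()
  xyz <- far(nrow(top))
  og <- 2; lig_o <- match("O1", top$name)
  xyz[og, ] <- c(0, 0, 0)
  xyz[lig_o, ] <- c(2.9, 0, 0)
  hits <- detect_contacts(xyz, top)
  expect_true(any(hits$resno == 1 & hits$type == "hbond"))

  xyz[lig_o, ] <- c(5.0, 0, 0)
  hits2 <- detect_contacts(xyz, top)
  expect_false(any(hits2$resno == 1))
})

test_that("the donor-H angle test rejects bent hydrogen bonds when hydrogens exist", {
  top <- micro_topology(hydrogens = TRUE)
  og <- 2; hg <- match("HG", top$name)
  lig_o <- match("O1", top$name); lig_h <- match("H1", top$name)

  xyz <- far(nrow(top))
  xyz[og, ] <- c(0, 0, 0)
  xyz[hg, ] <- c(0.96, 0, 0)
  xyz[lig_o, ] <- c(2.9, 0.3, 0)     # near-linear: angle ~165 degrees
  xyz[lig_h, ] <- c(3.86, 0.3, 0)
  hits <- detect_contacts(xyz, top)
  expect_true(any(hits$resno == 1 & hits$type == "hbond"))

  # both partners carry a hydrogen pointing away from the other: the pair is
  # within distance but no donor geometry is satisfied in either direction
  xyz[hg, ] <- c(-0.96, 0, 0)
  xyz[lig_h, ] <- c(3.86, 0.3, 0)
  hits2 <- detect_contacts(xyz, top)
  expect_false(any(hits2$resno == 1 & hits2$type == "hbond"))
})

test_that("hydrophobic, ionic and water-bridge classes fire on their geometries", {
  top <- micro_topology(water = TRUE)
  xyz <- far(nrow(top))
  cd1 <- match("CD1", top$name); lig_c <- match("C1", top$name)
  xyz[cd1, ] <- c(0, 10, 0)
  xyz[lig_c, ] <- c(4.0, 10, 0)
  hits <- detect_contacts(xyz, top)
  expect_true(any(hits$resno == 2 & hits$type == "hydrophobic"))

  nz <- match("NZ", top$name); oxt <- match("OXT", top$name)
  xyz[nz, ] <- c(0, 20, 0)
  xyz[oxt, ] <- c(3.5, 20, 0)
  hits <- detect_contacts(xyz, top)
  expect_true(any(hits$resno == 3 & hits$type == "ionic"))

  ow <- match("OW", top$name); og <- 2; lig_o <- match("O1", top$name)
  xyz[og, ] <- c(0, 30, 0)
  xyz[ow, ] <- c(2.8, 30, 0)
  xyz[lig_o, ] <- c(5.6, 30, 0)   # water 2.8 A from both partners
  hits <- detect_contacts(xyz, top)
  expect_true(any(hits$resno == 1 & hits$type == "water_bridge"))

  expect_error(contact_criteria(hbond_dist = -1), "parameter error")
})

test_that("detection agrees exactly with an all-pairs brute-force oracle", {
  set.seed(55)
  top <- micro_topology(water = TRUE)
  crit <- contact_criteria()
  for (trial in 1:25) {
    xyz <- matrix(runif(nrow(top) * 3, 0, 12), nrow(top), 3)
    hits <- detect_contacts(xyz, top, crit)
    # brute force, definition-by-definition
    lig <- which(top$ligand); prot <- which(!top$ligand & !top$water)
    wat <- which(top$water)
    d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    expected <- list()
    for (i in prot) for (j in lig) {
      dij <- d(i, j)
      if (dij > 1e-6 && dij <= crit$hbond_dist &&
          ((top$donor[i] && top$acceptor[j]) ||
           (top$donor[j] && top$acceptor[i])))
        expected[[length(expected) + 1L]] <- c(top$resno[i], "hbond")
      if (dij <= crit$hydrophobic_dist && top$apolar[i] && top$apolar[j])
        expected[[length(expected) + 1L]] <- c(top$resno[i], "hydrophobic")
      if (dij <= crit$ionic_dist &&
          ((top$pos_charged[i] && top$neg_charged[j]) ||
           (top$neg_charged[i] && top$pos_charged[j])))
        expected[[length(expected) + 1L]] <- c(top$resno[i], "ionic")
    }
    for (w in wat) for (i in prot) for (j in lig) {
      if (d(w, i) <= crit$hbond_dist && d(w, j) <= crit$hbond_dist &&
          (top$donor[i] || top$acceptor[i]) &&
          (top$donor[j] || top$acceptor[j]))
        expected[[length(expected) + 1L]] <- c(top$resno[i], "water_bridge")
    }
    exp_df <- unique(do.call(rbind, lapply(expected, function(e)
      data.frame(resno = as.integer(e[1]), type = e[2],
                 stringsAsFactors = FALSE))))
    got <- unique(hits[, c("resno", "type")])
    key <- function(df) if (is.null(df) || nrow(df) == 0) character(0)
      else sort(paste(df$resno, df$type))
    expect_identical(key(got), key(exp_df))
  }
})

test_that("interaction fractions are frame-order invariant and monotone in cutoffs", {
  lig <- list(list(type = "hbond", resno = 3, bound_fraction = 0.6),
              list(type = "hydrophobic", resno = 6, bound_fraction = 0.4))
  sim <- simulate_ensemble(synthetic_spec(
    n_residues = 8, n_basins = 1, ligand = lig, n_replicates = 1,
    n_frames = 150, seed = 61))
  tl <- contact_timeline(sim$ensemble, sim$topology)
  fr <- interaction_fractions(tl)
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))

  perm <- sample(n_frames(sim$ensemble))
  shuffled <- ensemble(sim$ensemble$coords[perm, , , drop = FALSE])
  fr2 <- interaction_fractions(contact_timeline(shuffled, sim$topology))
  expect_equal(fr2$fraction[order(fr2$resno, fr2$type)],
               fr$fraction[order(fr$resno, fr$type)])

  # enlarging any cutoff never decreases any fraction
  wide <- contact_criteria(hbond_dist = 4.5, hydrophobic_dist = 6,
                           ionic_dist = 6)
  frw <- interaction_fractions(contact_timeline(sim$ensemble, sim$topology,
                                                wide))
  for (i in seq_len(nrow(fr))) {
    match_row <- frw[frw$resno == fr$resno[i] & frw$type == fr$type[i], ]
    if (nrow(match_row))
      expect_gte(match_row$fraction, fr$fraction[i])
  }
})
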