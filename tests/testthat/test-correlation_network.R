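test_that("common rigid motion gives uniform correlation +1 and split latents give -1", {
  set.seed(13)
  n <- 6
  base <- matrix(rnorm(n * 3, sd = 5), n, 3)
  # every atom shares one random displacement per frame
  frames <- lapply(1:40, function(k) {
    shift <- rnorm(3)
    base + matrix(shift, n, 3, byrow = TRUE)
  })
  C <- dccm(frames_to_ensemble(frames), align = FALSE)
  expect_true(all(abs(unclass(C) - 1) < 1e-9))

  # block 1 driven by f, block 2 by -f
  u <- c(1, 0, 0)
  frames2 <- lapply(1:60, function(k) {
    f <- rnorm(1)
    out <- base
    out[1:3, ] <- out[1:3, ] + f * matrix(u, 3, 3, byrow = TRUE)
    out[4:6, ] <- out[4:6, ] - f * matrix(u, 3, 3, byrow = TRUE)
    out
  })
  C2 <- unclass(dccm(frames_to_ensemble(frames2), align = FALSE))
  expect_true(all(abs(C2[1:3, 4:6] + 1) < 1e-9))
  expect_true(all(abs(C2[1:3, 1:3] - 1) < 1e-9))
})

test_that("planted rank-1 blocks are recovered near their closed-form correlation", {
  rho <- 0.6
  spec <- synthetic_spec(
    n_residues = 60, n_basins = 1, intra_basin_sigma = 0.5,
    correlation_blocks = list(list(block_a = 5:14, block_b = 30:39,
                                   rho = rho, sign = +1)),
    n_replicates = 3, n_frames = 700, seed = 17)
  sim <- simulate_ensemble(spec)
  ca <- which(sim$topology$calpha)
  # the generator emits no global rigid motion, so the closed form
  # rho = a^2 / (a^2 + 3 sigma^2) holds exactly on the raw frames
  C <- unclass(dccm(sim$ensemble, ca, topology = sim$topology, align = FALSE))
  inter <- mean(C[5:14, 30:39])
  expect_equal(inter, rho, tolerance = 0.05)
  expect_equal(inter, sim$ground_truth$expected_block_correlation[1],
               tolerance = 0.05)
  # residues outside the blocks stay uncorrelated
  bg <- mean(abs(C[45:55, 5:14]))
  expect_lt(bg, 0.15)
  # superposition absorbs part of the coherent block motion into the global
  # fit, attenuating but never flipping the planted signal
  C_fit <- unclass(dccm(sim$ensemble, ca, topology = sim$topology))
  inter_fit <- mean(C_fit[5:14, 30:39])
  expect_gt(inter_fit, 0.15)
  expect_lt(inter_fit, inter + 0.05)
})

test_that("DCCM matches the double-loop oracle and is rigid-motion invariant", {
  set.seed(29)
  n <- 8; f <- 50
  base <- matrix(rnorm(n * 3, sd = 5), n, 3)
  frames <- lapply(seq_len(f), function(k) base + matrix(rnorm(n * 3, sd = 0.5), n, 3))
  ens <- frames_to_ensemble(frames)

  C <- dccm(ens, align = FALSE)
  expect_equal(unclass(C), oracle_dccm(frames), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unclass(C), t(unclass(C)), tolerance = 1e-12)
  expect_equal(unname(diag(unclass(C))), rep(1, n), tolerance = 1e-9)
  expect_true(all(abs(unclass(C)) <= 1 + 1e-12))

  # adding a global rigid motion per frame leaves aligned DCCM unchanged
  moved <- lapply(seq_len(f), function(k)
    rigid_rotate(frames[[k]], angles = 0.02 * k * c(1, -1, 2),
                 shift = 0.1 * k * c(1, 2, -1)))
  C_moved <- dccm(frames_to_ensemble(moved), align = TRUE)
  C_ref <- dccm(ens, align = TRUE)
  expect_equal(unclass(C_moved), unclass(C_ref), tolerance = 1e-6)

  static <- frames_to_ensemble(rep(list(base), 5))
  expect_error(dccm(static, align = FALSE), "zero variance")
})

test_that("domain networks average hand-computable correlations", {
  # identity-plus-zeros, two 2-residue domains
  C0 <- diag(4)
  class(C0) <- c("dccm_matrix", "matrix", "array")
  attr(C0, "resno") <- 1:4
  dimnames(C0) <- list(1:4, 1:4)
  net0 <- domain_network(C0, domain_map(A = 1:2, B = 3:4))
  expect_equal(net0$weights["A", "B"], 0)
  expect_equal(net0$weights["A", "A"], 0)

  C1 <- matrix(1, 4, 4)
  class(C1) <- c("dccm_matrix", "matrix", "array")
  attr(C1, "resno") <- 1:4
  net1 <- domain_network(C1, domain_map(A = 1:2, B = 3:4))
  expect_true(all(net1$weights == 1))

  # 3-domain toy with hand-filled entries
  resno <- 1:5
  Ct <- diag(5)
  Ct[1, 2] <- Ct[2, 1] <- 0.8
  Ct[1, 3] <- Ct[3, 1] <- 0.4
  Ct[2, 3] <- Ct[3, 2] <- 0.2
  Ct[1, 4] <- Ct[4, 1] <- -0.6
  Ct[2, 4] <- Ct[4, 2] <- -0.2
  Ct[3, 4] <- Ct[4, 3] <- 0.1
  Ct[5, ] <- Ct[, 5] <- 0.05; Ct[5, 5] <- 1
  class(Ct) <- c("dccm_matrix", "matrix", "array")
  attr(Ct, "resno") <- resno
  net <- domain_network(Ct, domain_map(D1 = 1:2, D2 = 3:4, D3 = 5L))
  expect_equal(net$weights["D1", "D2"], mean(c(0.4, -0.6, 0.2, -0.2)))
  expect_equal(net$weights["D2", "D3"], mean(c(0.05, 0.05)))
  expect_equal(net$weights["D1", "D1"], 0.8)
  expect_equal(net$weights["D2", "D2"], 0.1)
  expect_equal(net$weights, t(net$weights))

  expect_error(domain_network(Ct, domain_map(D1 = 7L)), "mapping error")
})

test_that("domain averaging is equivariant under residue relabeling", {
  set.seed(37)
  n <- 10
  M <- matrix(rnorm(n * n), n, n); M <- tcrossprod(M)
  C <- stats::cov2cor(M)
  mk <- function(C, resno) {
    class(C) <- c("dccm_matrix", "matrix", "array")
    attr(C, "resno") <- resno
    dimnames(C) <- list(resno, resno)
    C
  }
  map <- domain_map(A = c(1L, 4L, 7L), B = c(2L, 9L))
  w1 <- domain_network(mk(C, 1:10), map)$weights
  perm <- sample(n)
  w2 <- domain_network(mk(C[perm, perm], (1:10)[perm]), map)$weights
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("network reports threshold edges and validate inputs", {
  W <- matrix(c(1, 0.5, -0.1, 0.5, 1, 0.3, -0.1, 0.3, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net <- structure(list(nodes = c("a", "b", "c"), weights = W,
                        map = domain_map(a = 1L, b = 2L, c = 3L)),
                   class = "domain_network")
  expect_equal(nrow(network_report(net, threshold = 0)), 3)  # complete graph
  expect_equal(nrow(network_report(net, threshold = 0.25)), 2)
  expect_error(network_report(net, threshold = 1.01), "invalid threshold")

  # dense planted blocks produce more supra-threshold edges than no blocks
  blocks <- list(list(block_a = 1:5, block_b = 11:15, rho = 0.7, sign = 1),
                 list(block_a = 6:10, block_b = 16:20, rho = 0.7, sign = -1))
  sim_lig <- simulate_ensemble(synthetic_spec(
    n_residues = 24, n_basins = 1, correlation_blocks = blocks,
    n_replicates = 2, n_frames = 400, seed = 41))
  sim_apo <- simulate_ensemble(synthetic_spec(
    n_residues = 24, n_basins = 1, n_replicates = 2, n_frames = 400,
    seed = 41))
  map <- domain_map(B1 = 1:5, B2 = 11:15, B3 = 6:10, B4 = 16:20)
  n_edges <- function(sim) {
    ca <- which(sim$topology$calpha)
    C <- dccm(sim$ensemble, ca, topology = sim$topology, align = FALSE)
    nrow(network_report(domain_network(C, map), threshold = 0.25))
  }
  expect_gt(n_edges(sim_lig), n_edges(sim_apo))
})
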