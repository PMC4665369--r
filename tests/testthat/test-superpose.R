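test_that("superposing a model onto itself is the identity", {
  d <- gen_duplex("GGCAUGCCAUGC")
  sp <- superpose_structures(d, d, identity_pairing(d))
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$retained_pairs, sp$initial_pairs)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-12)
})

test_that("known rigid transforms are recovered exactly", {
  d <- gen_duplex("GGCAUGCCAUGC")
  R <- random_rotation(seed = 3)
  tr <- c(12, -7, 4)
  moved <- perturb_structure(d, R, tr)
  sp <- superpose_structures(moved, d, identity_pairing(d))
  expect_lt(sp$rmsd, 1e-9)
  # the recovered transform inverts the applied one
  expect_equal(sp$rotation, t(R), tolerance = 1e-9)
  expect_equal(as.vector(sp$rotation %*% tr + sp$translation), c(0, 0, 0),
               tolerance = 1e-9)
  # cross-check against an independent least-squares fit
  ref <- suppressWarnings(bio3d::fit.xyz(
    fixed = as.vector(t(as.matrix(d[, c("x", "y", "z")]))),
    mobile = as.vector(t(as.matrix(moved[, c("x", "y", "z")])))))
  expect_equal(sqrt(mean((ref - as.vector(t(as.matrix(d[, c("x", "y", "z")]))))^2) * 3),
               sp$rmsd, tolerance = 1e-6)
})

test_that("rmsd under Gaussian noise matches the closed-form expectation", {
  # for i.i.d. noise of sd sigma per coordinate, E[rmsd] -> sigma * sqrt(3)
  set.seed(20)
  seqs <- paste(sample(c("A", "C", "G", "U"), 20, replace = TRUE), collapse = "")
  d <- gen_duplex(seqs)
  # replicate atoms to reach ~500 pairs by using all atoms of the duplex
  pairing <- identity_pairing(d)
  expect_gte(nrow(pairing), 400)
  noisy <- perturb_structure(d, noise_sigma = 0.3, seed = 77)
  sp <- superpose_structures(noisy, d, pairing, prune_cutoff = 50)
  expect_equal(sp$rmsd, 0.3 * sqrt(3), tolerance = 0.1)
})

test_that("rmsd is invariant under a common rigid transform of both models", {
  d <- gen_duplex("GGCAUGCCAUGC")
  noisy <- perturb_structure(d, noise_sigma = 0.2, seed = 5)
  pairing <- identity_pairing(d)
  sp0 <- superpose_structures(noisy, d, pairing, prune_cutoff = 50)
  R <- random_rotation(seed = 13); tr <- c(-4, 9, 2)
  sp1 <- superpose_structures(perturb_structure(noisy, R, tr),
                              perturb_structure(d, R, tr),
                              pairing, prune_cutoff = 50)
  expect_equal(sp0$rmsd, sp1$rmsd, tolerance = 1e-9)
  expect_equal(det(sp1$rotation), 1, tolerance = 1e-12)
})

test_that("iterative pruning drops outliers and lowers the rmsd", {
  d <- gen_duplex("GGCAUGCCAUGC")
  noisy <- perturb_structure(d, noise_sigma = 0.05, seed = 8)
  # displace 10 atoms far away
  idx <- seq(1, nrow(noisy), length.out = 10)
  noisy$x[idx] <- noisy$x[idx] + 25
  pairing <- identity_pairing(d)
  unpruned <- superpose_structures(noisy, d, pairing, prune_cutoff = 1e6)
  pruned <- superpose_structures(noisy, d, pairing, prune_cutoff = 2.0)
  expect_equal(pruned$initial_pairs, nrow(pairing))
  expect_equal(pruned$retained_pairs, nrow(pairing) - 10)
  expect_lt(pruned$rmsd, unpruned$rmsd)
  expect_false(any(tidy(pruned)$retained[idx]))
  g <- glance(pruned)
  expect_equal(g$rotation_det, 1, tolerance = 1e-12)

  expect_error(superpose_structures(d, d, identity_pairing(d)[1:2, ]),
               class = "mthia_degeneracy_error")
})

test_that("residue equivalence maps by nearest transformed C1'", {
  d <- gen_duplex("GGCAUGCCAUGC")
  R <- random_rotation(seed = 4); tr <- c(3, 3, 3)
  moved <- perturb_structure(d, R, tr)
  sp <- superpose_structures(moved, d, identity_pairing(d))
  m <- map_equivalent_residue("A:5", moved, d, sp)
  expect_true(m$mapped)
  expect_equal(m$chain, "A")
  expect_equal(m$resno, 5L)
  # symmetric on ideal data
  inv <- superpose_structures(d, moved, identity_pairing(d))
  back <- map_equivalent_residue(paste0(m$chain, ":", m$resno), d, moved, inv)
  expect_equal(back$resno, 5L)
  # unmapped when the neighbourhood is absent
  other <- d[d$chain == "A" & d$resno > 8, ]
  m2 <- map_equivalent_residue("A:1", moved, other, sp, max_dist = 4)
  expect_false(m2$mapped)
  expect_true(is.na(m2$resno))
})

test_that("sequence-derived pairings drive cross-structure superposition", {
  d <- gen_duplex("GGCAUGCCAUGC")
  R <- random_rotation(seed = 21)
  moved <- perturb_structure(d, R, c(1, 2, 3))
  pairing <- pairing_from_sequences(moved, d, "A", "A")
  expect_equal(nrow(pairing), 12L)
  sp <- superpose_structures(moved, d, pairing)
  expect_lt(sp$rmsd, 1e-9)
})
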