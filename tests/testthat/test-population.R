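test_that("a single neutral closed-shell atom gets zero Mulliken charge", {
  res <- mulliken_populations(
    density = list(closed = matrix(2)), overlap = matrix(1),
    basis_to_atom = 1L, Z = 2L)
  expect_equal(res$charges, 0)
  expect_equal(res$spin_populations, 0)
})

test_that("a symmetric homonuclear case splits the population equally", {
  S <- matrix(c(1, 0.4, 0.4, 1), 2)
  # symmetric bonding MO, doubly occupied
  c1 <- 1 / sqrt(2 + 2 * 0.4)
  P <- 2 * tcrossprod(c(c1, c1))
  res <- mulliken_populations(list(closed = P), S, c(1L, 2L), c(1L, 1L))
  expect_equal(res$populations[1], res$populations[2])
  expect_equal(sum(res$populations), 2, tolerance = 1e-10)
})

test_that("matrix Mulliken agrees with the brute-force double loop", {
  set.seed(42)
  for (i in 1:100) {
    nb <- sample(3:10, 1)
    na <- sample(1:min(3, nb), 1)
    mw <- make_mock_wavefunction(n_basis = nb, n_atoms = na,
                                 n_occupied = sample.int(nb - 2L, 1L) + 1L,
                                 open_shell = sample(c(TRUE, FALSE), 1))
    wf <- mw$wavefunction
    P_total <- if ("closed" %in% names(wf$density)) wf$density$closed
               else wf$density$alpha + wf$density$beta
    res <- mulliken_populations(wf$density, wf$overlap, wf$basis_to_atom,
                                mw$Z)
    oracle <- brute_mulliken_populations(P_total, wf$overlap,
                                         wf$basis_to_atom, na)
    expect_equal(res$populations, oracle, tolerance = 1e-10)
    # conservation: charges sum to the molecular net charge
    expect_equal(sum(res$charges), mw$charge, tolerance = 1e-8)
  }
})

test_that("spin populations sum to the alpha-beta electron excess", {
  mw <- make_mock_wavefunction(n_basis = 8, n_atoms = 3, n_occupied = 3,
                               open_shell = TRUE, seed = 5)
  res <- mulliken_populations(mw$wavefunction$density,
                              mw$wavefunction$overlap,
                              mw$wavefunction$basis_to_atom, mw$Z)
  expect_equal(sum(res$spin_populations), 1, tolerance = 1e-8)
})

test_that("dimension and symmetry errors are caught", {
  S <- diag(2); S[1, 2] <- 0.1
  expect_error(mulliken_populations(list(closed = diag(2)), S, 1:2, c(1, 1)),
               "symmetric")
  expect_error(mulliken_populations(list(closed = diag(3)), diag(2), 1:2,
                                    c(1, 1)),
               "dimension")
})

test_that("MO fragment weights: localization, symmetry and the oracle", {
  # concentrated on one atom with identity overlap
  comp <- mo_fragment_composition(c(1, 0), diag(2), c(1L, 2L),
                                  c("A", "B"))
  expect_equal(unname(comp$weights[["A"]]), 1)
  # two equivalent atoms, S12 = 0.5, c = (1,1)/sqrt(3): equal split
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  comp2 <- mo_fragment_composition(c(1, 1) / sqrt(3), S, c(1L, 2L),
                                   c("A", "B"))
  expect_equal(unname(comp2$weights), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(sum(comp2$weights), 1, tolerance = 1e-8)

  set.seed(7)
  for (i in 1:100) {
    mw <- make_mock_wavefunction(n_basis = 9, n_atoms = 3, n_occupied = 3)
    wf <- mw$wavefunction
    frag <- c("f1", "f2", "f3")
    cvec <- wf$mo_coefficients$closed[, sample(9, 1)]
    comp3 <- mo_fragment_composition(cvec, wf$overlap, wf$basis_to_atom,
                                     frag)
    oracle <- brute_fragment_weights(cvec, wf$overlap, wf$basis_to_atom,
                                     frag)
    expect_equal(comp3$weights, oracle, tolerance = 1e-10)
    expect_equal(sum(comp3$weights), 1, tolerance = 1e-8)
  }
})

test_that("fragment weights are invariant under basis relabeling within atoms", {
  mw <- make_mock_wavefunction(n_basis = 6, n_atoms = 3, n_occupied = 2,
                               seed = 13)
  wf <- mw$wavefunction
  cvec <- wf$mo_coefficients$closed[, 2]
  frag <- c("A", "B", "C")
  ref <- mo_fragment_composition(cvec, wf$overlap, wf$basis_to_atom, frag)
  # swap the two basis functions of atom 1 (indices 1 and 2)
  perm <- c(2, 1, 3, 4, 5, 6)
  comp <- mo_fragment_composition(cvec[perm], wf$overlap[perm, perm],
                                  wf$basis_to_atom[perm], frag)
  expect_equal(comp$weights, ref$weights, tolerance = 1e-12)
})

test_that("unnormalized MOs and unmapped atoms are rejected", {
  expect_error(mo_fragment_composition(c(2, 0), diag(2), c(1L, 2L),
                                       c("A", "B")),
               "normalized")
  expect_error(mo_fragment_composition(c(1, 0), diag(2), c(1L, 2L),
                                       c("A", NA)),
               "unmapped")
})

test_that("delocalization ratio matches its closed forms", {
  mk <- function(w) structure(list(weights = w),
                              class = "fragment_composition")
  expect_equal(delocalization_ratio(mk(c(A = 1, B = 0, C = 0, D = 0))),
               0.25)
  expect_equal(delocalization_ratio(mk(rep(0.2, 5))), 1)
  # hand evaluation: (1 / 0.38) / 3
  expect_equal(delocalization_ratio(mk(c(0.5, 0.3, 0.2))),
               (1 / 0.38) / 3, tolerance = 1e-12)
  expect_error(delocalization_ratio(mk(numeric())), "empty")
})

test_that("valence/dipole-bound classification follows the threshold rule", {
  mk <- function(w) structure(list(weights = w),
                              class = "fragment_composition")
  expect_identical(classify_anion(mk(c(A = 0.95, B = 0.05))),
                   "dipole_bound")
  expect_identical(classify_anion(mk(rep(0.25, 4))), "valence_bound")
  expect_identical(classify_anion(mk(c(0.5, 0.3, 0.2))), "valence_bound")
  # boundary: major weight exactly at threshold counts as dipole-bound
  expect_identical(classify_anion(mk(c(0.85, 0.06, 0.09))), "dipole_bound")
  # second fragment at the ceiling blocks the dipole-bound call
  expect_identical(classify_anion(mk(c(0.88, 0.10, 0.02))),
                   "valence_bound")
  # thresholds are configurable
  expect_identical(classify_anion(mk(c(0.7, 0.3)), major = 0.6,
                                  minor = 0.4), "dipole_bound")
})

test_that("somo_composition finds the highest occupied alpha orbital", {
  mw <- make_mock_wavefunction(n_basis = 6, n_atoms = 3, n_occupied = 2,
                               open_shell = TRUE, seed = 3)
  geo <- geometry_frame(c("C", "C", "C"), cbind(1.5 * (0:2), 0, 0),
                        fragment = c("f1", "f2", "f3"))
  rec <- es_record(
    species_id = "somo", charge = -1L, multiplicity = 2L, state = "anion",
    geometry_tag = "opt_anion", level_tag = "basis1", e_elec = -1,
    orbitals = list(
      alpha = list(energies = c(-1, -0.5, -0.2, 0.1, 0.4, 0.9),
                   occupations = c(1, 1, 1, 0, 0, 0)),
      beta = list(energies = c(-1, -0.5, -0.1, 0.2, 0.5, 1),
                  occupations = c(1, 1, 0, 0, 0, 0))),
    wavefunction = mw$wavefunction)
  # geometry attached separately to skip the electron-count cross-check
  # (the mock wavefunction's nuclei are He-like placeholders)
  rec$geometry <- geo
  comp <- somo_composition(rec)
  expect_identical(comp$mo_index, 3L)
  oracle <- brute_fragment_weights(mw$wavefunction$mo_coefficients$alpha[, 3],
                                   mw$wavefunction$overlap,
                                   mw$wavefunction$basis_to_atom,
                                   c("f1", "f2", "f3"))
  expect_equal(comp$weights, oracle, tolerance = 1e-10)
})
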