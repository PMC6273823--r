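minimal_record <- function(...) {
  args <- list(
    species_id = "1", charge = 0L, multiplicity = 1L, state = "neutral",
    geometry_tag = "opt_neutral", level_tag = "basis1",
    e_elec = -100.5, zpve = 0.1,
    orbitals = list(closed = list(energies = c(-0.5, 0.1),
                                  occupations = c(2, 0))),
    geometry = geometry_frame("He", cbind(0, 0, 0))
  )
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(es_record, args)
}

test_that("a valid minimal record passes and prints", {
  rec <- minimal_record()
  expect_s3_class(rec, "es_record")
  expect_length(record_violations(rec), 0)
  expect_output(print(rec), "species 1")
})

test_that("each invariant violation is rejected by name", {
  expect_error(minimal_record(state = "cation"), "state")
  expect_error(minimal_record(zpve = -0.1), "zpve")
  expect_error(minimal_record(level_tag = "basis9"), "level_tag")
  expect_error(
    minimal_record(orbitals = list(closed = list(
      energies = c(0.1, -0.5), occupations = c(2, 0)))),
    "orbital_order")
  expect_error(
    minimal_record(orbitals = list(closed = list(
      energies = c(-0.5, 0.1), occupations = c(2, 2)))),
    "electron_count")
  expect_error(
    minimal_record(orbitals = list(closed = list(
      energies = c(-0.5, 0.1), occupations = c(3, 0)))),
    "occupation_range")
  # anion must carry charge -1
  expect_error(minimal_record(state = "anion", geometry_tag = "opt_anion"),
               "anion_charge")
  expect_error(minimal_record(atomic_charges = c(0, 0)), "atomic_charges")
})

test_that("geometry invariants hold: unique indices, Z >= 1, unique labels", {
  expect_error(geometry_frame(c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)),
                              label = c("C7", "C7")),
               "labels")
  expect_error(geometry_frame("X", cbind(0, 0, 0)), "unknown element")
  g <- geometry_frame(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
                      label = c("C9", "O9"))
  expect_identical(g$Z, c(6L, 8L))
})

test_that("record JSON round-trips field for field", {
  rec <- es_record(
    species_id = "roundtrip", charge = 0L, multiplicity = 1L,
    state = "neutral", geometry_tag = "opt_neutral", level_tag = "basis1",
    e_elec = -123.456789012345, zpve = 0.987654321,
    orbitals = list(closed = list(energies = c(-1.5, -0.5, 0.25, 0.5),
                                  occupations = c(2, 2, 0, 0))),
    n_imaginary_freq = 0L,
    geometry = geometry_frame(c("He", "He"), rbind(c(0, 0, 0), c(3, 0, 0)),
                              label = c("C7", NA),
                              fragment = c("exo_alkene", "piperidone_ring")),
    wavefunction = NULL,
    atomic_charges = c(0.12, -0.12),
    atomic_spin_populations = NULL
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_record(rec, f)
  back <- read_record(f)
  expect_equal(back$e_elec, rec$e_elec, tolerance = 1e-14)
  expect_equal(back$orbitals, rec$orbitals, tolerance = 1e-14)
  expect_equal(back$geometry, rec$geometry, tolerance = 1e-14)
  expect_equal(back$atomic_charges, rec$atomic_charges)
  expect_equal(back$zpve, rec$zpve)
  expect_null(back$wavefunction)
})

test_that("records with wavefunction matrices survive the JSON round trip", {
  mw <- make_mock_wavefunction(n_basis = 6, n_atoms = 3, n_occupied = 2,
                               seed = 11)
  rec <- es_record(
    species_id = "wf", charge = 0L, multiplicity = 1L, state = "neutral",
    geometry_tag = "opt_neutral", level_tag = "other", e_elec = -1,
    wavefunction = mw$wavefunction)
  f <- withr::local_tempfile(fileext = ".json")
  write_record(rec, f)
  back <- read_record(f)
  expect_equal(back$wavefunction$overlap, mw$wavefunction$overlap,
               tolerance = 1e-12)
  expect_equal(back$wavefunction$density$closed,
               mw$wavefunction$density$closed, tolerance = 1e-12)
})

test_that("schema violations in record files raise named parse errors", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"species_id": "x", "charge": 0}', f)
  expect_error(read_record(f), "missing_field")
  writeLines("not json at all {", f)
  expect_error(read_record(f), "json")
})

test_that("wavefunction invariants are enforced", {
  S <- diag(3); S[1, 2] <- 0.2  # asymmetric
  expect_error(wavefunction_data(S, 1:3), "symmetric")
  S <- diag(c(1, 1, 1.1))
  expect_error(wavefunction_data(S, 1:3), "diagonal")
  C <- matrix(c(2, 0, 0, 0, 1, 0, 0, 0, 1), 3)  # unnormalized column
  expect_error(wavefunction_data(diag(3), 1:3,
                                 mo_coefficients = list(closed = C)),
               "normalized")
})

test_that("XYZ read/write round-trips geometry and comment", {
  g <- load_fixture("toy_enone_xyz")
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g, f, comment = "toy opt_neutral")
  back <- read_xyz(f)
  expect_equal(back$comment, "toy opt_neutral")
  expect_equal(back$geometry[, c("x", "y", "z")], g[, c("x", "y", "z")],
               tolerance = 1e-10)
  expect_identical(back$geometry$element, g$element)
})

test_that("ingestion bridges a parsed payload without fabricating fields", {
  payload <- list(
    scf_energy_hartree = -42.25,
    orbital_energies_hartree = list(closed = c(-1, -0.4, 0.2)),
    occupations = list(closed = c(2, 2, 0))
  )
  rec <- ingest_parsed_output(payload)
  expect_null(rec$zpve)
  expect_null(rec$wavefunction)
  expect_equal(rec$e_elec, -42.25)

  open_payload <- list(
    species_id = "anion-x", charge = -1L, multiplicity = 2L,
    state = "anion", geometry_tag = "opt_anion",
    scf_energy_hartree = -42.5, zpve_hartree = 0.05,
    orbital_energies_hartree = list(alpha = c(-1, -0.3), beta = c(-0.9)),
    occupations = list(alpha = c(1, 1), beta = c(1))
  )
  rec2 <- ingest_parsed_output(open_payload)
  expect_named(rec2$orbitals, c("alpha", "beta"))
  expect_equal(rec2$zpve, 0.05)

  expect_error(ingest_parsed_output(list(scf_energy_hartree = -1)),
               "orbital energies")
})
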