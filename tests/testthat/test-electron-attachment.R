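test_that("corrected energies add ZPVE at stationary points only", {
  q <- make_species_quadruple(1.0, 0.8, 1.2, zpve_neutral = 0.1,
                              zpve_anion = 0.098, seed = 2)
  expect_equal(corrected_energy(q$neutral_opt),
               q$neutral_opt$e_elec + 0.1)
  expect_equal(corrected_energy(q$anion_vertical),
               q$anion_vertical$e_elec)
  q$neutral_opt$zpve <- NULL
  expect_error(corrected_energy(q$neutral_opt), "zpve")
})

test_that("composite energies are big-basis electronic plus small-basis ZPVE", {
  expect_equal(composite_energy(-100.5, 0.1), -100.4)
  expect_equal(composite_energy(0, 0), 0)
  expect_error(composite_energy(NA_real_, 0.1), "finite")
  # a prescribed basis shift survives the composite bookkeeping
  q1 <- make_species_quadruple(0.9, 0.8, 1.0, seed = 3)
  shift <- 0.015  # Hartree lowering from the bigger basis
  q2 <- q1
  for (m in names(q2)) {
    q2[[m]]$e_elec <- composite_energy(q1[[m]]$e_elec - shift, 0)
    q2[[m]]$level_tag <- "basis2_composite"
  }
  a1 <- attachment_energies(q1)
  a2 <- attachment_energies(q2)
  expect_equal(a2$aea, a1$aea, tolerance = 1e-9)  # common shift cancels
})

test_that("attachment energies match the hand-worked quadruple", {
  rec <- function(state, gtag, e, zpve = NULL) {
    es_record(species_id = "hand", charge = if (state == "anion") -1L else 0L,
              multiplicity = if (state == "anion") 2L else 1L,
              state = state, geometry_tag = gtag, level_tag = "basis1",
              e_elec = e, zpve = zpve)
  }
  q <- species_quadruple(
    neutral_opt = rec("neutral", "opt_neutral", -100.0, 0.1),
    anion_opt = rec("anion", "opt_anion", -100.04, 0.098),
    anion_vertical = rec("anion", "vertical_at_neutral", -100.03),
    neutral_vertical = rec("neutral", "vertical_at_anion", -99.995))
  ae <- attachment_energies(q)
  expect_equal(ae$aea, hartree_to_ev(0.042), tolerance = 1e-10)
  expect_equal(ae$vea, hartree_to_ev(0.030), tolerance = 1e-10)
  expect_equal(ae$vde, hartree_to_ev(0.045), tolerance = 1e-10)
  expect_equal(report_round(c(ae$aea, ae$vea, ae$vde), 3),
               c(1.143, 0.816, 1.225))
})

test_that("identical member energies give identically zero energies", {
  q <- make_species_quadruple(0, 0, 0, zpve_neutral = 0, zpve_anion = 0,
                              seed = 4)
  ae <- attachment_energies(q)
  expect_equal(c(ae$aea, ae$vea, ae$vde), c(0, 0, 0), tolerance = 1e-9)
})

test_that("quadruple construction enforces tags, ids and ZPVE presence", {
  q <- make_species_quadruple(1, 0.9, 1.1, seed = 5)
  mism <- q$anion_opt; mism$species_id <- "other"
  expect_error(species_quadruple(q$neutral_opt, mism, q$anion_vertical,
                                 q$neutral_vertical),
               "species_id")
  swapped <- q$anion_vertical
  expect_error(species_quadruple(q$neutral_opt, swapped, q$anion_vertical,
                                 q$neutral_vertical),
               "state/geometry_tag")
  no_zpve <- q$neutral_opt; no_zpve$zpve <- NULL
  expect_error(species_quadruple(no_zpve, q$anion_opt, q$anion_vertical,
                                 q$neutral_vertical),
               "zpve")
})

test_that("AEA is invariant under a common shift of all electronic energies", {
  q <- make_species_quadruple(0.932, 0.791, 1.059, seed = 6)
  a0 <- attachment_energies(q)
  for (m in names(q)) q[[m]]$e_elec <- q[[m]]$e_elec + 12.345
  a1 <- attachment_energies(q)
  expect_equal(a1$aea, a0$aea, tolerance = 1e-9)
  expect_equal(a1$vea, a0$vea, tolerance = 1e-9)
  expect_equal(a1$vde, a0$vde, tolerance = 1e-9)
})

test_that("bound checks distinguish holds / violated_lower / violated_upper", {
  mk <- function(a, v, d) structure(list(aea = a, vea = v, vde = d),
                                    class = "attachment_energies")
  expect_identical(check_bounds(mk(0.932, 0.791, 1.059)), "holds")
  expect_identical(check_bounds(mk(1, 1, 1)), "holds")
  expect_identical(check_bounds(mk(0.5, 0.6, 0.7)), "violated_lower")
  expect_identical(check_bounds(mk(0.8, 0.6, 0.7)), "violated_upper")
})

test_that("sign flags follow strict positivity", {
  mk <- function(a, v, d) structure(list(aea = a, vea = v, vde = d),
                                    class = "attachment_energies")
  expect_true(all(sign_interpretation(mk(0.932, 0.791, 1.059))))
  expect_identical(unname(sign_interpretation(mk(-0.1, -0.2, 0.05))),
                   c(FALSE, FALSE, TRUE))
  expect_false(any(sign_interpretation(mk(0, 0, 0))))
})

test_that("attachment_energy_table groups records and skips fragments", {
  q1 <- make_species_quadruple(1, 0.9, 1.1, species_id = "a", seed = 8)
  q2 <- make_species_quadruple(0.5, 0.4, 0.6, species_id = "b",
                               level_tag = "basis2_composite", seed = 9)
  recs <- c(unname(unclass(q1)), unname(unclass(q2)))
  # plus an orphan record that can never form a quadruple
  orphan <- make_species_quadruple(2, 1.9, 2.1, species_id = "c",
                                   seed = 10)$neutral_opt
  tab <- suppressMessages(attachment_energy_table(c(recs, list(orphan))))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$aea_ev[tab$compound == "a"], 1, tolerance = 1e-9)
  expect_equal(tab$vde_ev[tab$compound == "b"], 0.6, tolerance = 1e-9)
})
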