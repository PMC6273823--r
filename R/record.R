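#' Build a molecular geometry table
#'
#' A geometry is a plain `data.frame` with one row per atom and columns
#' `index` (1-based), `element`, `Z` (nuclear charge, e), `x`, `y`, `z`
#' (Angstrom), `label` (optional site label such as "C7", "C9", "O9",
#' "N11"), and `fragment` (optional fragment name such as
#' "piperidone_ring" or "exo_alkene"). Atom indices are 1-based
#' everywhere, matching the conventional numbering of the
#' C7=C8-C9=O9 enone fragment.
#'
#' @param element Character vector of element symbols.
#' @param xyz Numeric matrix, n x 3, Cartesian coordinates in Angstrom.
#' @param Z Integer nuclear charges; defaults to a lookup from `element`.
#' @param label Optional character vector of unique site labels.
#' @param fragment Optional character vector of fragment names.
#' @return A validated geometry `data.frame`.
#' @export
geometry_frame <- function(element, xyz, Z = NULL, label = NA_character_,
                           fragment = NA_character_) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- length(element)
  stopifnot(nrow(xyz) == n)
  if (is.null(Z)) Z <- element_z(element)
  g <- data.frame(
    index = seq_len(n), element = element, Z = as.integer(Z),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    label = rep_len(as.character(label), n),
    fragment = rep_len(as.character(fragment), n),
    stringsAsFactors = FALSE
  )
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  if (anyDuplicated(g$index)) {
    stop("geometry: atom indices must be unique", call. = FALSE)
  }
  if (any(g$Z < 1L)) {
    stop("geometry: nuclear charge Z must be >= 1", call. = FALSE)
  }
  lab <- g$label[!is.na(g$label)]
  if (anyDuplicated(lab)) {
    stop("geometry: site labels must be unique", call. = FALSE)
  }
  invisible(g)
}

# Element symbol -> nuclear charge, main-group coverage sufficient for
# organic electrophiles and their halogen/amine/nitrile substituents.
.ELEMENT_Z <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Br = 35L, I = 53L
)

element_z <- function(element) {
  z <- .ELEMENT_Z[element]
  if (any(is.na(z))) {
    stop("unknown element symbol: ",
         paste(element[is.na(z)], collapse = ", "), call. = FALSE)
  }
  unname(z)
}

#' Construct an electronic-structure record
#'
#' One record describes one chemical species at one geometry and one
#' level of theory: total electronic energy, optional zero-point
#' vibrational energy, per-spin orbital energies and occupations, and
#' optional wavefunction matrices or pre-condensed populations. Records
#' are the common currency of every analysis stage.
#'
#' Spin channels: an unrestricted (open-shell) record stores channels
#' `alpha` and `beta` with occupations in `[0, 1]`; a restricted
#' closed-shell record stores the single channel `closed` with
#' occupations in `[0, 2]`. The channel naming doubles as the dialect
#' flag.
#'
#' @param species_id Compound identifier, e.g. `"1"` .. `"12"`.
#' @param charge Net charge (e).
#' @param multiplicity Spin multiplicity 2S+1.
#' @param state `"neutral"` or `"anion"`.
#' @param geometry_tag One of `"opt_neutral"`, `"opt_anion"`,
#'   `"vertical_at_neutral"`, `"vertical_at_anion"`.
#' @param level_tag One of `"basis1"`, `"basis2_composite"`, `"other"`.
#' @param e_elec Total electronic energy, Hartree.
#' @param zpve Zero-point vibrational energy, Hartree, or `NULL` for
#'   vertical (non-stationary) points.
#' @param orbitals Named list of spin channels; each channel is a list
#'   with `energies` (Hartree, ascending) and `occupations`. `NULL` for
#'   energy-only records.
#' @param n_imaginary_freq Number of imaginary frequencies at the
#'   geometry, or `NULL` when no frequency job is attached.
#' @param geometry A [geometry_frame()] data frame, or `NULL`.
#' @param wavefunction A [wavefunction_data()] object, or `NULL`.
#' @param atomic_charges Optional per-atom charges (e).
#' @param atomic_spin_populations Optional per-atom spin populations (e).
#' @return An object of class `es_record`, validated.
#' @export
es_record <- function(species_id, charge, multiplicity, state,
                      geometry_tag, level_tag, e_elec, zpve = NULL,
                      orbitals = NULL, n_imaginary_freq = NULL,
                      geometry = NULL, wavefunction = NULL,
                      atomic_charges = NULL,
                      atomic_spin_populations = NULL) {
  rec <- structure(
    list(
      species_id = as.character(species_id),
      charge = as.integer(charge),
      multiplicity = as.integer(multiplicity),
      state = state,
      geometry_tag = geometry_tag,
      level_tag = level_tag,
      e_elec = as.numeric(e_elec),
      zpve = if (is.null(zpve)) NULL else as.numeric(zpve),
      orbitals = orbitals,
      n_imaginary_freq = if (is.null(n_imaginary_freq)) NULL
                         else as.integer(n_imaginary_freq),
      geometry = geometry,
      wavefunction = wavefunction,
      atomic_charges = atomic_charges,
      atomic_spin_populations = atomic_spin_populations
    ),
    class = "es_record"
  )
  validate_record(rec)
  rec
}

#' Validate an electronic-structure record
#'
#' Checks every record invariant and stops with a named violation on the
#' first failure. Use [record_violations()] for a non-throwing report of
#' all violations.
#'
#' @param rec An `es_record`.
#' @return `rec`, invisibly.
#' @export
validate_record <- function(rec) {
  v <- record_violations(rec)
  if (length(v)) {
    stop("invalid es_record [", v[[1L]]$name, "]: ", v[[1L]]$message,
         call. = FALSE)
  }
  invisible(rec)
}

#' List all invariant violations of a record
#'
#' @param rec An `es_record` (or a bare list shaped like one).
#' @return A list of violations, each a list with `name` and `message`;
#'   empty when the record is valid.
#' @export
record_violations <- function(rec) {
  v <- list()
  bad <- function(name, message) {
    v[[length(v) + 1L]] <<- list(name = name, message = message)
  }

  if (!rec$state %in% c("neutral", "anion")) {
    bad("state", paste0("unknown state '", rec$state, "'"))
  }
  tags <- c("opt_neutral", "opt_anion", "vertical_at_neutral",
            "vertical_at_anion")
  if (!rec$geometry_tag %in% tags) {
    bad("geometry_tag", paste0("unknown geometry_tag '", rec$geometry_tag, "'"))
  }
  if (!rec$level_tag %in% c("basis1", "basis2_composite", "other")) {
    bad("level_tag", paste0("unknown level_tag '", rec$level_tag, "'"))
  }
  if (!is.finite(rec$e_elec)) bad("e_elec", "e_elec must be finite")
  if (!is.null(rec$zpve)) {
    if (!is.finite(rec$zpve) || rec$zpve < 0) {
      bad("zpve", "zpve must be finite and >= 0")
    }
  }
  if (identical(rec$state, "anion") && rec$charge != -1L) {
    # neutral species here carry charge 0; the anion is one electron more
    bad("anion_charge", "state 'anion' requires charge = neutral - 1 = -1")
  }
  if (identical(rec$state, "neutral") && rec$charge != 0L) {
    bad("neutral_charge", "state 'neutral' requires charge 0")
  }

  if (!is.null(rec$orbitals)) {
    chans <- names(rec$orbitals)
    ok_sets <- list("closed", c("alpha", "beta"))
    if (!any(vapply(ok_sets, function(s) setequal(chans, s), logical(1)))) {
      bad("spin_channels",
          "orbital channels must be 'closed' or 'alpha'+'beta'")
    }
    occ_max <- if (identical(chans, "closed")) 2 else 1
    for (ch in chans) {
      o <- rec$orbitals[[ch]]
      if (length(o$energies) != length(o$occupations)) {
        bad("orbital_lengths",
            paste0("channel '", ch, "': energies/occupations length mismatch"))
        next
      }
      if (is.unsorted(o$energies)) {
        bad("orbital_order",
            paste0("channel '", ch, "': energies must be ascending"))
      }
      if (any(o$occupations < -1e-9 | o$occupations > occ_max + 1e-9)) {
        bad("occupation_range",
            paste0("channel '", ch, "': occupations outside [0, ",
                   occ_max, "]"))
      }
    }
    if (!is.null(rec$geometry)) {
      n_el <- sum(rec$geometry$Z) - rec$charge
      occ_sum <- sum(unlist(lapply(rec$orbitals, `[[`, "occupations")))
      if (abs(occ_sum - n_el) > 1e-6) {
        bad("electron_count",
            sprintf("occupation sum %.8f != electron count %d", occ_sum, n_el))
      }
    }
  }

  if (!is.null(rec$geometry)) {
    gv <- tryCatch({ validate_geometry(rec$geometry); NULL },
                   error = function(e) conditionMessage(e))
    if (!is.null(gv)) bad("geometry", gv)
    n_atoms <- nrow(rec$geometry)
    for (fld in c("atomic_charges", "atomic_spin_populations")) {
      if (!is.null(rec[[fld]]) && length(rec[[fld]]) != n_atoms) {
        bad(fld, paste0(fld, " length != number of atoms"))
      }
    }
  }

  if (!is.null(rec$wavefunction)) {
    wv <- tryCatch({ validate_wavefunction(rec$wavefunction); NULL },
                   error = function(e) conditionMessage(e))
    if (!is.null(wv)) bad("wavefunction", wv)
  }
  v
}

#' Assemble wavefunction matrices for population analysis
#'
#' Holds the per-spin MO coefficient matrices C (basis functions x MOs),
#' the overlap matrix S, the per-spin density matrices P, and the map
#' from basis-function index to atom index. These are the computable
#' representation behind orbital pictures: everything population
#' analysis needs and nothing more.
#'
#' @param overlap Symmetric basis x basis overlap matrix with unit
#'   diagonal.
#' @param basis_to_atom Integer vector mapping each basis function to a
#'   1-based atom index.
#' @param mo_coefficients Named list of per-spin coefficient matrices
#'   (`closed`, or `alpha`/`beta`), or `NULL`.
#' @param density Named list of per-spin density matrices, or `NULL`.
#' @return An object of class `wavefunction_data`.
#' @export
wavefunction_data <- function(overlap, basis_to_atom,
                              mo_coefficients = NULL, density = NULL) {
  wf <- structure(
    list(mo_coefficients = mo_coefficients, overlap = overlap,
         density = density, basis_to_atom = as.integer(basis_to_atom)),
    class = "wavefunction_data"
  )
  validate_wavefunction(wf)
  wf
}

validate_wavefunction <- function(wf) {
  S <- wf$overlap
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop("overlap must be a square matrix", call. = FALSE)
  }
  if (max(abs(S - t(S))) > 1e-8) {
    stop("overlap matrix must be symmetric within 1e-8", call. = FALSE)
  }
  if (max(abs(diag(S) - 1)) > 1e-8) {
    stop("overlap diagonal must be 1 within 1e-8", call. = FALSE)
  }
  nb <- nrow(S)
  if (length(wf$basis_to_atom) != nb) {
    stop("basis_to_atom length must equal basis dimension", call. = FALSE)
  }
  for (C in wf$mo_coefficients) {
    if (nrow(C) != nb) stop("MO coefficient rows != basis dimension",
                            call. = FALSE)
    norms <- colSums(C * (S %*% C))
    if (any(abs(norms - 1) > 1e-6)) {
      stop("MO columns must be S-normalized within 1e-6", call. = FALSE)
    }
  }
  for (P in wf$density) {
    if (!is.matrix(P) || any(dim(P) != nb)) {
      stop("density matrix dimensions != basis dimension", call. = FALSE)
    }
  }
  invisible(wf)
}

#' @export
print.es_record <- function(x, ...) {
  cat(sprintf("<es_record> species %s | %s | %s | %s\n", x$species_id,
              x$state, x$geometry_tag, x$level_tag))
  cat(sprintf("  E_elec = %.8f Ha", x$e_elec))
  if (!is.null(x$zpve)) cat(sprintf("  ZPVE = %.6f Ha", x$zpve))
  cat("\n")
  if (!is.null(x$orbitals)) {
    cat("  orbitals:", paste(names(x$orbitals), collapse = "+"),
        "(", sum(lengths(lapply(x$orbitals, `[[`, "energies"))), "levels )\n")
  }
  if (!is.null(x$geometry)) cat("  geometry:", nrow(x$geometry), "atoms\n")
  invisible(x)
}
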