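#' Mulliken gross atomic populations, charges and spin populations
#'
#' The gross population of atom A is the sum over its basis functions of
#' the diagonal of the density-overlap product, `diag(P_total %*% S)`;
#' the Mulliken charge is `Z_A` minus that population, and the spin
#' population comes from the spin density `P_alpha - P_beta`. Mulliken
#' is the default condensation scheme here (it is the default in the
#' mainstream quantum-chemistry codes whose outputs records mirror);
#' externally condensed charges from other schemes can be attached to a
#' record directly.
#'
#' @param density Named list of per-spin density matrices: `closed` for
#'   a restricted record, or `alpha` and `beta` for unrestricted.
#' @param overlap Symmetric overlap matrix S.
#' @param basis_to_atom Integer vector, basis function -> 1-based atom.
#' @param Z Integer vector of per-atom nuclear charges.
#' @return A list with `populations`, `charges` and `spin_populations`
#'   (all per-atom, e; spin populations are zero for a restricted
#'   density).
#' @export
mulliken_populations <- function(density, overlap, basis_to_atom, Z) {
  nb <- nrow(overlap)
  if (!isTRUE(all.equal(overlap, t(overlap), tolerance = 1e-8))) {
    stop("mulliken_populations: overlap must be symmetric", call. = FALSE)
  }
  for (P in density) {
    if (!is.matrix(P) || any(dim(P) != nb)) {
      stop("mulliken_populations: density/overlap dimension mismatch",
           call. = FALSE)
    }
  }
  if (length(basis_to_atom) != nb) {
    stop("mulliken_populations: basis_to_atom length mismatch",
         call. = FALSE)
  }
  n_atoms <- length(Z)
  if (!all(basis_to_atom %in% seq_len(n_atoms))) {
    stop("mulliken_populations: basis mapped to unknown atom",
         call. = FALSE)
  }

  if ("closed" %in% names(density)) {
    P_total <- density$closed
    P_spin <- matrix(0, nb, nb)
  } else {
    P_total <- density$alpha + density$beta
    P_spin <- density$alpha - density$beta
  }
  gop_total <- diag(P_total %*% overlap)   # gross orbital populations
  gop_spin <- diag(P_spin %*% overlap)
  atom_f <- factor(basis_to_atom, levels = seq_len(n_atoms))
  populations <- as.numeric(tapply(gop_total, atom_f, sum, default = 0))
  spin_populations <- as.numeric(tapply(gop_spin, atom_f, sum, default = 0))
  list(
    populations = populations,
    charges = Z - populations,
    spin_populations = spin_populations
  )
}

#' Fragment composition of one molecular orbital
#'
#' Mulliken partition of a normalized MO column c over named fragments:
#' the weight of fragment F is the sum over its basis functions of
#' `c * (S c)`. Weights sum to 1 for an S-normalized orbital; small
#' negative weights are a known Mulliken artifact and are reported raw.
#'
#' @param c Numeric MO coefficient vector (one column of C).
#' @param overlap Overlap matrix S.
#' @param basis_to_atom Integer vector, basis function -> atom index.
#' @param atom_to_fragment Character vector, atom index -> fragment
#'   name; every atom carrying a basis function must be mapped.
#' @param mo_index Optional MO index carried through to the result.
#' @param spin Optional spin channel name carried through.
#' @return An object of class `fragment_composition`: a list with
#'   `mo_index`, `spin` and `weights` (named numeric, fragments).
#' @export
mo_fragment_composition <- function(c, overlap, basis_to_atom,
                                    atom_to_fragment, mo_index = NA_integer_,
                                    spin = NA_character_) {
  norm <- sum(c * (overlap %*% c))
  if (abs(norm - 1) > 1e-6) {
    stop("mo_fragment_composition: MO is not S-normalized (c'Sc = ",
         format(norm), ")", call. = FALSE)
  }
  frag_of_basis <- atom_to_fragment[basis_to_atom]
  if (any(is.na(frag_of_basis))) {
    stop("mo_fragment_composition: basis function on unmapped atom",
         call. = FALSE)
  }
  contrib <- c * as.numeric(overlap %*% c)
  weights <- tapply(contrib, factor(frag_of_basis), sum)
  structure(
    list(mo_index = mo_index, spin = spin,
         weights = stats::setNames(as.numeric(weights), names(weights))),
    class = "fragment_composition"
  )
}

#' Delocalization ratio of a fragment composition
#'
#' Normalized participation ratio: `(1 / sum(w^2)) / n_fragments`.
#' Uniform spread over all fragments gives 1; full localization on a
#' single fragment gives `1/n_fragments`. Negative Mulliken artifacts
#' are clipped to zero and the weights renormalized before the ratio is
#' taken.
#'
#' @param comp A `fragment_composition`.
#' @return A fraction in (0, 1].
#' @export
delocalization_ratio <- function(comp) {
  w <- comp$weights
  if (!length(w)) stop("delocalization_ratio: empty weights", call. = FALSE)
  w <- pmax(w, 0)
  w <- w / sum(w)
  (1 / sum(w^2)) / length(w)
}

#' Classify an anion SOMO as valence- or dipole-bound
#'
#' A dipole-bound anion holds the excess electron in a limited region of
#' the molecule, so its SOMO is dominated by a single fragment; a
#' valence-bound anion spreads the SOMO over the molecular frame. The
#' rule: dipole-bound iff the largest fragment weight is at least
#' `major` AND the second-largest is below `minor`; otherwise
#' valence-bound. The thresholds are heuristic (orbital pictures, not a
#' sharp physical boundary) and therefore configurable. Negative
#' Mulliken artifacts are clipped to 0 for classification.
#'
#' @param comp A `fragment_composition`.
#' @param major Dominant-fragment threshold, default 0.85.
#' @param minor Second-fragment ceiling, default 0.10.
#' @return `"valence_bound"` or `"dipole_bound"`.
#' @export
classify_anion <- function(comp, major = 0.85, minor = 0.10) {
  w <- sort(pmax(comp$weights, 0), decreasing = TRUE)
  second <- if (length(w) >= 2L) w[[2L]] else 0
  if (w[[1L]] >= major && second < minor) "dipole_bound" else "valence_bound"
}

#' Tabulate fragment compositions of several MOs
#'
#' @param comps List of `fragment_composition` objects.
#' @return A long data.frame `mo_index, spin, fragment, weight`.
#' @export
fragment_composition_table <- function(comps) {
  do.call(rbind, lapply(comps, function(cp) {
    data.frame(mo_index = cp$mo_index, spin = cp$spin,
               fragment = names(cp$weights), weight = unname(cp$weights),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Fragment composition of a record's SOMO
#'
#' Locates the singly occupied MO of an open-shell record (the highest
#' alpha orbital with occupation above `threshold`) and partitions it
#' over the fragments declared in the record's geometry. The record
#' must carry alpha MO coefficients, an overlap matrix, and a fragment
#' assignment for every atom holding basis functions.
#'
#' @param rec An open-shell [es_record()] with orbitals, wavefunction
#'   and fragment-annotated geometry.
#' @param threshold Occupation cut defining "occupied".
#' @return A `fragment_composition` for the SOMO.
#' @export
somo_composition <- function(rec, threshold = 0.5) {
  if (is.null(rec$orbitals$alpha)) {
    stop("somo_composition: record has no alpha orbital channel",
         call. = FALSE)
  }
  if (is.null(rec$wavefunction$mo_coefficients$alpha)) {
    stop("somo_composition: record has no alpha MO coefficients",
         call. = FALSE)
  }
  occ <- rec$orbitals$alpha$occupations
  idx <- which(occ > threshold)
  if (!length(idx)) stop("somo_composition: no occupied alpha orbital",
                         call. = FALSE)
  somo <- max(idx)  # energies ascending, so the last occupied is highest
  frag <- rec$geometry$fragment
  if (any(is.na(frag))) {
    stop("somo_composition: geometry lacks fragment assignments",
         call. = FALSE)
  }
  mo_fragment_composition(
    c = rec$wavefunction$mo_coefficients$alpha[, somo],
    overlap = rec$wavefunction$overlap,
    basis_to_atom = rec$wavefunction$basis_to_atom,
    atom_to_fragment = frag,
    mo_index = somo, spin = "alpha"
  )
}
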