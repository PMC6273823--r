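#' Extract frontier-orbital energies from a record
#'
#' The HOMO is the highest-energy orbital whose occupation exceeds the
#' threshold (per spin orbital; 0.5 by default, robust to fractional
#' occupation printouts) and the LUMO the lowest-energy orbital below
#' it. For open-shell records the alpha channel defines the frontier by
#' default, so the SOMO plays the HOMO role; `spin = "merged"` pools
#' both channels instead.
#'
#' @param rec An [es_record()] with orbitals.
#' @param threshold Occupation cut separating occupied from virtual.
#' @param spin `"alpha"` (default for open shell) or `"merged"`.
#' @return A list with `eps_homo` and `eps_lumo` in eV.
#' @export
frontier_orbitals <- function(rec, threshold = 0.5, spin = c("alpha",
                                                             "merged")) {
  spin <- match.arg(spin)
  if (is.null(rec$orbitals)) {
    stop("frontier_orbitals: record has no orbitals", call. = FALSE)
  }
  if ("closed" %in% names(rec$orbitals)) {
    ch <- rec$orbitals["closed"]
    threshold <- threshold * 2  # restricted occupations run 0..2
  } else if (spin == "alpha") {
    ch <- rec$orbitals["alpha"]
  } else {
    ch <- rec$orbitals
  }
  energies <- unlist(lapply(ch, `[[`, "energies"), use.names = FALSE)
  occs <- unlist(lapply(ch, `[[`, "occupations"), use.names = FALSE)
  if (!length(energies)) {
    stop("frontier_orbitals: empty orbital list", call. = FALSE)
  }
  occupied <- occs > threshold
  if (!any(occupied)) {
    stop("frontier_orbitals: no occupied orbital", call. = FALSE)
  }
  if (all(occupied)) {
    stop("frontier_orbitals: no virtual orbital", call. = FALSE)
  }
  list(eps_homo = hartree_to_ev(max(energies[occupied])),
       eps_lumo = hartree_to_ev(min(energies[!occupied])))
}

#' Global conceptual-DFT reactivity indices
#'
#' From frontier-orbital energies in eV: the HOMO-LUMO gap, the
#' electronic chemical potential mu = (eps_H + eps_L)/2, the chemical
#' hardness eta = (eps_L - eps_H)/2 (the convention carrying the 1/2
#' factor), and the electrophilicity index omega = mu^2 / (2 eta),
#' all computed from unrounded inputs.
#'
#' @param eps_homo HOMO energy, eV.
#' @param eps_lumo LUMO energy, eV; must exceed `eps_homo`.
#' @return An object of class `global_indices`: list with `eps_homo`,
#'   `eps_lumo`, `gap`, `mu`, `eta`, `omega`, all eV.
#' @examples
#' gi <- global_reactivity(-6.01, -2.09)
#' report_round(c(gi$mu, gi$eta, gi$omega), 2)
#' @export
global_reactivity <- function(eps_homo, eps_lumo) {
  if (!is.finite(eps_homo) || !is.finite(eps_lumo)) {
    stop("global_reactivity: energies must be finite", call. = FALSE)
  }
  gap <- eps_lumo - eps_homo
  if (gap <= 0) {
    stop("global_reactivity: hardness undefined for gap <= 0",
         call. = FALSE)
  }
  mu <- (eps_homo + eps_lumo) / 2
  eta <- gap / 2
  structure(
    list(eps_homo = eps_homo, eps_lumo = eps_lumo, gap = gap,
         mu = mu, eta = eta, omega = mu^2 / (2 * eta)),
    class = "global_indices"
  )
}

#' @export
print.global_indices <- function(x, ...) {
  cat(sprintf(
    "<global_indices> HOMO %.2f  LUMO %.2f  GAP %.2f  mu %.2f  eta %.2f  omega %.2f (eV)\n",
    x$eps_homo, x$eps_lumo, x$gap, x$mu, x$eta, x$omega))
  invisible(x)
}

#' Rank compounds by electrophilicity
#'
#' Orders compounds by descending omega; values closer than `tie_tol`
#' share a rank (competition ranking), so chemically indistinguishable
#' electrophilicities — e.g. para-Cl versus para-Br congeners — report
#' as equal.
#'
#' @param indices Named list of `global_indices` (or named numeric
#'   vector of omega values); names are compound ids.
#' @param tie_tol Absolute omega difference treated as a tie (eV).
#' @return A data.frame `compound, omega, rank`, sorted by descending
#'   omega.
#' @export
rank_by_omega <- function(indices, tie_tol = 0.005) {
  omega <- if (is.numeric(indices)) indices
           else vapply(indices, `[[`, numeric(1), "omega")
  if (length(omega) < 1L) {
    stop("rank_by_omega: need at least one compound", call. = FALSE)
  }
  ord <- order(-omega, names(omega))
  omega <- omega[ord]
  rank <- integer(length(omega))
  rank[1L] <- 1L
  for (i in seq_along(omega)[-1L]) {
    rank[i] <- if (omega[i - 1L] - omega[i] < tie_tol) rank[i - 1L] else i
  }
  data.frame(compound = names(omega), omega = unname(omega), rank = rank,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Global-index table for a set of records
#'
#' Runs [frontier_orbitals()] and [global_reactivity()] over records and
#' assembles a table2-dialect data.frame ready for [write_table()].
#'
#' @param records Named list of [es_record()]s (names = compound ids) or
#'   unnamed (species_id used).
#' @param ... Passed to [frontier_orbitals()].
#' @return A data.frame in table2 column order, unrounded values.
#' @export
global_index_table <- function(records, ...) {
  ids <- names(records)
  if (is.null(ids)) {
    ids <- vapply(records, `[[`, character(1), "species_id")
  }
  rows <- lapply(seq_along(records), function(i) {
    fo <- frontier_orbitals(records[[i]], ...)
    gi <- global_reactivity(fo$eps_homo, fo$eps_lumo)
    data.frame(compound = ids[i], homo_ev = gi$eps_homo,
               lumo_ev = gi$eps_lumo, gap_ev = gi$gap, mu_ev = gi$mu,
               eta_ev = gi$eta, omega_ev = gi$omega,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
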