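#' Condensed Fukui function for nucleophilic attack
#'
#' Finite-difference form on atomic charges evaluated at the same
#' (neutral) geometry: `f+_k = q_k(N) - q_k(N+1)`, equivalently the
#' gain in gross population on atom k when one electron is added. The
#' values sum to 1 by construction of the inputs.
#'
#' @param charges_N Per-atom charges of the N-electron (neutral)
#'   species, e.
#' @param charges_N_plus_1 Per-atom charges of the (N+1)-electron
#'   species at the same geometry, e.
#' @return Per-atom f+ vector.
#' @export
fukui_plus <- function(charges_N, charges_N_plus_1) {
  if (length(charges_N) != length(charges_N_plus_1)) {
    stop("fukui_plus: charge vectors differ in length", call. = FALSE)
  }
  dq_total <- sum(charges_N) - sum(charges_N_plus_1)
  if (abs(dq_total - 1) > 1e-6) {
    stop(sprintf(
      "fukui_plus: total charge difference is %.8f, expected 1 (one added electron)",
      dq_total), call. = FALSE)
  }
  charges_N - charges_N_plus_1
}

#' Condensed Parr function for nucleophilic attack
#'
#' P+ is the atomic spin population of the radical anion: where the
#' unpaired (just-attached) electron sits. A doublet anion carries one
#' net spin, so the populations must sum to ~1; by default they are
#' renormalized to sum to exactly 1.
#'
#' @param spin_populations_anion Per-atom spin populations of the
#'   radical anion, e.
#' @param renormalize Renormalize to an exact unit sum (default TRUE);
#'   FALSE returns the raw populations.
#' @param tol Allowed deviation of the raw sum from 1.
#' @return Per-atom P+ vector.
#' @export
parr_plus <- function(spin_populations_anion, renormalize = TRUE,
                      tol = 1e-3) {
  s <- sum(spin_populations_anion)
  if (abs(s - 1) > tol) {
    stop(sprintf(
      "parr_plus: spin populations sum to %.6f, not 1 (is this a doublet anion?)",
      s), call. = FALSE)
  }
  if (renormalize) spin_populations_anion / s else spin_populations_anion
}

#' Bundle condensed site indices with their site labels
#'
#' @param fukui_plus Per-atom f+ vector.
#' @param parr_plus Per-atom P+ vector, or NULL.
#' @param site_map Named integer vector, site label -> atom index
#'   (e.g. `c(C7 = 7, C9 = 9)`).
#' @return An object of class `condensed_site_indices`.
#' @export
condensed_site_indices <- function(fukui_plus, parr_plus = NULL,
                                   site_map = integer()) {
  if (!is.null(parr_plus) &&
      length(parr_plus) != length(fukui_plus)) {
    stop("condensed_site_indices: index vectors differ in length",
         call. = FALSE)
  }
  if (length(site_map) && any(site_map > length(fukui_plus))) {
    stop("condensed_site_indices: site_map points past the atom list",
         call. = FALSE)
  }
  structure(list(fukui_plus = fukui_plus, parr_plus = parr_plus,
                 site_map = site_map),
            class = "condensed_site_indices")
}

#' Compare two electrophilic sites
#'
#' Reports, per condensed index, the difference value(site_a) -
#' value(site_b) and which site each index prefers. Differences smaller
#' than `tie_tol` (5e-4 by default, matching 3-decimal reporting) are
#' ties. For the enone fragment, site_a = C7 (beta carbon) and site_b =
#' C9 (carbonyl carbon).
#'
#' @param idx A [condensed_site_indices()].
#' @param site_a,site_b Labels resolvable through `idx$site_map`.
#' @param tie_tol Tie threshold on the index difference.
#' @return A list with `ordering` (`"a_preferred"`, `"b_preferred"` or
#'   `"tie"`, from f+ and P+ jointly when both agree, else from f+),
#'   `delta_f`, `delta_p` (NA if P+ absent), and per-index orderings.
#' @export
site_selectivity <- function(idx, site_a, site_b, tie_tol = 5e-4) {
  resolve <- function(lab) {
    if (!lab %in% names(idx$site_map)) {
      stop("site_selectivity: unknown site label '", lab, "'",
           call. = FALSE)
    }
    idx$site_map[[lab]]
  }
  ia <- resolve(site_a); ib <- resolve(site_b)
  order_of <- function(delta) {
    if (is.na(delta) || abs(delta) < tie_tol) "tie"
    else if (delta > 0) "a_preferred" else "b_preferred"
  }
  delta_f <- idx$fukui_plus[ia] - idx$fukui_plus[ib]
  delta_p <- if (is.null(idx$parr_plus)) NA_real_
             else idx$parr_plus[ia] - idx$parr_plus[ib]
  of <- order_of(delta_f); op <- order_of(delta_p)
  ordering <- if (is.na(delta_p) || op == "tie") of
              else if (of == "tie") op
              else if (identical(of, op)) of
              else "tie"   # indices disagree: no call
  list(ordering = ordering, delta_f = unname(delta_f),
       delta_p = unname(delta_p), ordering_f = of, ordering_p = op,
       site_a = site_a, site_b = site_b)
}

#' Preferred addition mode of an enone electrophile
#'
#' Conjugate (1,4) addition attacks the beta carbon C7; direct (1,2)
#' addition attacks the carbonyl carbon C9. The preferred mode follows
#' the site preferred by the condensed indices.
#'
#' @param sel Output of [site_selectivity()] with sites (C7, C9).
#' @return `"mode_1_4"`, `"mode_1_2"` or `"undetermined"` on a tie.
#' @export
addition_mode_report <- function(sel) {
  switch(sel$ordering,
         a_preferred = "mode_1_4",
         b_preferred = "mode_1_2",
         "undetermined")
}
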