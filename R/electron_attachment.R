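#' Bundle the four records behind one compound's attachment energies
#'
#' Adiabatic and vertical electron affinities and the vertical
#' detachment energy need four species: the optimized neutral, the
#' optimized radical anion, the anion at the neutral's geometry, and
#' the neutral at the anion's geometry. Stationary members carry a
#' ZPVE (and, when frequencies are attached, zero imaginary modes);
#' vertical members are single points and carry none.
#'
#' @param neutral_opt Record: state neutral, geometry_tag opt_neutral.
#' @param anion_opt Record: state anion, geometry_tag opt_anion.
#' @param anion_vertical Record: anion at vertical_at_neutral.
#' @param neutral_vertical Record: neutral at vertical_at_anion.
#' @return An object of class `species_quadruple`.
#' @export
species_quadruple <- function(neutral_opt, anion_opt, anion_vertical,
                              neutral_vertical) {
  q <- structure(
    list(neutral_opt = neutral_opt, anion_opt = anion_opt,
         anion_vertical = anion_vertical,
         neutral_vertical = neutral_vertical),
    class = "species_quadruple"
  )
  expect_tags <- list(
    neutral_opt = c("neutral", "opt_neutral"),
    anion_opt = c("anion", "opt_anion"),
    anion_vertical = c("anion", "vertical_at_neutral"),
    neutral_vertical = c("neutral", "vertical_at_anion")
  )
  for (m in names(expect_tags)) {
    rec <- q[[m]]
    if (is.null(rec)) stop("species_quadruple: missing member ", m,
                           call. = FALSE)
    if (!identical(rec$state, expect_tags[[m]][1]) ||
        !identical(rec$geometry_tag, expect_tags[[m]][2])) {
      stop("species_quadruple: member ", m, " has state/geometry_tag (",
           rec$state, ", ", rec$geometry_tag, ")", call. = FALSE)
    }
  }
  ids <- vapply(q, `[[`, character(1), "species_id")
  lvl <- vapply(q, `[[`, character(1), "level_tag")
  if (length(unique(ids)) != 1L || length(unique(lvl)) != 1L) {
    stop("species_quadruple: members must share species_id and level_tag",
         call. = FALSE)
  }
  for (m in c("neutral_opt", "anion_opt")) {
    if (is.null(q[[m]]$zpve)) {
      stop("species_quadruple: stationary member ", m, " lacks zpve",
           call. = FALSE)
    }
    nim <- q[[m]]$n_imaginary_freq
    if (!is.null(nim) && nim != 0L) {
      stop("species_quadruple: stationary member ", m,
           " has imaginary frequencies", call. = FALSE)
    }
  }
  q
}

#' ZPVE-corrected energy of a record
#'
#' Stationary points report `E = E_elec + ZPVE`; vertical single points
#' have no frequencies, so they report the electronic energy alone (the
#' parent stationary species' ZPVE would cancel in any vertical
#' difference anyway).
#'
#' @param rec An [es_record()].
#' @return Energy in Hartree.
#' @export
corrected_energy <- function(rec) {
  vertical <- rec$geometry_tag %in% c("vertical_at_neutral",
                                      "vertical_at_anion")
  if (vertical) return(rec$e_elec)
  if (is.null(rec$zpve)) {
    stop("corrected_energy: stationary record lacks zpve", call. = FALSE)
  }
  rec$e_elec + rec$zpve
}

#' Compose a big-basis energy with a small-basis ZPVE
#'
#' The composite protocol: single-point energies from a large basis on
#' geometries from a smaller one, corrected by the small basis's ZPVE.
#' The result belongs to level `basis2_composite`.
#'
#' @param e_elec_big Electronic energy at the large basis, Hartree.
#' @param zpve_small ZPVE from the small-basis frequency job, Hartree.
#' @return Sum, Hartree.
#' @export
composite_energy <- function(e_elec_big, zpve_small) {
  if (!is.finite(e_elec_big) || !is.finite(zpve_small)) {
    stop("composite_energy: inputs must be finite", call. = FALSE)
  }
  e_elec_big + zpve_small
}

#' Adiabatic/vertical electron affinities and detachment energy
#'
#' Sign convention is "neutral minus anion" throughout, so a positive
#' value means the anion lies lower:
#' \itemize{
#'   \item AEA = E(optimized neutral) - E(optimized anion), both
#'     ZPVE-corrected;
#'   \item VEA = E_elec(optimized neutral) - E_elec(anion at the
#'     neutral geometry);
#'   \item VDE = E_elec(neutral at the anion geometry) -
#'     E_elec(optimized anion).
#' }
#'
#' @param q A [species_quadruple()].
#' @return An object of class `attachment_energies`: list with `aea`,
#'   `vea`, `vde` (eV) and `level_tag`.
#' @export
attachment_energies <- function(q) {
  stopifnot(inherits(q, "species_quadruple"))
  aea <- corrected_energy(q$neutral_opt) - corrected_energy(q$anion_opt)
  vea <- q$neutral_opt$e_elec - q$anion_vertical$e_elec
  vde <- q$neutral_vertical$e_elec - q$anion_opt$e_elec
  structure(
    list(aea = hartree_to_ev(aea), vea = hartree_to_ev(vea),
         vde = hartree_to_ev(vde), level_tag = q$neutral_opt$level_tag),
    class = "attachment_energies"
  )
}

#' @export
print.attachment_energies <- function(x, ...) {
  cat(sprintf("<attachment_energies> AEA %.3f  VEA %.3f  VDE %.3f eV [%s]\n",
              x$aea, x$vea, x$vde, x$level_tag))
  invisible(x)
}

#' Check the vertical bounds on the adiabatic electron affinity
#'
#' When neutral and anion geometries are similar, the vertical electron
#' affinity and the vertical detachment energy bracket the adiabatic
#' value: VEA <= AEA <= VDE. The check allows 1e-9 eV of float slack,
#' far below the 1e-3 eV reporting precision.
#'
#' @param ae An `attachment_energies` (or list with `aea`,`vea`,`vde`).
#' @param slack Numeric slack in eV.
#' @return `"holds"`, `"violated_lower"` (VEA > AEA) or
#'   `"violated_upper"` (AEA > VDE).
#' @export
check_bounds <- function(ae, slack = 1e-9) {
  if (ae$vea > ae$aea + slack) return("violated_lower")
  if (ae$aea > ae$vde + slack) return("violated_upper")
  "holds"
}

#' Physical interpretation flags of attachment-energy signs
#'
#' Strictly positive AEA means the relaxed radical anion is bound;
#' positive VEA means vertical electron attachment is already
#' favorable; positive VDE means vertical electron auto-detachment from
#' the anion is unlikely.
#'
#' @param ae An `attachment_energies`.
#' @return Named logical vector `stable_anion`,
#'   `favorable_vertical_attachment`, `autodetachment_unlikely`.
#' @export
sign_interpretation <- function(ae) {
  c(stable_anion = ae$aea > 0,
    favorable_vertical_attachment = ae$vea > 0,
    autodetachment_unlikely = ae$vde > 0)
}

#' Attachment-energy table for grouped records
#'
#' Groups a flat list of records by species_id and level_tag, builds a
#' [species_quadruple()] per complete group, and returns a
#' table3-dialect data.frame. Incomplete groups are skipped with a
#' message rather than failing the run.
#'
#' @param records List of [es_record()]s.
#' @return A data.frame in table3 column order (unrounded eV values).
#' @export
attachment_energy_table <- function(records) {
  key <- vapply(records, function(r) paste(r$species_id, r$level_tag,
                                           sep = "\r"), character(1))
  rows <- list()
  for (k in unique(key)) {
    grp <- records[key == k]
    slot_of <- function(state, gtag) {
      hit <- Filter(function(r) identical(r$state, state) &&
                      identical(r$geometry_tag, gtag), grp)
      if (length(hit)) hit[[1L]] else NULL
    }
    members <- list(
      neutral_opt = slot_of("neutral", "opt_neutral"),
      anion_opt = slot_of("anion", "opt_anion"),
      anion_vertical = slot_of("anion", "vertical_at_neutral"),
      neutral_vertical = slot_of("neutral", "vertical_at_anion")
    )
    if (any(vapply(members, is.null, logical(1)))) {
      message("attachment_energy_table: skipping incomplete group ",
              sub("\r", "/", k, fixed = TRUE))
      next
    }
    ae <- attachment_energies(do.call(species_quadruple, members))
    rows[[length(rows) + 1L]] <- data.frame(
      compound = grp[[1L]]$species_id, level_tag = grp[[1L]]$level_tag,
      aea_ev = ae$aea, vea_ev = ae$vea, vde_ev = ae$vde,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(compound = character(), level_tag = character(),
                      aea_ev = numeric(), vea_ev = numeric(),
                      vde_ev = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
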