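#' @importFrom jsonlite read_json write_json
NULL

# Report-table CSV dialects. Column order is fixed per dialect; table2
# prints 2 decimals, table3 and table4 print 3.
.TABLE_DIALECTS <- list(
  table2 = list(
    columns = c("compound", "homo_ev", "lumo_ev", "gap_ev", "mu_ev",
                "eta_ev", "omega_ev"),
    digits = 2L
  ),
  table3 = list(
    columns = c("compound", "level_tag", "aea_ev", "vea_ev", "vde_ev"),
    digits = 3L
  ),
  table4 = list(
    columns = c("compound", "f_plus_c7", "f_plus_c9", "p_plus_c7",
                "p_plus_c9"),
    digits = 3L
  )
)

#' Read an electronic-structure record from JSON
#'
#' The on-disk schema stores one species/geometry/level per file with
#' energies in Hartree and coordinates in Angstrom; optional fields are
#' JSON `null` (never zero, since zero is a meaningful population
#' value). The returned record is fully validated.
#'
#' @param path Path to a record JSON file.
#' @return A validated [es_record()].
#' @export
read_record <- function(path) {
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("record parse error [json]: ",
                             conditionMessage(e), call. = FALSE)
  )
  required <- c("species_id", "charge", "multiplicity", "state",
                "geometry_tag", "level_tag", "e_elec_hartree")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("record parse error [missing_field]: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))

  orbitals <- NULL
  if (!is.null(raw$orbitals)) {
    orbitals <- lapply(raw$orbitals, function(ch) {
      list(energies = num(ch$energies_hartree),
           occupations = num(ch$occupations))
    })
  }

  geometry <- NULL
  if (!is.null(raw$geometry)) {
    atoms <- raw$geometry
    xyz <- t(vapply(atoms, function(a) as.numeric(unlist(a$xyz_angstrom)),
                    numeric(3)))
    opt_chr <- function(field) {
      vapply(atoms, function(a) {
        if (is.null(a[[field]])) NA_character_ else as.character(a[[field]])
      }, character(1))
    }
    geometry <- geometry_frame(
      element = vapply(atoms, function(a) as.character(a$element),
                       character(1)),
      xyz = xyz,
      Z = vapply(atoms, function(a) as.integer(a$z), integer(1)),
      label = opt_chr("label"),
      fragment = opt_chr("fragment")
    )
  }

  wavefunction <- NULL
  if (!is.null(raw$wavefunction)) {
    w <- raw$wavefunction
    as_mat <- function(m) do.call(rbind, lapply(m, function(r) num(r)))
    wavefunction <- wavefunction_data(
      overlap = as_mat(w$overlap),
      basis_to_atom = as.integer(unlist(w$basis_to_atom)),
      mo_coefficients = if (is.null(w$mo_coefficients)) NULL
                        else lapply(w$mo_coefficients, as_mat),
      density = if (is.null(w$density)) NULL
                else lapply(w$density, as_mat)
    )
  }

  es_record(
    species_id = raw$species_id, charge = raw$charge,
    multiplicity = raw$multiplicity, state = raw$state,
    geometry_tag = raw$geometry_tag, level_tag = raw$level_tag,
    e_elec = raw$e_elec_hartree, zpve = num(raw$zpve_hartree),
    orbitals = orbitals, n_imaginary_freq = raw$n_imaginary_freq,
    geometry = geometry, wavefunction = wavefunction,
    atomic_charges = num(raw$atomic_charges),
    atomic_spin_populations = num(raw$atomic_spin_populations)
  )
}

#' Write an electronic-structure record to JSON
#'
#' @param rec A validated [es_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path) {
  validate_record(rec)
  geometry <- NULL
  if (!is.null(rec$geometry)) {
    g <- rec$geometry
    geometry <- lapply(seq_len(nrow(g)), function(i) {
      list(index = g$index[i], element = g$element[i], z = g$Z[i],
           xyz_angstrom = c(g$x[i], g$y[i], g$z[i]),
           label = if (is.na(g$label[i])) NULL else g$label[i],
           fragment = if (is.na(g$fragment[i])) NULL else g$fragment[i])
    })
  }
  wavefunction <- NULL
  if (!is.null(rec$wavefunction)) {
    w <- rec$wavefunction
    mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])
    wavefunction <- list(
      mo_coefficients = if (is.null(w$mo_coefficients)) NULL
                        else lapply(w$mo_coefficients, mat_rows),
      overlap = mat_rows(w$overlap),
      density = if (is.null(w$density)) NULL
                else lapply(w$density, mat_rows),
      basis_to_atom = w$basis_to_atom
    )
  }
  orbitals <- NULL
  if (!is.null(rec$orbitals)) {
    orbitals <- lapply(rec$orbitals, function(ch) {
      list(energies_hartree = ch$energies, occupations = ch$occupations)
    })
  }
  payload <- list(
    species_id = rec$species_id, charge = rec$charge,
    multiplicity = rec$multiplicity, state = rec$state,
    geometry_tag = rec$geometry_tag, level_tag = rec$level_tag,
    e_elec_hartree = rec$e_elec, zpve_hartree = rec$zpve,
    orbitals = orbitals, n_imaginary_freq = rec$n_imaginary_freq,
    geometry = geometry, wavefunction = wavefunction,
    atomic_charges = rec$atomic_charges,
    atomic_spin_populations = rec$atomic_spin_populations
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a report table in one of the packaged CSV dialects
#'
#' Dialects mirror the three report layouts: `table2` (frontier energies
#' and global indices, 2 decimals), `table3` (attachment energies per
#' level of theory in tidy long form, 3 decimals), `table4` (condensed
#' site indices at C7/C9, 3 decimals). Decimal point is ".", separator
#' ",", no thousands separators, so write-then-read round-trips values
#' at the printed precision.
#'
#' @param rows A data.frame whose columns match the dialect exactly.
#' @param dialect One of `"table2"`, `"table3"`, `"table4"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, dialect, path) {
  d <- .TABLE_DIALECTS[[match.arg(dialect, names(.TABLE_DIALECTS))]]
  if (!identical(names(rows), d$columns)) {
    stop("write_table: columns must be exactly {",
         paste(d$columns, collapse = ","), "}", call. = FALSE)
  }
  out <- rows
  for (col in d$columns) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- sprintf(paste0("%.", d$digits, "f"),
                            report_round(out[[col]], d$digits))
    } else {
      out[[col]] <- as.character(out[[col]])
    }
  }
  lines <- c(paste(d$columns, collapse = ","),
             if (nrow(out)) do.call(paste, c(unname(as.list(out)),
                                             sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a report table written by [write_table()]
#'
#' @param path CSV path.
#' @param dialect One of `"table2"`, `"table3"`, `"table4"`.
#' @return A data.frame with the dialect's columns; numeric columns
#'   parsed as numeric.
#' @export
read_table <- function(path, dialect) {
  d <- .TABLE_DIALECTS[[match.arg(dialect, names(.TABLE_DIALECTS))]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), d$columns)) {
    stop("read_table: header does not match dialect '", dialect, "'",
         call. = FALSE)
  }
  for (col in setdiff(d$columns, c("compound", "level_tag"))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Write a geometry as standard XYZ
#'
#' The comment line carries `species_id` and `geometry_tag` separated by
#' a space, so a scan or pipeline run can re-identify the frame.
#'
#' @param geometry A [geometry_frame()] data frame.
#' @param path Output path.
#' @param comment Comment line content.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geometry, path, comment = "") {
  lines <- c(
    as.character(nrow(geometry)),
    comment,
    sprintf("%-2s %18.12f %18.12f %18.12f", geometry$element,
            geometry$x, geometry$y, geometry$z)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a standard XYZ file
#'
#' @param path XYZ path.
#' @return A list with `geometry` (a [geometry_frame()]) and `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  comment <- lines[2L]
  body <- lines[2L + seq_len(n)]
  parts <- strsplit(trimws(body), "\\s+")
  element <- vapply(parts, `[[`, character(1), 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  list(geometry = geometry_frame(element, xyz), comment = comment)
}

#' Bridge a parsed quantum-chemistry payload into the record schema
#'
#' Accepts the flat list shape that generic QC log parsers produce:
#' an SCF energy, per-spin MO energies and occupations, and optional
#' geometry/ZPVE/matrix blocks. Fields absent in the payload stay
#' absent in the record — ingestion never fabricates a ZPVE or
#' matrices.
#'
#' @param parsed A list with at least `scf_energy_hartree`,
#'   `orbital_energies_hartree` (named per-spin list) and `occupations`
#'   (matching named list); optionally `zpve_hartree`, `elements` +
#'   `coords_angstrom`, `n_imaginary_freq`, and the identification
#'   fields (`species_id`, `charge`, `multiplicity`, `state`,
#'   `geometry_tag`, `level_tag`, defaulting to a neutral optimized
#'   species).
#' @return A validated [es_record()].
#' @export
ingest_parsed_output <- function(parsed) {
  if (is.null(parsed$scf_energy_hartree)) {
    stop("ingest: payload lacks scf_energy_hartree", call. = FALSE)
  }
  if (is.null(parsed$orbital_energies_hartree)) {
    stop("ingest: payload lacks orbital energies", call. = FALSE)
  }
  energies <- parsed$orbital_energies_hartree
  occs <- parsed$occupations
  if (is.null(occs) || !identical(names(occs), names(energies))) {
    stop("ingest: occupations must accompany orbital energies per spin",
         call. = FALSE)
  }
  orbitals <- lapply(names(energies), function(ch) {
    list(energies = as.numeric(energies[[ch]]),
         occupations = as.numeric(occs[[ch]]))
  })
  names(orbitals) <- names(energies)
  geometry <- NULL
  if (!is.null(parsed$elements)) {
    geometry <- geometry_frame(parsed$elements, parsed$coords_angstrom)
  }
  es_record(
    species_id = parsed$species_id %||% "unknown",
    charge = parsed$charge %||% 0L,
    multiplicity = parsed$multiplicity %||% 1L,
    state = parsed$state %||% "neutral",
    geometry_tag = parsed$geometry_tag %||% "opt_neutral",
    level_tag = parsed$level_tag %||% "other",
    e_elec = parsed$scf_energy_hartree,
    zpve = parsed$zpve_hartree,
    orbitals = orbitals,
    n_imaginary_freq = parsed$n_imaginary_freq,
    geometry = geometry
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
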