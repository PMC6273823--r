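#' Torsion-scan machinery
#'
#' Rigid two-dihedral conformational grid scans of the kind used to
#' locate the minimum-energy rotamer about the N11-C12 and C12-C(aryl)
#' bonds of an N-benzyl piperidone before reoptimization. The energy
#' model is a pluggable callback (a semiempirical engine, a DFT
#' single-point wrapper, or one of the packaged analytic surfaces); the
#' scan logic, dihedral driver and connectivity partitioning live here.
#'
#' @name torsion-scan
NULL

# Covalent radii (Angstrom, Pyykko-style single-bond values) for the
# connectivity cutoff dist <= scale * (r_a + r_b).
.COVALENT_RADII <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
  N = 0.71, O = 0.66, F = 0.57, Na = 1.66, Mg = 1.41, Al = 1.21,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, K = 2.03, Ca = 1.76,
  Br = 1.20, I = 1.39
)

#' Dihedral scan specification
#'
#' @param atoms Integer vector of four distinct 1-based atom indices
#'   (a, b, c, d); the scan rotates about the b-c bond.
#' @param grid Angles in degrees, each in `[-180, 180)`; default a 15
#'   degree grid (24 points).
#' @return An object of class `dihedral_spec`.
#' @export
dihedral_spec <- function(atoms, grid = seq(-180, 165, by = 15)) {
  atoms <- as.integer(atoms)
  if (length(atoms) != 4L || anyDuplicated(atoms)) {
    stop("dihedral_spec: need four distinct atom indices", call. = FALSE)
  }
  if (any(grid < -180 | grid >= 180)) {
    stop("dihedral_spec: grid angles must lie in [-180, 180)",
         call. = FALSE)
  }
  structure(list(atoms = atoms, grid = as.numeric(grid)),
            class = "dihedral_spec")
}

#' Measure a dihedral angle
#'
#' @param geometry A [geometry_frame()].
#' @param atoms Four 1-based atom indices (a, b, c, d).
#' @return Signed a-b-c-d dihedral in degrees, in `[-180, 180)`.
#' @export
measure_dihedral <- function(geometry, atoms) {
  p <- as.matrix(geometry[match(atoms, geometry$index), c("x", "y", "z")])
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  # IUPAC-signed: atan2(|b2| b1.(b2 x b3), (b1 x b2).(b2 x b3))
  y <- sqrt(sum(b2^2)) * sum(b1 * pracma_cross(b2, b3))
  x <- sum(pracma_cross(b1, b2) * pracma_cross(b2, b3))
  ang <- atan2(y, x) * 180 / pi
  if (ang >= 180) ang <- ang - 360
  if (ang < -180) ang <- ang + 360
  ang
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Adjacency from covalent radii; returns an n x n logical matrix.
connectivity_matrix <- function(geometry, scale = 1.2) {
  xyz <- as.matrix(geometry[, c("x", "y", "z")])
  r <- .COVALENT_RADII[geometry$element]
  if (any(is.na(r))) {
    stop("connectivity: no covalent radius for element(s) ",
         paste(unique(geometry$element[is.na(r)]), collapse = ", "),
         call. = FALSE)
  }
  d <- as.matrix(stats::dist(xyz))
  cutoff <- outer(r, r, `+`) * scale
  adj <- d <= cutoff & d > 1e-8
  diag(adj) <- FALSE
  adj
}

# Atoms reachable from `start` in adj with the b-c edge removed.
component_from <- function(adj, start, drop_edge) {
  adj[drop_edge[1], drop_edge[2]] <- FALSE
  adj[drop_edge[2], drop_edge[1]] <- FALSE
  n <- nrow(adj)
  seen <- logical(n)
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    nbr <- which(adj[cur, ] & !seen)
    seen[nbr] <- TRUE
    queue <- c(queue, nbr)
  }
  which(seen)
}

#' Set a dihedral by rigid rotation
#'
#' Rotates the part of the molecule on the far side of the b-c bond
#' about the b-c axis until the a-b-c-d dihedral equals `angle`. The
#' rotation is a rigid-body isometry, so every bond length and every
#' distance within the rotated group is preserved. The b-c bond must
#' partition the molecule (i.e. not sit in a ring) under covalent-radius
#' connectivity.
#'
#' @param geometry A [geometry_frame()].
#' @param spec A [dihedral_spec()] (its grid is ignored here).
#' @param angle Target dihedral, degrees.
#' @param scale Covalent-radius scale for connectivity (default 1.2).
#' @return The geometry with the dihedral set to `angle`.
#' @export
set_dihedral <- function(geometry, spec, angle, scale = 1.2) {
  at <- spec$atoms
  adj <- connectivity_matrix(geometry, scale)
  ib <- match(at[2], geometry$index)
  ic <- match(at[3], geometry$index)
  distal <- component_from(adj, ic, c(ib, ic))
  if (ib %in% distal) {
    stop("set_dihedral: bond ", at[2], "-", at[3],
         " lies in a ring; rotation would not partition the molecule",
         call. = FALSE)
  }
  current <- measure_dihedral(geometry, at)
  delta <- (angle - current) * pi / 180
  xyz <- as.matrix(geometry[, c("x", "y", "z")])
  axis <- xyz[ic, ] - xyz[ib, ]
  axis <- axis / sqrt(sum(axis^2))
  # Rodrigues rotation of the distal set about the b->c axis through b
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(delta) * K + (1 - cos(delta)) * (K %*% K)
  origin <- xyz[ib, ]
  moved <- sweep(xyz[distal, , drop = FALSE], 2, origin)
  xyz[distal, ] <- sweep(moved %*% t(R), 2, origin, `+`)
  geometry$x <- xyz[, 1]; geometry$y <- xyz[, 2]; geometry$z <- xyz[, 3]
  geometry
}

#' Two-dihedral conformational grid scan
#'
#' Evaluates `energy_fn` on the full cross product of the two dihedral
#' grids and returns every grid point plus the argmin, with ties broken
#' by the lexicographically smallest (theta1, theta2). With a geometry,
#' each point is generated by [set_dihedral()] and the callback is
#' invoked as `energy_fn(geometry, theta)`; with `geometry = NULL` the
#' callback sees only `theta = c(theta1, theta2)` — the pure
#' angle-space form used with analytic surfaces.
#'
#' @param geometry A [geometry_frame()] or `NULL`.
#' @param specs List of two [dihedral_spec()]s.
#' @param energy_fn Callback returning a finite scalar energy
#'   (arbitrary units, only differences matter).
#' @return An object of class `torsion_scan_result`: list with `grid`
#'   (data.frame `theta1_deg,theta2_deg,energy`) and `minimum` (list
#'   `theta1`, `theta2`, `energy`).
#' @export
grid_scan <- function(geometry, specs, energy_fn) {
  if (length(specs) != 2L) {
    stop("grid_scan: exactly two dihedral specs required", call. = FALSE)
  }
  g1 <- sort(specs[[1L]]$grid)
  g2 <- sort(specs[[2L]]$grid)
  pts <- expand.grid(theta2_deg = g2, theta1_deg = g1)[, 2:1]
  energy <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    th <- c(pts$theta1_deg[i], pts$theta2_deg[i])
    e <- tryCatch({
      if (is.null(geometry)) {
        energy_fn(th)
      } else {
        geo <- set_dihedral(geometry, specs[[1L]], th[1])
        geo <- set_dihedral(geo, specs[[2L]], th[2])
        energy_fn(geo, th)
      }
    }, error = function(err) {
      stop(sprintf("grid_scan: energy callback failed at (%g, %g): %s",
                   th[1], th[2], conditionMessage(err)), call. = FALSE)
    })
    if (!is.finite(e)) {
      stop(sprintf("grid_scan: non-finite energy at (%g, %g)",
                   th[1], th[2]), call. = FALSE)
    }
    energy[i] <- e
  }
  grid <- data.frame(theta1_deg = pts$theta1_deg,
                     theta2_deg = pts$theta2_deg, energy = energy)
  # argmin with lexicographic (theta1, theta2) tie-break: grid is already
  # sorted lexicographically, and which.min takes the first minimum.
  imin <- which.min(energy)
  structure(
    list(grid = grid,
         minimum = list(theta1 = grid$theta1_deg[imin],
                        theta2 = grid$theta2_deg[imin],
                        energy = energy[imin])),
    class = "torsion_scan_result"
  )
}

#' @export
print.torsion_scan_result <- function(x, ...) {
  cat(sprintf(
    "<torsion_scan_result> %d points; minimum E = %.6f at (%g, %g) deg\n",
    nrow(x$grid), x$minimum$energy, x$minimum$theta1, x$minimum$theta2))
  invisible(x)
}

#' Packaged analytic two-dihedral torsional surface
#'
#' A separable cosine potential
#' `V = k1 (1 - cos(theta1 - m1)) + k2 (1 - cos(theta2 - m2))` with its
#' global minimum at `(m1, m2)`, usable directly as the angle-space
#' callback of [grid_scan()]. A stand-in for a semiempirical torsional
#' profile in tests and demos.
#'
#' @param minima Numeric length-2, minimum position in degrees.
#' @param barriers Numeric length-2 force amplitudes (energy units).
#' @return Function `f(theta)` (or `f(geometry, theta)`) returning the
#'   surface value.
#' @export
cosine_torsion_surface <- function(minima = c(60, 0), barriers = c(1, 1)) {
  force(minima); force(barriers)
  function(...) {
    args <- list(...)
    theta <- args[[length(args)]]  # angle vector is always last
    d <- (theta - minima) * pi / 180
    sum(barriers * (1 - cos(d)))
  }
}

#' Write a torsion-scan grid to CSV
#'
#' @param result A `torsion_scan_result`.
#' @param path Output path; columns `theta1_deg,theta2_deg,energy`.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(result, path) {
  utils::write.csv(result$grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
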