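# Independent brute-force oracles used across the suite. These stay
# elementwise / closed-form so they cannot share a code path with the
# matrix implementations they check.

# Mulliken gross population of each atom by explicit double loop over
# basis-function pairs.
brute_mulliken_populations <- function(P_total, S, basis_to_atom, n_atoms) {
  nb <- nrow(S)
  pop <- numeric(n_atoms)
  for (mu in seq_len(nb)) {
    acc <- 0
    for (nu in seq_len(nb)) acc <- acc + P_total[mu, nu] * S[nu, mu]
    pop[basis_to_atom[mu]] <- pop[basis_to_atom[mu]] + acc
  }
  pop
}

# Fragment weights of one MO by explicit summation.
brute_fragment_weights <- function(c, S, basis_to_atom, atom_to_fragment) {
  nb <- length(c)
  frags <- sort(unique(atom_to_fragment))
  w <- stats::setNames(numeric(length(frags)), frags)
  for (mu in seq_len(nb)) {
    acc <- 0
    for (nu in seq_len(nb)) acc <- acc + c[mu] * S[mu, nu] * c[nu]
    f <- atom_to_fragment[basis_to_atom[mu]]
    w[f] <- w[f] + acc
  }
  w
}

# OLS by explicit normal equations on the design matrix [1 x].
brute_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Z-matrix (NeRF) placement: position D at distance r from C, angle
# B-C-D = ang and dihedral A-B-C-D = tor (degrees). Independent of the
# package's dihedral code, so it doubles as a construction oracle.
place_atom <- function(A, B, C, r, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  d2 <- c(-r * cos(ang), r * sin(ang) * cos(tor), r * sin(ang) * sin(tor))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  C + as.numeric(cbind(bc, m, n) %*% d2)
}

# A butane-like 4-carbon chain with a prescribed 1-2-3-4 dihedral.
chain_geometry <- function(dihedral_deg = 60) {
  A <- c(-0.51, 1.45, 0)   # ~1.54 from B at ~110 degrees
  B <- c(0, 0, 0)
  C <- c(1.54, 0, 0)
  D <- place_atom(A, B, C, 1.54, 112, dihedral_deg)
  geometry_frame(rep("C", 4), rbind(A, B, C, D))
}

# the packaged synthetic enone geometry with enone-site labels attached
labelled_enone <- function() {
  g <- load_fixture("toy_enone_xyz")
  g$label[1:4] <- c("C7", "C8", "C9", "O9")
  g
}

order_by_id <- function(ids) order(as.numeric(ids))
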