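# Small in-code molecular fixtures used across the test files.

# planar benzene ring with one phenolic OH and explicit ring hydrogens:
# atoms 1-6 ring C, 7 O, 8 H(on O), 9-13 H(on ring C2..C6)
toy_phenol <- function() {
  ang <- seq(0, by = pi / 3, length.out = 6)
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  coords <- rbind(ring,
                  c(2.75 * cos(ang[1]), 2.75 * sin(ang[1]), 0),   # O on C1
                  c(3.7 * cos(ang[1]), 3.7 * sin(ang[1]), 0),     # H on O
                  cbind(2.5 * cos(ang[2:6]), 2.5 * sin(ang[2:6]), 0))
  bonds <- rbind(cbind(1:6, c(2:6, 1)), c(1, 7), c(7, 8),
                 cbind(2:6, 9:13))
  list(coords = coords,
       elements = c(rep("C", 6), "O", "H", rep("H", 5)),
       bonds = bonds,
       formal_charges = rep(0, 13))
}

# protonated piperidine (chair-ish hexagon is fine for typing): atoms
# 1 N+, 2-6 ring C, 7-8 H on N, 9-18 H on ring C
toy_piperidinium <- function() {
  ang <- seq(0, by = pi / 3, length.out = 6)
  ring <- cbind(1.45 * cos(ang), 1.45 * sin(ang), 0.2 * rep(c(1, -1), 3))
  h1 <- cbind(2.4 * cos(ang), 2.4 * sin(ang), 0.8)
  h2 <- cbind(2.4 * cos(ang), 2.4 * sin(ang), -0.8)
  coords <- rbind(ring, h1[1, , drop = FALSE], h2[1, , drop = FALSE],
                  h1[2:6, ], h2[2:6, ])
  bonds <- rbind(cbind(1:6, c(2:6, 1)),
                 c(1, 7), c(1, 8),
                 cbind(2:6, 9:13), cbind(2:6, 14:18))
  list(coords = coords,
       elements = c("N", rep("C", 5), rep("H", 12)),
       bonds = bonds,
       formal_charges = c(1, rep(0, 17)))
}

# butane-like 4-atom heavy chain with one rotatable central torsion
toy_chain4 <- function() {
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.3, 0), c(3.8, 1.3, 0.4))
  list(coords = coords, elements = rep("C", 4),
       bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
}

# dihedral angle oracle, independent of the package internals
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# single-conformer ensemble helper for grid tests
one_conf_ensemble <- function(coords, elements, id = "x", bonds = NULL) {
  conformer_ensemble(id, array(coords, dim = c(nrow(coords), 3, 1)),
                     energies = 0, elements = elements, bonds = bonds)
}

# random proper rotation matrix (det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
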