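# Independent numerical oracles used across the suite. These deliberately
# avoid the closed-form code paths they are checking.

euler_rotation <- function(a, b, c) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# best-fit RMSD by direct numerical minimisation over Euler angles
rmsd_oracle <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  obj <- function(p) {
    R <- euler_rotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  starts <- expand.grid(a = c(0, pi / 2, pi, -pi / 2),
                        b = c(0, pi / 2, -pi / 2),
                        c = c(0, pi))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- optim(as.numeric(starts[i, ]), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# total-least-squares 3D line by numerical minimisation over direction angles
tls_line_oracle <- function(M) {
  ctr <- colMeans(M)
  C <- sweep(M, 2, ctr)
  obj <- function(p) {
    d <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
    sum(rowSums((C - outer(as.numeric(C %*% d), d))^2))
  }
  starts <- expand.grid(theta = c(0.3, pi / 2, 2.5),
                        phi = c(0, pi / 2, pi, 3 * pi / 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- optim(as.numeric(starts[i, ]), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  d <- c(sin(best$par[1]) * cos(best$par[2]),
         sin(best$par[1]) * sin(best$par[2]), cos(best$par[1]))
  list(direction = d, rss = best$value)
}

# dihedral by the projection-plane construction (different route from the
# atan2-of-normals implementation)
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  u <- b2 / sqrt(sum(b2^2))
  w1 <- -b1 - sum(-b1 * u) * u
  w2 <- b3 - sum(b3 * u) * u
  cr <- c(w1[2] * w2[3] - w1[3] * w2[2],
          w1[3] * w2[1] - w1[1] * w2[3],
          w1[1] * w2[2] - w1[2] * w2[1])
  ang <- atan2(sum(u * cr), sum(w1 * w2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# direct textbook evaluation of the path-progress formulas
path_oracle <- function(R, lambda) {
  w <- exp(-lambda * R)
  list(spath = sum(seq_along(R) * w) / sum(w),
       zpath = -log(sum(w)) / lambda)
}

# hand-written PDB fixture: three residues, nine atoms
write_mini_pdb <- function(path) {
  lines <- c(
    "ATOM      1  P     G A   1       1.000   2.000   3.000  1.00 10.00           P",
    "ATOM      2  C4'   G A   1       2.500   2.000   3.000  1.00 10.00           C",
    "ATOM      3  C1'   G A   1       3.000   3.500   3.000  1.00 10.00           C",
    "ATOM      4  P     C A   2       4.000   5.000   6.000  1.00 11.00           P",
    "ATOM      5  C4'   C A   2       5.500   5.000   6.000  1.00 11.00           C",
    "ATOM      6  C1'   C A   2       6.000   6.500   6.000  1.00 11.00           C",
    "ATOM      7  P     U A   3       7.000   8.000   9.000  1.00 12.00           P",
    "ATOM      8  C4'   U A   3       8.500   8.000   9.000  1.00 12.00           C",
    "ATOM      9  C1'   U A   3       9.000   9.500   9.000  1.00 12.00           C",
    "END"
  )
  writeLines(lines, path)
  path
}

write_mini_cif <- function(path) {
  lines <- c(
    "data_mini",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 P P   G A 1 G 1.000 2.000 3.000 1.00 10.0 1",
    "ATOM 2 C \"C4'\" G A 1 G 2.500 2.000 3.000 1.00 10.0 1",
    "ATOM 3 C \"C1'\" G A 1 G 3.000 3.500 3.000 1.00 10.0 1",
    "ATOM 4 P P   C A 2 C 4.000 5.000 6.000 1.00 11.0 1",
    "ATOM 5 C \"C4'\" C A 2 C 5.500 5.000 6.000 1.00 11.0 1",
    "ATOM 6 C \"C1'\" C A 2 C 6.000 6.500 6.000 1.00 11.0 1",
    "#"
  )
  writeLines(lines, path)
  path
}
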