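#' Kabsch rigid-body superposition
#'
#' Computes the least-squares optimal rotation and translation mapping
#' `mobile` onto `target` (closed-form solution via singular value
#' decomposition, with the determinant correction that guarantees a proper
#' rotation). With `reject_cycles > 0` the fit is repeated, discarding at
#' each cycle the atom pairs whose residual exceeds `reject_sigma` standard
#' deviations of the current residual distribution, mirroring the iterative
#' outlier rejection of common structure-alignment programs. The RMSD over
#' all pairs (no rejection) is always co-reported so the convention is
#' auditable.
#'
#' @param mobile,target n x 3 coordinate matrices (or data frames with
#'   x, y, z columns) of paired atoms, n >= 3.
#' @param reject_cycles number of outlier-rejection cycles (default 5).
#' @param reject_sigma rejection threshold in residual standard deviations
#'   (default 2).
#' @return A list of class `superposition` with elements `rotation` (3 x 3,
#'   determinant +1), `translation` (length-3, Angstrom), `rmsd` (Angstrom,
#'   over retained pairs), `rmsd_all` (no rejection), `n_atoms_used`,
#'   `n_rejected`, and `retained` (logical index of retained pairs).
#' @export
kabsch_superpose <- function(mobile, target, reject_cycles = 5L,
                             reject_sigma = 2.0) {
  X <- as_coord_matrix(mobile)
  Y <- as_coord_matrix(target)
  if (nrow(X) != nrow(Y)) abort("mobile and target must pair equal atom counts")
  if (nrow(X) < 3) abort("superposition needs at least 3 atom pairs")
  if (reject_sigma <= 0) abort("reject_sigma must be positive")

  fit_all <- kabsch_core(X, Y)
  keep <- rep(TRUE, nrow(X))
  fit <- fit_all
  if (reject_cycles > 0) {
    for (cycle in seq_len(reject_cycles)) {
      res <- per_pair_residual(X, Y, fit)
      res_kept <- res[keep]
      sdk <- sd(res_kept)
      if (!is.finite(sdk) || sdk < 1e-9) break  # already uniform: nothing to reject
      thr <- mean(res_kept) + reject_sigma * sdk
      new_keep <- keep & (res <= thr)
      if (sum(new_keep) < 3 || all(new_keep == keep)) break
      keep <- new_keep
      fit <- kabsch_core(X[keep, , drop = FALSE], Y[keep, , drop = FALSE])
    }
  }
  res <- per_pair_residual(X, Y, fit)
  structure(list(
    rotation = fit$R,
    translation = fit$t,
    rmsd = sqrt(mean(res[keep]^2)),
    rmsd_all = sqrt(mean(per_pair_residual(X, Y, fit_all)^2)),
    n_atoms_used = sum(keep),
    n_rejected = sum(!keep),
    retained = keep
  ), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(paste0("<superposition> rmsd %.4f A over %d atoms",
                     " (%d rejected; rmsd %.4f A with none rejected)\n"),
              x$rmsd, x$n_atoms_used, x$n_rejected, x$rmsd_all))
  invisible(x)
}

as_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- coords(x)
  x <- as.matrix(x)
  if (ncol(x) != 3) abort("coordinates must have exactly 3 columns")
  storage.mode(x) <- "double"
  x
}

# closed-form Kabsch: R maps centered mobile onto centered target
kabsch_core <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cy - as.numeric(R %*% cx)
  list(R = R, t = t)
}

per_pair_residual <- function(X, Y, fit) {
  Xt <- transform_coords(X, fit$R, fit$t)
  sqrt(rowSums((Xt - Y)^2))
}

#' Apply a rigid transform
#'
#' @param x coordinate matrix or `rna_structure`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector.
#' @return Object of the same kind as `x` with transformed coordinates.
#' @export
transform_coords <- function(x, rotation, translation = c(0, 0, 0)) {
  if (inherits(x, "rna_structure") || is.data.frame(x)) {
    m <- coords(x)
    m2 <- sweep(m %*% t(rotation), 2, translation, `+`)
    return(set_coords(x, m2))
  }
  sweep(as_coord_matrix(x) %*% t(rotation), 2, translation, `+`)
}

#' Atoms shared by two structures
#'
#' Pairs atoms by identical `(chain, resno, insert, atom)` keys (author
#' numbering only; no sequence-alignment fallback). Hydrogens are already
#' absent; single-atom ions are excluded.
#'
#' @param a,b `rna_structure` tibbles.
#' @param atoms optional atom-name filter.
#' @return List with components `a` and `b`: equal-length atom tibbles in
#'   matched order.
#' @export
common_atoms <- function(a, b, atoms = NULL) {
  ta <- as_tibble(a); tb <- as_tibble(b)
  if (!is.null(atoms)) {
    ta <- ta[ta$atom %in% atoms, ]
    tb <- tb[tb$atom %in% atoms, ]
  }
  key <- c("chain", "resno", "insert", "atom")
  ta$key <- do.call(paste, c(ta[key], sep = "|"))
  tb$key <- do.call(paste, c(tb[key], sep = "|"))
  shared <- intersect(ta$key, tb$key)
  ta <- ta[match(shared, ta$key), ]
  tb <- tb[match(shared, tb$key), ]
  ord <- order(ta$chain, ta$resno, ta$insert, ta$atom)
  list(a = ta[ord, ], b = tb[ord, ])
}

#' Superpose one structure onto another
#'
#' Convenience wrapper: pairs common atoms (optionally restricted to a
#' selection or atom set), runs [kabsch_superpose()], and returns the mobile
#' structure transformed into the target frame along with the fit.
#'
#' @param mobile,target `rna_structure` tibbles.
#' @param sel optional [selection()] resolved on both structures to restrict
#'   the alignment atoms.
#' @param atoms optional atom-name filter (e.g. `"P"`).
#' @inheritParams kabsch_superpose
#' @return List with `structure` (transformed mobile) and `fit`
#'   (`superposition`).
#' @export
superpose_structures <- function(mobile, target, sel = NULL, atoms = NULL,
                                 reject_cycles = 5L, reject_sigma = 2.0) {
  ma <- mobile; tb <- target
  if (!is.null(sel)) {
    ma <- resolve_selection(mobile, sel)
    tb <- resolve_selection(target, sel)
  }
  pair <- common_atoms(ma, tb, atoms = atoms)
  if (nrow(pair$a) == 0) abort("no common atoms between the two structures")
  fit <- kabsch_superpose(coords(pair$a), coords(pair$b),
                          reject_cycles = reject_cycles,
                          reject_sigma = reject_sigma)
  list(structure = transform_coords(mobile, fit$rotation, fit$translation),
       fit = fit)
}

#' Per-residue displacement profile between two models
#'
#' Superposes `a` onto `b` over all common non-hydrogen atoms (all-atom
#' alignment with the default rejection schedule), then reports, for every
#' residue common to both models, the Euclidean distance between the
#' analogous `atom_used` atoms (default the backbone phosphate). This maps
#' where two conformations differ: in the group II intron D1 comparison it
#' highlights the i1-i2 and peripheral D1c nucleotides as the most displaced
#' and the D1d1 stem as the least.
#'
#' @param a,b `rna_structure` tibbles sharing author numbering.
#' @param atom_used atom name compared per residue (default `"P"`).
#' @inheritParams kabsch_superpose
#' @return Tibble of class `displacement_profile` with columns `chain`,
#'   `resno`, `resname`, `displacement` (Angstrom); residues missing
#'   `atom_used` in either model are omitted and reported in the
#'   `n_omitted_residues` attribute. The superposition is attached as the
#'   `fit` attribute.
#' @export
displacement_profile <- function(a, b, atom_used = "P",
                                 reject_cycles = 5L, reject_sigma = 2.0) {
  pair_all <- common_atoms(a, b)
  if (nrow(pair_all$a) == 0) abort("structures share no residues")
  fit <- kabsch_superpose(coords(pair_all$a), coords(pair_all$b),
                          reject_cycles = reject_cycles,
                          reject_sigma = reject_sigma)
  pair <- common_atoms(a, b, atoms = atom_used)
  moved <- transform_coords(coords(pair$a), fit$rotation, fit$translation)
  d <- sqrt(rowSums((moved - coords(pair$b))^2))
  out <- tibble(
    chain = pair$a$chain, resno = pair$a$resno,
    resname = pair$a$resname, displacement = d
  )
  res_a <- dplyr::distinct(as_tibble(a)[, c("chain", "resno")])
  res_b <- dplyr::distinct(as_tibble(b)[, c("chain", "resno")])
  n_common <- nrow(dplyr::inner_join(res_a, res_b, by = c("chain", "resno")))
  attr(out, "n_omitted_residues") <- n_common - nrow(out)
  attr(out, "fit") <- fit
  attr(out, "atom_used") <- atom_used
  class(out) <- c("displacement_profile", class(out))
  out
}
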