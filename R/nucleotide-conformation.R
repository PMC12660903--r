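#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking down the p2->p3 bond, the angle is positive
#' for a clockwise rotation of p3->p4 relative to p1->p2, with values in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    abort("undefined dihedral: three consecutive points are collinear")
  }
  b2n <- b2 / sqrt(sum(b2^2))
  xcomp <- sum(n1 * n2)
  ycomp <- sum(cross3(n1, n2) * b2n)
  ang <- atan2(ycomp, xcomp) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone pseudo-torsions eta and theta
#'
#' The coarse-grained two-atom-per-residue backbone representation:
#' `eta(i) = dihedral(C4'(i-1), P(i), C4'(i), P(i+1))` and
#' `theta(i) = dihedral(P(i), C4'(i), P(i+1), C4'(i+1))`. Chain termini and
#' residues whose required P/C4' atoms are missing are flagged `NA` rather
#' than raising an error. Comparing eta/theta profiles between conformations
#' localizes backbone pivots such as the group II intron D1 hinge motifs.
#'
#' @param s an `rna_structure`.
#' @param chain chain identifier (default first chain).
#' @return Tibble with columns `chain`, `resno`, `resname`, `eta`, `theta`
#'   (degrees in (-180, 180], `NA` when undefined).
#' @export
pseudo_torsions <- function(s, chain = NULL) {
  tbl <- as_tibble(s)
  chain <- chain %||% tbl$chain[1]
  tbl <- tbl[tbl$chain == chain, ]
  if (nrow(tbl) == 0) abort(paste0("no residues on chain ", chain))
  res <- dplyr::distinct(tbl[, c("chain", "resno", "resname")])
  res <- res[order(res$resno), ]
  n <- nrow(res)
  if (n < 3) abort("pseudo-torsions need >= 3 residues")
  get_atom <- function(resno, name) {
    hit <- tbl[tbl$resno == resno & tbl$atom == name, ]
    if (nrow(hit) == 0) return(NULL)
    as.numeric(coords(hit)[1, ])
  }
  eta <- theta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    r <- res$resno
    # a gap in author numbering is a chain break, not a bonded neighbour
    if (r[i] - r[i - 1] != 1 || r[i + 1] - r[i] != 1) next
    c4_prev <- get_atom(r[i - 1], "C4'")
    p_i <- get_atom(r[i], "P")
    c4_i <- get_atom(r[i], "C4'")
    p_next <- get_atom(r[i + 1], "P")
    c4_next <- get_atom(r[i + 1], "C4'")
    if (!is.null(c4_prev) && !is.null(p_i) && !is.null(c4_i) &&
        !is.null(p_next)) {
      eta[i] <- tryCatch(dihedral(c4_prev, p_i, c4_i, p_next),
                         error = function(e) NA_real_)
    }
    if (!is.null(p_i) && !is.null(c4_i) && !is.null(p_next) &&
        !is.null(c4_next)) {
      theta[i] <- tryCatch(dihedral(p_i, c4_i, p_next, c4_next),
                           error = function(e) NA_real_)
    }
  }
  tibble(chain = res$chain, resno = res$resno, resname = res$resname,
         eta = eta, theta = theta)
}

#' Bulged-in / bulged-out classification of a nucleotide
#'
#' Measures the perpendicular distance of the nucleobase ring centroid from
#' the local helical axis and compares it against the distribution of the
#' same distance over the non-hinge residues of the helix. A base whose
#' centroid sits more than `out_threshold` standard deviations beyond the
#' helix mean is `bulged_out` (solvent-exposed, as hinge-1 residues A72 and
#' C116 in the closed scaffold); below `in_threshold` it is `bulged_in`
#' (stacked toward the helix interior); the gap between the thresholds is
#' reported `indeterminate` so borderline residues do not flip-flop.
#'
#' @param s an `rna_structure`.
#' @param residue `c(chain, resno)` of the query nucleotide.
#' @param helix [selection()] of the helix providing the axis and reference
#'   residues.
#' @param atom_set backbone atoms for the axis fit.
#' @param exclude_resno residues excluded from the reference distribution
#'   (typically the hinge residues, including the query).
#' @param out_threshold,in_threshold z-score thresholds (defaults +2 / +1).
#' @return One-row tibble: `chain`, `resno`, `axis_distance`,
#'   `reference_distance`, `reference_sd` (Angstrom), `zscore`, `label`.
#' @export
classify_flip <- function(s, residue, helix, atom_set = backbone_atoms(),
                          exclude_resno = NULL,
                          out_threshold = 2, in_threshold = 1) {
  axis <- fit_helix_axis(s, helix, atom_set = atom_set)
  chain <- as.character(residue[[1]])
  resno <- as.integer(residue[[2]])
  exclude_resno <- unique(c(as.integer(exclude_resno), resno))
  d_query <- base_axis_distance(s, chain, resno, axis)
  if (is.na(d_query)) {
    abort(sprintf("residue %s%d has fewer than 3 base ring atoms", chain, resno))
  }
  helix_atoms <- resolve_selection(s, helix)
  ref_res <- dplyr::distinct(helix_atoms[, c("chain", "resno", "resname")])
  ref_res <- ref_res[!(ref_res$resno %in% exclude_resno), ]
  d_ref <- vapply(seq_len(nrow(ref_res)), function(i) {
    base_axis_distance(s, ref_res$chain[i], ref_res$resno[i], axis)
  }, numeric(1))
  d_ref <- d_ref[!is.na(d_ref)]
  if (length(d_ref) < 3) abort("too few reference residues with base atoms")
  mu <- mean(d_ref); sdev <- sd(d_ref)
  z <- if (sdev > 0) (d_query - mu) / sdev else 0
  label <- if (z > out_threshold) "bulged_out"
           else if (z < in_threshold) "bulged_in"
           else "indeterminate"
  tibble(chain = chain, resno = resno,
         axis_distance = d_query, reference_distance = mu,
         reference_sd = sdev, zscore = z, label = label)
}

base_axis_distance <- function(s, chain, resno, axis) {
  tbl <- as_tibble(s)
  res <- tbl[tbl$chain == chain & tbl$resno == resno, ]
  if (nrow(res) == 0) return(NA_real_)
  ring <- res[res$atom %in% base_ring_atoms(res$resname[1]), ]
  if (nrow(ring) < 3) return(NA_real_)
  centroid <- colMeans(coords(ring))
  v <- centroid - axis$anchor
  perp <- v - sum(v * axis$direction) * axis$direction
  sqrt(sum(perp^2))
}
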