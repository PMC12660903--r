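#' Fit a helical axis to a subdomain
#'
#' The axis is the total-least-squares 3D line through the selected
#' sugar-phosphate backbone atoms: it passes through their centroid along the
#' principal (largest-variance) direction of the centered atom cloud. Both
#' strands of a duplex subdomain contribute to one fit. The direction sign is
#' fixed deterministically by the 5'-to-3' convention: the axis points from
#' the centroid of the first three residues of the lowest-numbered strand
#' segment toward the centroid of its last three residues.
#'
#' @param s an `rna_structure`.
#' @param sel [selection()] defining the subdomain.
#' @param atom_set backbone atom names used for the fit; default
#'   [backbone_atoms()].
#' @return A list of class `helix_axis`: `anchor` (centroid, Angstrom),
#'   `direction` (unit vector), `residual_rms` (RMS perpendicular distance,
#'   Angstrom), `n_atoms`, `n_missing_residues`, and `ambiguous` (TRUE when
#'   the two largest cloud variances coincide within 1e-6 and the axis is not
#'   well defined).
#' @export
fit_helix_axis <- function(s, sel, atom_set = backbone_atoms()) {
  atoms <- resolve_selection(s, sel)
  n_missing <- attr(atoms, "n_missing_residues") %||% 0L
  if (!is.null(atom_set)) atoms <- atoms[atoms$atom %in% atom_set, ]
  if (nrow(atoms) < 6) {
    abort(sprintf("helix-axis fit%s needs >= 6 atoms, got %d",
                  if (is.null(sel$name)) "" else paste0(" for '", sel$name, "'"),
                  nrow(atoms)))
  }
  m <- coords(atoms)
  anchor <- colMeans(m)
  centered <- sweep(m, 2, anchor)
  s3 <- svd(centered, nu = 0)
  direction <- s3$v[, 1]
  var1 <- s3$d[1]^2 / nrow(m)
  var2 <- s3$d[2]^2 / nrow(m)
  ambiguous <- (var1 - var2) < 1e-6
  if (ambiguous) {
    warn("degenerate atom cloud: helical axis direction is ambiguous")
  }
  # 5'->3' orientation along the lowest-numbered strand segment: the
  # contiguous run of residues starting at the lowest selected number
  seg <- atoms[atoms$chain == sel$chain[1], ]
  resnos <- sort(unique(seg$resno))
  run_end <- which(diff(resnos) != 1)
  run <- if (length(run_end) > 0) resnos[seq_len(run_end[1])] else resnos
  if (length(run) >= 2) {
    lo <- head(run, 3); hi <- tail(run, 3)
    p_lo <- colMeans(coords(seg[seg$resno %in% lo, ]))
    p_hi <- colMeans(coords(seg[seg$resno %in% hi, ]))
    if (sum((p_hi - p_lo) * direction) < 0) direction <- -direction
  }
  perp <- centered - outer(as.numeric(centered %*% direction), direction)
  structure(list(
    anchor = anchor,
    direction = direction / sqrt(sum(direction^2)),
    residual_rms = sqrt(mean(rowSums(perp^2))),
    n_atoms = nrow(m),
    n_missing_residues = n_missing,
    ambiguous = ambiguous
  ), class = "helix_axis")
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf("<helix_axis> dir (%.3f, %.3f, %.3f), residual %.2f A, %d atoms\n",
              x$direction[1], x$direction[2], x$direction[3],
              x$residual_rms, x$n_atoms))
  invisible(x)
}

#' Angle between two helical axes
#'
#' The directed angle is `acos(a . b)` in `[0, 180]` degrees using the
#' 5'-to-3' oriented directions; the undirected angle folds it into
#' `[0, 90]`. Both values are always returned; `convention` selects which one
#' populates `angle`.
#'
#' @param a,b `helix_axis` objects (or unit 3-vectors).
#' @param convention `"directed"` (default) or `"undirected"`.
#' @return Tibble with columns `angle`, `directed`, `undirected` (degrees).
#' @export
angle_between_axes <- function(a, b, convention = c("directed", "undirected")) {
  convention <- match.arg(convention)
  ua <- if (inherits(a, "helix_axis")) a$direction else a / sqrt(sum(a^2))
  ub <- if (inherits(b, "helix_axis")) b$direction else b / sqrt(sum(b^2))
  cosang <- max(-1, min(1, sum(ua * ub)))
  directed <- acos(cosang) * 180 / pi
  undirected <- min(directed, 180 - directed)
  tibble(
    angle = if (convention == "directed") directed else undirected,
    directed = directed,
    undirected = undirected
  )
}

#' Gate distance of the D1 pocket
#'
#' Euclidean distance between the two registry gate atoms; for the packaged
#' O. iheyensis registry these are the C1' atoms of G75 and U238, a scalar
#' proxy for the aperture of the D1 active-site pocket.
#'
#' @param s an `rna_structure`.
#' @param registry a [read_registry()] registry (default the packaged one).
#' @return Distance in Angstrom.
#' @export
gate_distance <- function(s, registry = default_registry()) {
  pts <- lapply(registry$gate, function(g) {
    hit <- as_tibble(s)
    hit <- hit[hit$chain == g$chain & hit$resno == g$resno &
                 hit$atom == g$atom, ]
    if (nrow(hit) == 0) {
      abort(sprintf("gate atom %s missing from residue %s%d",
                    g$atom, g$chain, g$resno))
    }
    as.numeric(coords(hit)[1, ])
  })
  sqrt(sum((pts[[1]] - pts[[2]])^2))
}

#' Radius of gyration
#'
#' Mass-unweighted RMS distance of the selected non-hydrogen atoms from
#' their centroid.
#'
#' @param s an `rna_structure`.
#' @param sel optional [selection()]; `NULL` uses all atoms.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(s, sel = NULL) {
  atoms <- if (is.null(sel)) as_tibble(s) else resolve_selection(s, sel)
  if (nrow(atoms) < 2) abort("radius of gyration needs >= 2 atoms")
  m <- coords(atoms)
  centered <- sweep(m, 2, colMeans(m))
  sqrt(mean(rowSums(centered^2)))
}

#' Compute the scaffold descriptor set of one model
#'
#' Fits one helical axis per registered subdomain and reports the four
#' inter-helical angles (A: core D1c vs D1d1; B: core D1c vs peripheral D1c;
#' C: core D1c vs i1-i2; D: D1d1 vs i1-i2), the gate distance, and the
#' radius of gyration over the union of the subdomain selections. Residues
#' missing from any subdomain (e.g. disordered peripheral nucleotides in
#' cryo-EM models) are skipped with a tally; the fit proceeds while at least
#' six backbone atoms remain.
#'
#' @param s an `rna_structure`.
#' @param registry a [read_registry()] registry.
#' @param convention angle convention passed to [angle_between_axes()].
#' @return One-row tibble: `model_id`, `angle_A` .. `angle_D` (degrees,
#'   chosen convention), the matching `angle_*_undirected` values,
#'   `gate_distance` and `rg` (Angstrom), and `n_missing_residues`. The
#'   fitted axes are attached as the `axes` attribute.
#' @export
compute_descriptors <- function(s, registry = default_registry(),
                                convention = c("directed", "undirected")) {
  convention <- match.arg(convention)
  axes <- lapply(names(registry$subdomains), function(nm) {
    tryCatch(
      fit_helix_axis(s, registry$subdomains[[nm]], atom_set = registry$atom_set),
      error = function(e) {
        abort(sprintf("axis fit failed for subdomain '%s': %s",
                      nm, conditionMessage(e)))
      }
    )
  })
  names(axes) <- names(registry$subdomains)
  ang <- lapply(registry$angles, function(pair) {
    angle_between_axes(axes[[pair[1]]], axes[[pair[2]]], convention = convention)
  })
  all_ranges <- unlist(lapply(registry$subdomains, function(sd) sd$ranges),
                       recursive = FALSE)
  all_chains <- unlist(lapply(registry$subdomains, function(sd) sd$chain))
  union_sel <- selection(all_ranges, chain = all_chains)
  out <- tibble(model_id = structure_id(s))
  for (nm in names(ang)) {
    out[[paste0("angle_", nm)]] <- ang[[nm]]$angle
    out[[paste0("angle_", nm, "_undirected")]] <- ang[[nm]]$undirected
  }
  out$gate_distance <- gate_distance(s, registry)
  out$rg <- radius_of_gyration(s, union_sel)
  out$n_missing_residues <- sum(vapply(axes, `[[`, numeric(1),
                                       "n_missing_residues"))
  attr(out, "axes") <- axes
  class(out) <- c("descriptor_set", class(out))
  out
}
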